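# Mean and second-moment equations of the jump model and its diffusion
# approximations, with exact closure for affine gain.
#
# The coordinate map is linear, so the mean of the embedded process obeys
#   d/dt E nu = -E nu / tau + E Fbar(nu, t) / tau.
# For affine gain (clip inactive on visited states) E Fbar(nu) =
# Fbar(E nu) and the mean system is a closed linear ODE -- exactly the
# spatially discretized Wilson-Cowan equation. The second moments then
# close as well, and the Langevin and linear-noise second-moment
# equations coincide.

affine_coefficients <- function(m, t = 0) {
  if (!m$gain$kind %in% c("affine", "constant"))
    stop("exact closure requires an affine (or constant) gain",
         call. = FALSE)
  if (m$gain$kind == "constant") {
    b1 <- 0; b2 <- m$gain$params$c
  } else {
    b1 <- m$gain$params$beta1; b2 <- m$gain$params$beta2
  }
  list(A1 = b1 * m$W_bar, c0 = b1 * m$input_bar(t) + b2, b1 = b1, b2 = b2)
}

#' Solve the mean ODE on the partition
#'
#' Integrates `d/dt Enu = (-Enu + Fbar(Enu, t)) / tau` by classical RK4.
#' For affine gain this is the exact mean of the jump process; for
#' nonlinear gain it is the first-order (mean-field) closure
#' `E f(.) ~ f(E .)` only, and must be requested explicitly.
#'
#' @param m an `nf_micro_model`.
#' @param theta0_mean initial mean counts (vector of length P).
#' @param T horizon.
#' @param dt RK4 step.
#' @param closure `"affine-exact"` (default; errors for nonlinear gain)
#'   or `"mean-field"`.
#' @return object of class `nf_moments_mean`: `times`, matrix `values`
#'   (times x P, active fractions), `closure`.
#' @export
solve_mean_ode <- function(m, theta0_mean, T, dt = 1e-3,
                           closure = c("affine-exact", "mean-field")) {
  closure <- match.arg(closure)
  if (closure == "affine-exact" && !m$gain$kind %in% c("affine", "constant"))
    stop("affine-exact closure requires affine or constant gain; ",
         "use closure = \"mean-field\" for nonlinear gains", call. = FALSE)
  P <- m$partition$P
  l <- as.numeric(m$partition$pop_sizes)
  v <- as.numeric(theta0_mean) / l
  stopifnot(length(v) == P)
  rhs <- function(vv, tt) {
    z <- as.numeric(m$W_bar %*% vv) + m$input_bar(tt)
    (-vv + m$gain$fn(z)) / m$tau
  }
  nsteps <- max(1L, ceiling(T / dt))
  h <- T / nsteps
  times <- seq(0, T, length.out = nsteps + 1L)
  out <- matrix(NA_real_, nsteps + 1L, P)
  out[1, ] <- v
  for (s in seq_len(nsteps)) {
    tt <- times[s]
    k1 <- rhs(v, tt); k2 <- rhs(v + h / 2 * k1, tt + h / 2)
    k3 <- rhs(v + h / 2 * k2, tt + h / 2); k4 <- rhs(v + h * k3, tt + h)
    v <- v + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    out[s + 1L, ] <- v
  }
  structure(list(times = times, values = out, closure = closure,
                 partition = m$partition),
            class = "nf_moments_mean")
}

#' Second-moment ODE right-hand side
#'
#' Evaluates `d/dt E (phi, nu)^2` for the jump model (`"micro"`), the
#' Langevin approximation (`"langevin"`) and the linear-noise
#' approximation (`"linear_noise"`), closed through first and second
#' moments under affine gain. The drift part
#' `2/tau E[(phi, nu)(phi, -nu + Fbar(nu, t))]` is common; the noise
#' parts are, per variant, the expected finite-n quadratic variation
#' (micro), `eps^2 <G(mean, t) phi, phi>` (Langevin: affine closure
#' moves the expectation inside), and `eps^2 <G(nu_det, t) phi, phi>`
#' (linear noise, frozen on the deterministic solution). When the mean
#' equals the deterministic solution — which holds for affine gain —
#' Langevin and linear-noise right-hand sides coincide.
#'
#' @param m an `nf_micro_model` with affine or constant gain.
#' @param phi vectorized test function.
#' @param mu mean active fractions (length P).
#' @param S second-moment matrix `E[nu nu^T]` (P x P).
#' @param variant `"micro"`, `"langevin"` or `"linear_noise"`.
#' @param t time.
#' @param epsilon noise amplitude for the SPDE variants (defaults to
#'   [epsilon_from_partition()] of the model's partition).
#' @param nu_det deterministic solution on the partition at `t`
#'   (linear-noise variant; defaults to `mu`).
#' @return scalar RHS value.
#' @export
second_moment_rhs <- function(m, phi, mu, S,
                              variant = c("micro", "langevin",
                                          "linear_noise"),
                              t = 0, epsilon = NULL, nu_det = mu) {
  variant <- match.arg(variant)
  ac <- affine_coefficients(m, t)
  p <- cell_pairing(m$partition, phi)
  P <- m$partition$P
  l <- as.numeric(m$partition$pop_sizes)
  stopifnot(length(mu) == P, all(dim(S) == c(P, P)))
  q <- as.numeric(crossprod(ac$A1 - diag(P), p))  # (A1 - I)^T p
  drift <- 2 / m$tau * (sum(p * (S %*% q)) + sum(p * mu) * sum(p * ac$c0))
  gbar_mu <- as.numeric(ac$A1 %*% mu) + ac$c0  # Fbar at the mean
  if (variant == "micro") {
    noise <- sum((mu + gbar_mu) / l * p^2) / m$tau
  } else {
    if (is.null(epsilon)) epsilon <- epsilon_from_partition(m$partition)
    p2 <- cell_pairing(m$partition, function(x) phi(x)^2)
    vv <- if (variant == "langevin") mu else nu_det
    gbar <- as.numeric(ac$A1 %*% vv) + ac$c0
    noise <- epsilon^2 * sum((vv + gbar) * p2) / m$tau
  }
  drift + noise
}

#' Solve the closed micro second-moment system (affine gain)
#'
#' Under affine gain the pair (mean vector, second-moment matrix) of the
#' embedded process solves the closed linear system
#' `dS_kj/dt = (1/tau)[S(A1 - I)^T + (A1 - I)S + c0 mu^T + mu c0^T]_kj
#'  + delta_kj (mu_k + (A1 mu + c0)_k) / (tau l_k)`;
#' integrated by RK4. Returns `s_phi(t) = p^T S(t) p` for each supplied
#' test function, the mean trajectory, and the final matrix.
#'
#' @param m an `nf_micro_model` with affine or constant gain.
#' @param theta0 deterministic initial counts (vector length P).
#' @param T horizon.
#' @param dt RK4 step.
#' @param phis list of vectorized test functions.
#' @return object of class `nf_moments_second`: `times`, `mean`
#'   (times x P fractions), `s_phi` (times x phis), `S_final`.
#' @export
solve_second_moment <- function(m, theta0, T, dt = 1e-3, phis = list()) {
  ac0 <- affine_coefficients(m, 0)
  P <- m$partition$P
  l <- as.numeric(m$partition$pop_sizes)
  mu <- as.numeric(theta0) / l
  S <- outer(mu, mu)  # deterministic start: E[nu nu^T] = mu mu^T
  nsteps <- max(1L, ceiling(T / dt))
  h <- T / nsteps
  times <- seq(0, T, length.out = nsteps + 1L)
  pmat <- if (length(phis)) vapply(phis, function(f)
    cell_pairing(m$partition, f), numeric(P)) else matrix(0, P, 0)
  mean_out <- matrix(NA_real_, nsteps + 1L, P)
  s_out <- matrix(NA_real_, nsteps + 1L, ncol(pmat))
  record <- function(i, mu, S) {
    mean_out[i, ] <<- mu
    if (ncol(pmat)) s_out[i, ] <<- diag(t(pmat) %*% S %*% pmat)
  }
  deriv <- function(mu, S, tt) {
    ac <- affine_coefficients(m, tt)
    Am <- ac$A1 - diag(P)
    gmu <- as.numeric(ac$A1 %*% mu) + ac$c0
    dmu <- (-mu + gmu) / m$tau
    dS <- (S %*% t(Am) + Am %*% S +
             outer(ac$c0, mu) + outer(mu, ac$c0)) / m$tau
    diag(dS) <- diag(dS) + (mu + gmu) / (m$tau * l^2) * l
    list(dmu = dmu, dS = dS)
  }
  record(1L, mu, S)
  for (s in seq_len(nsteps)) {
    tt <- times[s]
    k1 <- deriv(mu, S, tt)
    k2 <- deriv(mu + h / 2 * k1$dmu, S + h / 2 * k1$dS, tt + h / 2)
    k3 <- deriv(mu + h / 2 * k2$dmu, S + h / 2 * k2$dS, tt + h / 2)
    k4 <- deriv(mu + h * k3$dmu, S + h * k3$dS, tt + h)
    mu <- mu + h / 6 * (k1$dmu + 2 * k2$dmu + 2 * k3$dmu + k4$dmu)
    S <- S + h / 6 * (k1$dS + 2 * k2$dS + 2 * k3$dS + k4$dS)
    record(s + 1L, mu, S)
  }
  structure(list(times = times, mean = mean_out, s_phi = s_out,
                 S_final = S, partition = m$partition),
            class = "nf_moments_second")
}

#' Compare moment systems across model representations
#'
#' Tabulates first and second moments of the test-function pairings
#' `(phi, nu_t)` at the output times for: the jump-process Monte Carlo
#' ensemble, the Langevin and linear-noise ensembles, and the closed
#' moment ODEs (exact for affine gain, mean-field closure otherwise).
#'
#' @param m an `nf_micro_model`.
#' @param nu0 initial field (function or scalar).
#' @param T horizon.
#' @param phis list of test functions.
#' @param replicates Monte Carlo ensemble size.
#' @param seed base seed.
#' @param t_out output times.
#' @param dt ODE / SPDE step.
#' @param spde_grid grid cells for the SPDE ensembles.
#' @return data.frame with columns `time`, `phi`, `moment` (1 or 2),
#'   `micro_mc`, `micro_se`, `langevin`, `langevin_se`, `linear_noise`,
#'   `linear_noise_se`, `ode`.
#' @export
compare_moment_systems <- function(m, nu0, T, phis, replicates = 200,
                                   seed = 1, t_out = NULL, dt = 5e-3,
                                   spde_grid = 64) {
  if (is.null(t_out)) t_out <- seq(0, T, length.out = 5L)
  theta0 <- make_initial_state(m$partition, nu0)
  p <- m$partition
  pmat <- vapply(phis, function(f) cell_pairing(p, f),
                 numeric(p$P))
  # jump-process ensemble
  sims <- simulate_ensemble(m, theta0, T, replicates, seed, mesh = t_out,
                            reduce = function(s) s$counts)
  eps <- epsilon_from_partition(p)
  # pairings per replicate: times x phis x reps
  mc <- vapply(sims, function(cnt)
    crossprod(cnt / p$pop_sizes, pmat), matrix(0, length(t_out), length(phis)))
  spde_args <- list(tau = m$tau, gain = m$gain, kernel = m$kernel,
                    input = m$input, nu0 = nu0, epsilon = eps, T = T,
                    dom = p$domain, grid_size = spde_grid, dt = dt,
                    seed = seed, replicates = replicates, phis = phis,
                    t_out = t_out)
  lna <- do.call(integrate_spde, c(spde_args, variant = "linear_noise"))
  lang <- do.call(integrate_spde, c(spde_args, variant = "langevin"))
  closure <- if (m$gain$kind %in% c("affine", "constant"))
    "affine-exact" else "mean-field"
  ode_mean <- solve_mean_ode(m, theta0, T, dt = dt, closure = closure)
  ode_idx <- vapply(t_out, function(tt)
    which.min(abs(ode_mean$times - tt)), integer(1))
  ode2 <- if (closure == "affine-exact")
    solve_second_moment(m, theta0, T, dt = dt, phis = phis) else NULL
  rows <- list()
  mstat <- function(x) c(mean(x), stats::sd(x) / sqrt(length(x)))
  for (it in seq_along(t_out)) for (ip in seq_along(phis)) {
    x_mc <- mc[it, ip, ]
    x_lna <- lna$pairings_t[it, ip, ]
    x_lang <- lang$pairings_t[it, ip, ]
    for (mom in 1:2) {
      f <- if (mom == 1) identity else function(z) z^2
      s_mc <- mstat(f(x_mc)); s_ln <- mstat(f(x_lna)); s_lg <- mstat(f(x_lang))
      ode_val <- if (mom == 1)
        sum(pmat[, ip] * ode_mean$values[ode_idx[it], ])
      else if (!is.null(ode2))
        ode2$s_phi[which.min(abs(ode2$times - t_out[it])), ip]
      else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        time = t_out[it], phi = ip, moment = mom,
        micro_mc = s_mc[1], micro_se = s_mc[2],
        langevin = s_lg[1], langevin_se = s_lg[2],
        linear_noise = s_ln[1], linear_noise_se = s_ln[2],
        ode = ode_val)
    }
  }
  do.call(rbind, rows)
}
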