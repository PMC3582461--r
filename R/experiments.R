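# Scenario presets and the headline numerical experiments: empirical law
# of large numbers, uniform-in-time mean convergence, and the martingale
# central limit theorem, all at desk scale on the unit interval.

#' Scenario presets
#'
#' A scenario bundles the model ingredients with a partition family and
#' experiment sizes. The family `l(k, n) = pop_factor * n` keeps the
#' ratio `v_- ell_- / (v_+ ell_+) = 1` (uniform cells, equal population
#' sizes), which the CLT rescaling requires, and satisfies
#' `delta_+(n) -> 0`, `ell_-(n) -> infinity` along `n_values`.
#'
#' * `"constant"`: constant gain c = 0.5, stationary from the start
#'   (`nu0 = c`); all limit quantities in closed form.
#' * `"affine"`: clipped-affine gain 0.4 z + 0.3 with all-to-all
#'   coupling 0.5; the clip never activates on visited states, so the
#'   moment systems close exactly.
#' * `"sigmoid"`: logistic gain (beta1 = 5, beta2 = -2) with a Gaussian
#'   kernel (width 0.2) and constant input 0.3: a smooth, genuinely
#'   nonlinear neural field.
#'
#' @param name preset name.
#' @param n_values partition resolutions.
#' @param pop_factor population-size factor: `l(k, n) = pop_factor * n`.
#' @param T time horizon.
#' @param replicates Monte Carlo replicates.
#' @param alphas dual-norm orders reported alongside L2.
#' @return an object of class `nf_scenario`.
#' @export
scenario_preset <- function(name = c("constant", "affine", "sigmoid"),
                            n_values = c(4L, 8L, 16L, 32L),
                            pop_factor = 25, T = 2, replicates = 200,
                            alphas = 1) {
  name <- match.arg(name)
  dom <- domain(1L)
  sc <- switch(name,
    constant = list(
      gain = gain_constant(0.5), kernel = kernel_constant(1),
      input = input_constant(0), nu0 = function(x) rep(0.5, length(x))),
    affine = list(
      gain = gain_affine(0.4, 0.3, 1), kernel = kernel_constant(0.5),
      input = input_constant(0),
      nu0 = function(x) 0.3 + 0.2 * cos(pi * x)),
    sigmoid = list(
      gain = gain_sigmoid(5, -2), kernel = kernel_gaussian(1, 0.2),
      input = input_constant(0.3),
      nu0 = function(x) 0.2 + 0.2 * cos(pi * x)))
  structure(c(sc, list(
    name = name, dom = dom, tau = 1, n_values = sort(as.integer(n_values)),
    pop_factor = pop_factor, T = T, replicates = as.integer(replicates),
    alphas = alphas, K = 64L, mesh_points = 81L, dt_macro = 2e-3,
    cell_quad = 4L)), class = "nf_scenario")
}

#' @export
print.nf_scenario <- function(x, ...) {
  cat("<nf_scenario>", x$name, " n =", paste(x$n_values, collapse = ","),
      " l = ", x$pop_factor, "n  T =", x$T,
      " replicates =", x$replicates, "\n")
  invisible(x)
}

#' Validate a scenario against the limit-theorem hypotheses
#'
#' Checks that along the partition family the maximum diameter strictly
#' decreases and the minimum population size is non-decreasing (the law
#' of large numbers conditions), that the gain metadata validates by
#' sampling, and (if `clt = TRUE`) that the rescaling ratio
#' `v_- ell_- / (v_+ ell_+)` equals one for every family member.
#'
#' @param sc an `nf_scenario`.
#' @param clt also require the CLT ratio condition.
#' @return `TRUE` invisibly; errors with an explanation otherwise.
#' @export
validate_scenario <- function(sc, clt = FALSE) {
  stopifnot(inherits(sc, "nf_scenario"))
  if (length(sc$n_values) < 2L)
    stop("partition family needs at least two resolutions", call. = FALSE)
  stats <- lapply(sc$n_values, function(n)
    partition_stats(uniform_partition(sc$dom, n,
                                      pop_size = sc$pop_factor * n)))
  dp <- vapply(stats, `[[`, numeric(1), "delta_plus")
  lm_ <- vapply(stats, `[[`, numeric(1), "ell_minus")
  if (any(diff(dp) >= 0))
    stop("delta_+(n) must strictly decrease along the family", call. = FALSE)
  if (any(diff(lm_) < 0))
    stop("ell_-(n) must be non-decreasing along the family", call. = FALSE)
  validate_gain(sc$gain)
  if (clt) {
    r <- vapply(stats, function(s)
      s$v_minus / s$v_plus * s$ell_minus / s$ell_plus, numeric(1))
    if (any(abs(r - 1) > 1e-12))
      stop("CLT requires v_- ell_- / (v_+ ell_+) = 1 along the family",
           call. = FALSE)
  }
  invisible(TRUE)
}

# micro model + aligned per-cell macro solution for one family member
build_member <- function(sc, n, T = sc$T, t_out = NULL) {
  p <- uniform_partition(sc$dom, n, pop_size = sc$pop_factor * n)
  m <- micro_model(p, sc$tau, sc$gain, sc$kernel, sc$input)
  grid <- partition_grid(p, sc$cell_quad)
  macro <- solve_wilson_cowan(sc$tau, sc$gain, sc$kernel, sc$input,
                              sc$nu0, T, dom = sc$dom, grid = grid,
                              dt = sc$dt_macro, t_out = t_out)
  list(p = p, m = m, grid = grid, macro = macro)
}

# K x P matrix mapping piecewise-cell values to cosine coefficients (d=1)
partition_cosine_map <- function(p, K) {
  ext <- p$domain$extent[1]
  nc <- cos_norm_const(K, ext)
  sapply(seq_len(p$P), function(k)
    nc * cos_cell_integrals(K, p$lower[k, 1], p$upper[k, 1], ext))
}

# K x N cosine basis values at grid nodes (d=1)
grid_cosine_basis <- function(nodes, ext, K) {
  nc <- cos_norm_const(K, ext)
  nc * cos(outer((0:(K - 1L)) * pi / ext, nodes))
}

#' Empirical law of large numbers
#'
#' For each family member n: Monte Carlo estimate of
#' `E sup_t ||nu_t^n - nu(t)||` in L2 and in each requested dual norm
#' `H^{-alpha}` (the sup taken over the recording mesh), against the
#' macroscopic solution computed on a per-cell quadrature grid. Errors
#' are expected to decrease along the family; the log-log slope in n is
#' fitted.
#'
#' @param sc an `nf_scenario`.
#' @param seed base seed.
#' @param replicates overrides the scenario count if given.
#' @return object of class `nf_convergence`: `table` (one row per n),
#'   `slopes`, `kind = "lln"`.
#' @export
run_lln <- function(sc, seed = 1, replicates = NULL) {
  validate_scenario(sc)
  R <- if (is.null(replicates)) sc$replicates else replicates
  if (R < 2L) stop("need at least 2 replicates", call. = FALSE)
  mesh <- seq(0, sc$T, length.out = sc$mesh_points)
  K <- sc$K
  rows <- list()
  for (n in sc$n_values) {
    mb <- build_member(sc, n, t_out = mesh)
    p <- mb$p; l <- as.numeric(p$pop_sizes)
    gw <- mb$grid$weights
    M <- length(mesh)
    nu_vals <- t(mb$macro$values)            # N x M
    agg <- function(vals) rowsum(vals, mb$grid$cell)  # per-cell sums, P x M
    cellint1 <- agg(gw * nu_vals)
    cellint2 <- colSums(matrix(gw, length(gw), M) * nu_vals^2)  # int nu^2
    cellint2_cell <- agg(gw * nu_vals^2)
    Ccos <- partition_cosine_map(p, K)
    Bcos <- grid_cosine_basis(mb$grid$nodes[, 1], sc$dom$extent[1], K)
    Scoef <- Bcos %*% (gw * nu_vals)         # K x M smooth coefficients
    mults <- lapply(sc$alphas, function(a)
      mode_multipliers(mode_grid(K, 1L), sc$dom$extent, a))
    theta0 <- make_initial_state(p, sc$nu0)
    sup_l2 <- matrix(NA_real_, R, 1L)
    sup_a <- matrix(NA_real_, R, length(sc$alphas))
    for (r in seq_len(R)) {
      sim <- simulate_pdmp(mb$m, theta0, sc$T,
                           seed = replicate_seed(seed, r), mesh = mesh)
      V <- sim$counts / l                     # P x M fractions
      e2 <- colSums(V^2 * p$measures) - 2 * colSums(V * cellint1) +
        colSums(cellint2_cell)
      sup_l2[r, 1] <- sqrt(max(pmax(e2, 0)))
      if (length(sc$alphas)) {
        cf <- Ccos %*% V - Scoef              # K x M
        for (ia in seq_along(sc$alphas))
          sup_a[r, ia] <- sqrt(max(colSums(mults[[ia]] * cf^2)))
      }
    }
    st <- partition_stats(p)
    row <- data.frame(n = n, P = p$P, ell_minus = st$ell_minus,
                      delta_plus = st$delta_plus, v_plus = st$v_plus,
                      err_l2 = mean(sup_l2), se_l2 = stats::sd(sup_l2) / sqrt(R))
    for (ia in seq_along(sc$alphas)) {
      row[[paste0("err_a", sc$alphas[ia])]] <- mean(sup_a[, ia])
      row[[paste0("se_a", sc$alphas[ia])]] <- stats::sd(sup_a[, ia]) / sqrt(R)
    }
    rows[[length(rows) + 1L]] <- row
  }
  tab <- do.call(rbind, rows)
  slopes <- c(l2 = fit_slope(tab$n, tab$err_l2))
  for (a in sc$alphas)
    slopes[paste0("a", a)] <- fit_slope(tab$n, tab[[paste0("err_a", a)]])
  structure(list(table = tab, slopes = slopes, kind = "lln",
                 scenario = sc$name, replicates = R, seed = seed),
            class = "nf_convergence")
}

fit_slope <- function(n, err) {
  unname(stats::coef(stats::lm(log(err) ~ log(n)))[2])
}

#' @export
print.nf_convergence <- function(x, ...) {
  cat("<nf_convergence>", x$kind, "scenario =", x$scenario,
      " replicates =", x$replicates, "\n")
  print(x$table, row.names = FALSE, digits = 4)
  cat("log-log slopes in n:", paste(names(x$slopes),
                                    signif(x$slopes, 3), sep = "=",
                                    collapse = "  "), "\n")
  invisible(x)
}

#' @export
plot.nf_convergence <- function(x, ...) {
  err_cols <- grep("^err_", names(x$table), value = TRUE)
  graphics::matplot(x$table$n, as.matrix(x$table[err_cols]), log = "xy",
                    type = "b", pch = 1, xlab = "n", ylab = "error", ...)
  graphics::legend("bottomleft", legend = err_cols,
                   col = seq_along(err_cols), lty = seq_along(err_cols),
                   cex = 0.8)
  invisible(x)
}

#' Check a monotone-decrease trend allowing noisy inversions
#'
#' `TRUE` if the point estimates decrease along the rows except for at
#' most `allow` inversions, each within `z` combined standard errors.
#'
#' @param est point estimates (ordered by increasing n).
#' @param se their standard errors.
#' @param allow inversions tolerated (default 1).
#' @param z combined-SE multiple an inversion must stay within.
#' @return logical.
#' @export
trend_decreasing <- function(est, se, allow = 1L, z = 2) {
  d <- diff(est)
  bad <- d >= 0
  tol <- d <= z * sqrt(se[-length(se)]^2 + se[-1]^2)
  sum(bad) <= allow && all(!bad | tol)
}

#' Uniform-in-time mean convergence
#'
#' For each family member: `sup_t || E nu_t^n - nu(t) ||_{H^{-alpha}}`
#' over a coarse mesh up to `T = horizon_tau * tau`, with the
#' ensemble-mean field against the deterministic solution, plus the same
#' statistic restricted to `t <= 2 tau`. Standard errors by jackknife
#' over replicate batches.
#'
#' @param sc an `nf_scenario`.
#' @param seed base seed.
#' @param replicates overrides the scenario count.
#' @param horizon_tau horizon in units of tau (default 20).
#' @param alpha dual-norm order (default 1).
#' @param batches jackknife batches.
#' @return object of class `nf_convergence` with columns `stat`
#'   (sup to T), `se`, `stat_early` (sup to 2 tau), `se_early`,
#'   `diff_se` (SE of stat - stat_early).
#' @export
run_longtime <- function(sc, seed = 1, replicates = NULL,
                         horizon_tau = 20, alpha = 1, batches = 10L) {
  validate_scenario(sc)
  R <- if (is.null(replicates)) sc$replicates else replicates
  T <- horizon_tau * sc$tau
  mesh <- sort(unique(c(seq(0, T, length.out = 41L), 2 * sc$tau)))
  early <- mesh <= 2 * sc$tau + 1e-12
  K <- sc$K
  batch_of <- rep(seq_len(batches), length.out = R)
  rows <- list()
  for (n in sc$n_values) {
    mb <- build_member(sc, n, T = T, t_out = mesh)
    p <- mb$p; l <- as.numeric(p$pop_sizes)
    gw <- mb$grid$weights
    nu_vals <- t(mb$macro$values)
    Ccos <- partition_cosine_map(p, K)
    Bcos <- grid_cosine_basis(mb$grid$nodes[, 1], sc$dom$extent[1], K)
    Scoef <- Bcos %*% (gw * nu_vals)
    mult <- mode_multipliers(mode_grid(K, 1L), sc$dom$extent, alpha)
    theta0 <- make_initial_state(p, sc$nu0)
    sumV <- vector("list", batches)
    cnt <- integer(batches)
    for (r in seq_len(R)) {
      sim <- simulate_pdmp(mb$m, theta0, T,
                           seed = replicate_seed(seed, r), mesh = mesh)
      b <- batch_of[r]
      V <- sim$counts / l
      sumV[[b]] <- if (is.null(sumV[[b]])) V else sumV[[b]] + V
      cnt[b] <- cnt[b] + 1L
    }
    tot <- Reduce(`+`, sumV)
    stat_of <- function(Vbar) {
      cf <- Ccos %*% Vbar - Scoef
      e <- sqrt(colSums(mult * cf^2))
      c(sup = max(e), sup_early = max(e[early]))
    }
    full <- stat_of(tot / R)
    loo <- vapply(seq_len(batches), function(b)
      stat_of((tot - sumV[[b]]) / (R - cnt[b])), numeric(2))
    jk_se <- function(v) sqrt((batches - 1) / batches *
                                sum((v - mean(v))^2))
    d_loo <- loo[1, ] - loo[2, ]
    st <- partition_stats(p)
    rows[[length(rows) + 1L]] <- data.frame(
      n = n, P = p$P, ell_minus = st$ell_minus,
      delta_plus = st$delta_plus,
      stat = full["sup"], se = jk_se(loo[1, ]),
      stat_early = full["sup_early"], se_early = jk_se(loo[2, ]),
      diff_se = jk_se(d_loo))
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  structure(list(table = tab, slopes = c(stat = fit_slope(tab$n, tab$stat)),
                 kind = "longtime", scenario = sc$name, replicates = R,
                 seed = seed, alpha = alpha, horizon_tau = horizon_tau),
            class = "nf_convergence")
}

#' Martingale central limit theorem experiment
#'
#' For each family member n and test function phi: the empirical
#' variance of the rescaled pairing `rho_n (M_T, phi)` with jackknife
#' SE, the finite-n quadratic-variation oracle (whose expectation equals
#' the variance exactly), and the limiting value `<C(T) phi, phi>`.
#'
#' @param sc an `nf_scenario`.
#' @param seed base seed.
#' @param replicates overrides the scenario count (>= 100 recommended).
#' @param modes mode indices of the L2-orthonormal test functions
#'   (default 0:3).
#' @return object of class `nf_convergence` with one row per (n, phi).
#' @export
run_clt <- function(sc, seed = 1, replicates = NULL, modes = 0:3) {
  validate_scenario(sc, clt = TRUE)
  R <- if (is.null(replicates)) sc$replicates else replicates
  if (R < 2L) stop("need at least 2 replicates", call. = FALSE)
  phis <- lapply(modes, function(k) spectral_mode(sc$dom, k))
  rows <- list()
  for (n in sc$n_values) {
    mb <- build_member(sc, n, t_out = seq(0, sc$T, length.out = 101L))
    p <- mb$p; l <- as.numeric(p$pop_sizes)
    rho <- clt_rescaling(p)
    pmat <- vapply(phis, function(f) cell_pairing(p, f), numeric(p$P))
    theta0 <- make_initial_state(p, sc$nu0)
    X <- matrix(NA_real_, R, length(phis))
    QV <- matrix(NA_real_, R, length(phis))
    for (r in seq_len(R)) {
      sim <- simulate_pdmp(mb$m, theta0, sc$T,
                           seed = replicate_seed(seed, r), mesh = sc$T)
      Mc <- (sim$counts[, 1] - theta0 + sim$A[, 1] / sc$tau -
               l * sim$B[, 1] / sc$tau) / l
      X[r, ] <- as.numeric(crossprod(pmat, Mc))
      QV[r, ] <- colSums((sim$A[, 1] + l * sim$B[, 1]) / l^2 * pmat^2) /
        sc$tau
    }
    for (ip in seq_along(phis)) {
      ec <- empirical_covariance(X[, ip], rho)
      lim <- covariance_C(mb$macro, sc$T, phis[[ip]])
      rows[[length(rows) + 1L]] <- data.frame(
        n = n, phi = modes[ip], rho = rho,
        emp_var = ec$variance, emp_se = ec$se,
        emp_mean = ec$mean,
        oracle_var = rho^2 * mean(QV[, ip]),
        oracle_se = rho^2 * stats::sd(QV[, ip]) / sqrt(R),
        limit_var = lim,
        gap = abs(ec$variance - lim))
    }
  }
  tab <- do.call(rbind, rows)
  structure(list(table = tab, slopes = NULL, kind = "clt",
                 scenario = sc$name, replicates = R, seed = seed),
            class = "nf_convergence")
}
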