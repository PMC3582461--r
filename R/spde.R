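# Euler-Maruyama integration of the Langevin and linear-noise
# approximations with pointwise-multiplication noise:
#   dU = tau^{-1}(-U + F(U, t)) dt + eps g(t, x) dW(t, x)
# with g evaluated on the deterministic solution (linear noise;
# additive) or on the current state (Langevin; multiplicative), and
# g(t,x) = sqrt(nu/tau + f(int w nu dy + I)/tau).
#
# The drift is stepped by the same exponential-Euler rule as the
# deterministic solver, so the eps = 0 path reproduces it exactly.
# Space-time white noise is represented piecewise-constantly on the
# quadrature grid: the increment at a node with quadrature weight w_i has
# variance dt / w_i, which gives pairings (phi, g dW) the correct
# variance dt * int phi^2 g^2 dx.

#' Noise amplitude from partition statistics
#'
#' `eps_n = sqrt(v_+(n) / l_-(n)) = 1 / rho_n`: the reciprocal of the
#' CLT rescaling; the square root of area per neuron, i.e. inverse
#' root local neuron density.
#'
#' @param stats an `nf_partition_stats` (or `nf_partition`).
#' @return scalar noise amplitude.
#' @export
epsilon_from_partition <- function(stats) {
  if (inherits(stats, "nf_partition")) stats <- partition_stats(stats)
  sqrt(stats$v_plus / stats$ell_minus)
}

#' Diffusion coefficient field
#'
#' `g(x) = sqrt(v(x)/tau + f(int w v dy + I(t, x))/tau)` on the grid of
#' `v`. Square-root arguments in `[-1e-12, 0)` are clipped to zero (the
#' state of the multiplicative equation may dip below zero at finite
#' step size); more negative arguments are an error.
#'
#' @param v an `nf_grid_field` (state or deterministic solution).
#' @param t time.
#' @param tau time constant.
#' @param gain,kernel,input model ingredients.
#' @param K optional precomputed [kernel_matrix()] for the grid.
#' @return an `nf_grid_field` of non-negative values, with attribute
#'   `n_clipped`.
#' @export
diffusion_field_g <- function(v, t, tau, gain, kernel, input, K = NULL) {
  stopifnot(inherits(v, "nf_grid_field"))
  if (is.null(K)) K <- kernel_matrix(kernel, v$nodes, v$weights)
  x <- if (ncol(v$nodes) == 1) v$nodes[, 1] else v$nodes
  arg <- (v$values + gain$fn(as.numeric(K %*% v$values) + input$fn(t, x))) / tau
  n_clip <- sum(arg < 0)
  if (any(arg < -1e-12))
    stop("diffusion coefficient argument below -1e-12", call. = FALSE)
  g <- grid_field(v$nodes, v$weights, sqrt(pmax(arg, 0)), v$domain)
  attr(g, "n_clipped") <- n_clip
  g
}

#' Integrate the linear-noise / Langevin approximation
#'
#' Ensemble Euler-Maruyama integration (exponential-Euler drift). For
#' `variant = "linear_noise"` the noise coefficient is frozen on the
#' deterministic Wilson-Cowan solution, computed alongside with the
#' identical stepping (additive noise); for `variant = "langevin"` it is
#' evaluated on the current state (multiplicative noise) with sqrt
#' arguments clipped at zero and the clip fraction reported.
#'
#' @param tau,gain,kernel,input model ingredients.
#' @param nu0 initial field (function or scalar).
#' @param epsilon noise amplitude (>= 0), e.g.
#'   [epsilon_from_partition()].
#' @param T horizon.
#' @param dom a [domain()] (d = 1).
#' @param grid_size number of uniform midpoint cells for the spatial
#'   grid (piecewise-constant noise representation).
#' @param dt time step.
#' @param seed base seed; replicate r uses [replicate_seed()].
#' @param replicates ensemble size.
#' @param phis list of test functions; their pairings `(U_t, phi)` are
#'   recorded at every output time.
#' @param variant `"linear_noise"` or `"langevin"`.
#' @param t_out output times (default ~51 equispaced).
#' @return an object of class `nf_spde`: `times`, `mean_values`
#'   (times x nodes ensemble mean), `pairings` (replicates x phis at
#'   final time), `pairings_t` (times x phis x replicates array),
#'   `clip_fraction`, grid and parameters.
#' @export
integrate_spde <- function(tau, gain, kernel, input = input_constant(0),
                           nu0 = 0, epsilon, T = 1, dom = domain(),
                           grid_size = 64, dt = 1e-2, seed = 1,
                           replicates = 100, phis = list(),
                           variant = c("linear_noise", "langevin"),
                           t_out = NULL) {
  variant <- match.arg(variant)
  stopifnot(tau > 0, dt > 0, epsilon >= 0, dom$dim == 1L)
  # uniform midpoint grid: equal weights h, the piecewise-constant
  # cylindrical-Wiener discretization
  h <- dom$extent[1] / grid_size
  nodes <- matrix(seq(h / 2, dom$extent[1] - h / 2, by = h), ncol = 1)
  weights <- rep(h, grid_size)
  N <- grid_size
  x <- nodes[, 1]
  K <- kernel_matrix(kernel, nodes, weights)
  v0 <- if (is.function(nu0)) as.numeric(nu0(x)) else rep_len(nu0, N)
  nsteps <- max(1L, ceiling(T / dt))
  hstep <- T / nsteps
  E <- exp(-hstep / tau)
  step_times <- seq(0, T, length.out = nsteps + 1L)
  if (is.null(t_out)) {
    keep <- if (nsteps + 1L <= 51L) seq_len(nsteps + 1L) else
      unique(round(seq(1L, nsteps + 1L, length.out = 51L)))
  } else {
    keep <- vapply(t_out, function(tt) which.min(abs(step_times - tt)),
                   integer(1))
  }
  times <- step_times[keep]
  Fv <- function(vv, tt) gain$fn(as.numeric(K %*% vv) + input$fn(tt, x))

  # deterministic path (linear-noise coefficient and eps = 0 reference)
  det <- matrix(NA_real_, nsteps + 1L, N)
  det[1, ] <- v0
  for (s in seq_len(nsteps))
    det[s + 1L, ] <- E * det[s, ] + (1 - E) * Fv(det[s, ], step_times[s])
  gdet <- matrix(NA_real_, nsteps, N)  # g on [t_s, t_{s+1})
  for (s in seq_len(nsteps)) {
    arg <- (det[s, ] + Fv(det[s, ], step_times[s])) / tau
    gdet[s, ] <- sqrt(pmax(arg, 0))
  }

  nphi <- length(phis)
  phimat <- if (nphi) vapply(phis, function(f) f(x), numeric(N)) else
    matrix(0, N, 0)
  mean_vals <- matrix(0, length(keep), N)
  pair_t <- array(NA_real_, c(length(keep), nphi, replicates))
  clip <- 0; total_nodesteps <- 0
  sdW <- sqrt(hstep / weights)
  for (r in seq_len(replicates)) {
    set.seed(replicate_seed(seed, r))
    v <- v0
    ki <- 1L
    for (s in seq_len(nsteps + 1L)) {
      if (ki <= length(keep) && s == keep[ki]) {
        mean_vals[ki, ] <- mean_vals[ki, ] + v
        if (nphi)
          pair_t[ki, , r] <- as.numeric(crossprod(phimat, weights * v))
        ki <- ki + 1L
      }
      if (s > nsteps) break
      tt <- step_times[s]
      if (variant == "linear_noise") {
        gs <- gdet[s, ]
      } else {
        arg <- (v + Fv(v, tt)) / tau
        clip <- clip + sum(arg < 0)
        gs <- sqrt(pmax(arg, 0))
      }
      total_nodesteps <- total_nodesteps + N
      dW <- stats::rnorm(N, 0, sdW)
      v <- E * v + (1 - E) * Fv(v, tt) + epsilon * gs * dW
      if (any(!is.finite(v)))
        stop("SPDE integration diverged at step ", s, call. = FALSE)
    }
  }
  mean_vals <- mean_vals / replicates
  clip_fraction <- clip / max(1, total_nodesteps)
  if (variant == "langevin" && clip_fraction > 0.05)
    warning("sqrt-argument clipped on ",
            format(100 * clip_fraction, digits = 3), "% of node-steps")
  pairings <- if (nphi) {
    pm <- pair_t[length(keep), , , drop = FALSE]  # 1 x nphi x reps
    t(matrix(pm, nphi, replicates))
  } else NULL
  structure(list(times = times, mean_values = mean_vals,
                 pairings = pairings, pairings_t = pair_t,
                 deterministic = det[keep, , drop = FALSE],
                 nodes = nodes, weights = weights, epsilon = epsilon,
                 variant = variant, dt = hstep, tau = tau, seed = seed,
                 clip_fraction = clip_fraction,
                 replicates = replicates),
            class = "nf_spde")
}

#' @rdname integrate_spde
#' @param ... passed to [integrate_spde()].
#' @export
integrate_linear_noise <- function(...) {
  integrate_spde(..., variant = "linear_noise")
}

#' @rdname integrate_spde
#' @export
integrate_langevin <- function(...) {
  integrate_spde(..., variant = "langevin")
}

#' @export
print.nf_spde <- function(x, ...) {
  cat("<nf_spde>", x$variant, " eps =", format(x$epsilon),
      " replicates =", x$replicates,
      " clip =", format(x$clip_fraction), "\n")
  invisible(x)
}
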