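# Martingale extraction from trajectories, the CLT rescaling, the
# limiting diffusion covariance C(t), and empirical covariance
# estimation.
#
# The embedded process satisfies nu_t = nu_0 + int_0^t [-nu_s/tau +
# Fbar(nu_s, s)/tau] ds + M_t; the martingale M carries all the
# stochasticity and, rescaled by rho_n = sqrt(l_-(n) / v_+(n)),
# converges to the centred diffusion with covariance
# <C(t) phi, psi> = int_0^t int_D phi (nu(s,x)/tau + F(nu(s),s)(x)/tau)
# psi dx ds.

#' CLT rescaling factor
#'
#' `rho_n = sqrt(l_-(n) / v_+(n))`: paths of the martingale are scaled
#' by rho_n (variances by rho_n^2). The reciprocal is the noise
#' amplitude `epsilon_n` of the Langevin approximations.
#'
#' @param stats an `nf_partition_stats` (or `nf_partition`).
#' @return scalar rescaling factor.
#' @export
clt_rescaling <- function(stats) {
  if (inherits(stats, "nf_partition")) stats <- partition_stats(stats)
  sqrt(stats$ell_minus / stats$v_plus)
}

#' Extract the martingale part of a trajectory
#'
#' `M_t = nu^n(Theta_t) - nu^n(Theta_0) - int_0^t [-nu^n_s/tau +
#' Fbar(nu^n_s, s)/tau] ds`, computed exactly from the occupation and
#' gain integrals the simulator accumulates between jumps.
#'
#' @param traj an `nf_trajectory` simulated with a recording mesh.
#' @return an object of class `nf_martingale`: `mesh`, matrix `values`
#'   (P x length(mesh): per-cell field coefficients of M_t), `rho`
#'   (rescaling of the generating partition) and the `partition`.
#' @export
extract_martingale <- function(traj) {
  stopifnot(inherits(traj, "nf_trajectory"))
  m <- traj$model
  p <- m$partition
  l <- p$pop_sizes
  counts0 <- traj$counts[, 1]
  if (traj$mesh[1] != 0)
    counts0 <- traj$init
  # counts-level martingale: theta_t - theta_0 + A/tau - l B/tau
  Mc <- sweep(traj$counts, 1, as.numeric(counts0)) +
    traj$A / m$tau - sweep(traj$B, 1, as.numeric(l), `*`) / m$tau
  structure(list(mesh = traj$mesh, values = Mc / l,
                 rho = clt_rescaling(p), partition = p),
            class = "nf_martingale")
}

#' @export
print.nf_martingale <- function(x, ...) {
  cat("<nf_martingale> P =", nrow(x$values), " mesh points =",
      length(x$mesh), " rho =", format(x$rho), "\n")
  invisible(x)
}

#' Pair a test function against the cells of a partition
#'
#' `int_{D_k} phi dx` per cell: the weights through which partition
#' fields (and martingales) pair with a test function in L2.
#'
#' @param p an `nf_partition`.
#' @param phi vectorized function on the domain.
#' @param quad_order quadrature order per axis.
#' @return numeric vector of length P.
#' @export
cell_pairing <- function(p, phi, quad_order = 8) {
  vapply(seq_len(p$P), function(k)
    cell_average(phi, p$lower[k, ], p$upper[k, ], quad_order) * p$measures[k],
    numeric(1))
}

#' Martingale-test function pairing
#'
#' `(M_t, phi)_{L2}` along the mesh for one trajectory's martingale.
#'
#' @param mart an `nf_martingale`.
#' @param phi_cells cell pairings from [cell_pairing()].
#' @return numeric vector over the mesh.
#' @export
martingale_pairing <- function(mart, phi_cells) {
  as.numeric(crossprod(mart$values, phi_cells))
}

#' Finite-n quadratic variation of the paired martingale
#'
#' The predictable quadratic variation of `(M_t, phi)` up to `T`:
#' `tau^{-1} sum_k l(k)^{-2} (A_k(T) + l(k) B_k(T)) (int_{D_k} phi)^2`,
#' whose expectation equals `Var[(M_T, phi)]` exactly (Ito isometry).
#' This is the finite-n oracle the empirical CLT variance is compared
#' against.
#'
#' @param traj an `nf_trajectory` whose mesh contains `T`.
#' @param phi_cells cell pairings from [cell_pairing()].
#' @param T time (defaults to the trajectory horizon).
#' @return scalar quadratic variation.
#' @export
quadratic_variation <- function(traj, phi_cells, T = NULL) {
  m <- traj$model
  l <- as.numeric(m$partition$pop_sizes)
  if (is.null(T)) T <- traj$T
  i <- which.min(abs(traj$mesh - T))
  sum((traj$A[, i] + l * traj$B[, i]) / l^2 * phi_cells^2) / m$tau
}

#' Limiting diffusion covariance: the bilinear form G
#'
#' `<G(nu(t), t) phi, psi> = int_D phi (nu(t,x)/tau +
#' f(int w nu dy + I(t,x))/tau) psi dx` over the grid of a macroscopic
#' solution; symmetric and positive.
#'
#' @param macro an `nf_macro`.
#' @param t time (nearest recorded time used).
#' @param phi,psi vectorized test functions.
#' @return scalar form value.
#' @export
covariance_form_G <- function(macro, t, phi, psi = phi) {
  i <- macro_time_index(macro, t)
  x <- if (ncol(macro$grid$nodes) == 1) macro$grid$nodes[, 1] else
    macro$grid$nodes
  dens <- (macro$values[i, ] + macro_F_values(macro, i)) / macro$tau
  sum(macro$grid$weights * phi(x) * dens * psi(x))
}

#' Limiting diffusion covariance C(t)
#'
#' `<C(t) phi, psi> = int_0^t <G(nu(s), s) phi, psi> ds` by composite
#' trapezoid quadrature over the recorded macro time mesh; non-negative
#' and non-decreasing in `t` for `phi = psi`.
#'
#' @inheritParams covariance_form_G
#' @return scalar form value.
#' @export
covariance_C <- function(macro, t, phi, psi = phi) {
  i <- macro_time_index(macro, t)
  if (i == 1L) return(0)
  x <- if (ncol(macro$grid$nodes) == 1) macro$grid$nodes[, 1] else
    macro$grid$nodes
  pv <- phi(x) * psi(x) * macro$grid$weights
  g <- vapply(seq_len(i), function(j)
    sum(pv * (macro$values[j, ] + macro_F_values(macro, j))) / macro$tau,
    numeric(1))
  ts <- macro$times[seq_len(i)]
  sum(diff(ts) * (g[-1] + g[-length(g)]) / 2)
}

#' Truncated trace of C(t)
#'
#' Partial sums `sum_{j <= J} <C(t) phi_j, phi_j>` over the
#' alpha-orthonormal spectral modes; each summand obeys the uniform
#' bound `t (1 + ||f||_0) |D| ||phi_j||_{L2}^2 / tau`, and for
#' `alpha > d/2` the partial sums converge, which is the trace-class
#' property the limiting diffusion needs.
#'
#' @param macro an `nf_macro`.
#' @param t time.
#' @param J number of modes.
#' @param alpha weighting order of the basis (> d/2 for summability).
#' @return list with `value` (partial sum at J), `summands`, and
#'   `l2_norms` (the `||phi_j||_{L2}^2` entering the bound).
#' @export
trace_estimate <- function(macro, t, J, alpha) {
  stopifnot(J >= 1)
  dom <- macro$domain
  d <- dom$dim
  if (d != 1L) stop("trace_estimate implemented for d = 1", call. = FALSE)
  summands <- numeric(J)
  l2n <- numeric(J)
  for (j in seq_len(J)) {
    kap <- j - 1L
    phi <- spectral_mode(dom, kap, alpha)
    summands[j] <- covariance_C(macro, t, phi)
    l2n[j] <- (1 + (pi * kap / dom$extent)^2)^(-alpha)
  }
  list(value = sum(summands), summands = summands, l2_norms = l2n)
}

#' Empirical covariance of rescaled martingale pairings
#'
#' Sample variance of `X_r = rho_n (M_T^{(r)}, phi)` over replicates,
#' with jackknife standard error; the CLT predicts convergence to
#' `<C(T) phi, phi>`.
#'
#' @param X numeric vector of per-replicate pairings `(M_T, phi)` (not
#'   yet rescaled).
#' @param rho rescaling factor of the generating partition.
#' @return list with `variance`, `se`, `mean` and `n`.
#' @export
empirical_covariance <- function(X, rho = 1) {
  R <- length(X)
  if (R < 2L) stop("need at least 2 replicates", call. = FALSE)
  Xs <- rho * X
  v <- stats::var(Xs)
  # jackknife SE of the variance
  loo <- vapply(seq_len(R), function(r) stats::var(Xs[-r]), numeric(1))
  se <- sqrt((R - 1) / R * sum((loo - mean(loo))^2))
  list(variance = v, se = se, mean = mean(Xs), n = R)
}
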