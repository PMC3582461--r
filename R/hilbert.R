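# L2 and negative-order Sobolev (dual) norms on piecewise and grid
# fields, realized spectrally on the Neumann cosine basis of the box, and
# Poincare-inequality utilities.
#
# H^{-alpha}(D) is the dual of H^alpha(D). On a box this dual norm is
# equivalent to the multiplier norm sum_kappa (1 + |pi kappa / ext|^2)^(-alpha)
# c_kappa^2 over the cosine coefficients c_kappa; equivalent norms change
# constants but not convergence orders, which is what the verification
# suite measures.

#' L2(D) norm of a field
#'
#' Exact for partition-supported fields (`sqrt(sum c_k^2 |D_k|)`);
#' quadrature for grid fields.
#'
#' @param field an `nf_field`.
#' @return scalar norm.
#' @export
l2_norm <- function(field) {
  if (inherits(field, "nf_piecewise_field"))
    return(sqrt(sum(field$coef^2 * field$partition$measures)))
  if (inherits(field, "nf_grid_field"))
    return(sqrt(sum(field$weights * field$values^2)))
  stop("`field` must be an nf_field", call. = FALSE)
}

# Mode index matrix: K^d rows, entries 0..K-1, first axis fastest.
mode_grid <- function(K, d) {
  as.matrix(expand.grid(rep(list(0:(K - 1L)), d)))
}

# Neumann cosine multipliers (1 + |pi kappa / ext|^2)^(-alpha)
mode_multipliers <- function(modes, extent, alpha) {
  lam2 <- rowSums(sweep(modes, 2, pi / extent, `*`)^2)
  (1 + lam2)^(-alpha)
}

# int_a^b cos(kappa pi x / e) dx for all kappa in 0..K-1 (one axis)
cos_cell_integrals <- function(K, a, b, e) {
  kap <- 0:(K - 1L)
  out <- numeric(K)
  out[1] <- b - a
  if (K > 1L) {
    k <- kap[-1]
    out[-1] <- e / (k * pi) * (sin(k * pi * b / e) - sin(k * pi * a / e))
  }
  out
}

# normalization of the 1-axis basis function sqrt((2 - delta_k0)/e)
cos_norm_const <- function(K, e) sqrt(c(1, rep(2, K - 1L)) / e)

#' Cosine (Neumann) spectral coefficients of a field
#'
#' Coefficients on the orthonormal cosine tensor basis of the box. For
#' partition fields the per-cell integrals of the basis functions are in
#' closed form, so the projection is exact; for grid fields the
#' coefficients are computed by quadrature (accurate while the modes are
#' resolved by the grid, which the damped high modes of the dual norms
#' tolerate).
#'
#' @param field an `nf_field`.
#' @param K modes per axis.
#' @return list with `coef` (length K^d), `modes` (K^d x d index
#'   matrix) and `extent`.
#' @export
spectral_coefficients <- function(field, K = 256) {
  K <- as.integer(K)
  stopifnot(K >= 1L)
  if (inherits(field, "nf_piecewise_field")) {
    p <- field$partition
    ext <- p$domain$extent
    d <- p$domain$dim
    # per-axis integral tables: list over axes of K x P matrices
    tabs <- lapply(seq_len(d), function(i) {
      nc <- cos_norm_const(K, ext[i])
      sapply(seq_len(p$P), function(k)
        nc * cos_cell_integrals(K, p$lower[k, i], p$upper[k, i], ext[i]))
    })
    modes <- mode_grid(K, d)
    if (d == 1L) {
      coef <- as.numeric(tabs[[1]] %*% field$coef)
    } else if (d == 2L) {
      # coefficient(k1,k2) = sum_cells c_cell T1[k1,cell] T2[k2,cell];
      # column-major flattening matches expand.grid (first axis fastest)
      coef <- as.numeric(tabs[[1]] %*% sweep(t(tabs[[2]]), 1,
                                             field$coef, `*`))
    } else stop("d <= 2 supported", call. = FALSE)
    return(list(coef = coef, modes = modes, extent = ext))
  }
  if (inherits(field, "nf_grid_field")) {
    ext <- field$domain$extent
    d <- field$domain$dim
    modes <- mode_grid(K, d)
    nodes <- field$nodes
    B <- matrix(1, nrow(modes), nrow(nodes))
    for (i in seq_len(d)) {
      nc <- cos_norm_const(K, ext[i])
      B <- B * (nc[modes[, i] + 1L] *
                  cos(outer(modes[, i] * pi / ext[i], nodes[, i])))
    }
    coef <- as.numeric(B %*% (field$weights * field$values))
    return(list(coef = coef, modes = modes, extent = ext))
  }
  stop("`field` must be an nf_field", call. = FALSE)
}

#' Negative-order Sobolev norm
#'
#' Spectral multiplier realization of the `H^{-alpha}(D)` dual norm:
#' project onto the first `K^d` Neumann cosine modes, weight mode kappa
#' by `(1 + |pi kappa / extent|^2)^{-alpha}`, and take the weighted l2
#' norm. `alpha = 0` reproduces the L2 norm of the projection; the norm
#' is non-increasing in `alpha`.
#'
#' @param field an `nf_field`.
#' @param alpha dual smoothness order (>= 0).
#' @param K modes per axis (default 256).
#' @return scalar norm, with attribute `underresolved = TRUE` (and a
#'   warning) if a partition field has more than K/2 cells per axis.
#' @export
neg_sobolev_norm <- function(field, alpha, K = 256) {
  stopifnot(alpha >= 0)
  sc <- spectral_coefficients(field, K)
  under <- FALSE
  if (inherits(field, "nf_piecewise_field")) {
    npa <- field$partition$n
    if (!is.na(npa) && K < 2L * npa) {
      under <- TRUE
      warning("K < 2 cells per axis: partition field underresolved")
    }
  }
  mult <- mode_multipliers(sc$modes, sc$extent, alpha)
  out <- sqrt(sum(mult * sc$coef^2))
  if (under) attr(out, "underresolved") <- TRUE
  out
}

#' Duality pairing of two fields through the spectral basis
#'
#' Computes `(phi, psi)_{L2}` from truncated cosine coefficients; for
#' band-limited factors this equals the L2 inner product, which is the
#' evolution-triplet identity the dual norms rest on.
#'
#' @param f1,f2 `nf_field` objects on the same domain.
#' @param K modes per axis.
#' @return scalar pairing.
#' @export
spectral_pairing <- function(f1, f2, K = 256) {
  c1 <- spectral_coefficients(f1, K)
  c2 <- spectral_coefficients(f2, K)
  sum(c1$coef * c2$coef)
}

#' Poincare ratio of a smooth field on a box
#'
#' `||f - mean(f)||_{L2} / ||grad f||_{L2}`, which on a convex domain
#' never exceeds `diam(D) / pi`; the first nonconstant Neumann mode
#' attains the bound.
#'
#' @param fn scalar field (vectorized).
#' @param grad gradient: for d = 1 a function returning the derivative;
#'   for d > 1 returning a matrix of partials (points x d).
#' @param lower,upper box corners (default unit interval).
#' @param quad_order Gauss-Legendre order per axis (default 40).
#' @return scalar ratio.
#' @export
poincare_ratio <- function(fn, grad, lower = 0, upper = 1, quad_order = 40) {
  g <- tensor_gauss(as.numeric(lower), as.numeric(upper), quad_order)
  x <- if (ncol(g$nodes) == 1) g$nodes[, 1] else g$nodes
  v <- fn(x)
  vol <- prod(upper - lower)
  mean_v <- sum(g$weights * v) / vol
  num <- sqrt(sum(g$weights * (v - mean_v)^2))
  gv <- grad(x)
  if (is.null(dim(gv))) gv <- matrix(gv, ncol = 1)
  den <- sqrt(sum(g$weights * rowSums(gv^2)))
  if (den < 1e-14)
    stop("gradient vanishes: Poincare ratio undefined", call. = FALSE)
  num / den
}

#' Dual norm of a cell indicator
#'
#' `||1_{cell}||_{H^{-alpha}}` for a box cell inside the domain; at
#' `alpha = 0` this is `sqrt(|cell|)` exactly, and across a refining
#' cube family the squared norm scales like `|cell| v_+^{min(2 alpha/d, 1)}`.
#'
#' @param lower,upper cell corners.
#' @param dom the [domain()] containing the cell.
#' @param alpha dual order.
#' @param K modes per axis.
#' @return scalar norm.
#' @export
indicator_dual_norm <- function(lower, upper, dom, alpha, K = 256) {
  stopifnot(inherits(dom, "nf_domain"))
  lower <- as.numeric(lower); upper <- as.numeric(upper)
  d <- dom$dim
  ext <- dom$extent
  modes <- mode_grid(as.integer(K), d)
  coef <- rep(1, nrow(modes))
  for (i in seq_len(d)) {
    nc <- cos_norm_const(K, ext[i])
    ints <- nc * cos_cell_integrals(K, lower[i], upper[i], ext[i])
    coef <- coef * ints[modes[, i] + 1L]
  }
  mult <- mode_multipliers(modes, ext, alpha)
  sqrt(sum(mult * coef^2))
}

#' Spectral test functions
#'
#' The Neumann cosine mode `kappa` of the box, L2-orthonormal by
#' default; with `alpha > 0` the mode is rescaled by
#' `(1 + |pi kappa/ext|^2)^{-alpha/2}`, making the family orthonormal in
#' the alpha-weighted (H^alpha) spectral inner product — the basis the
#' trace of the limiting covariance is summed over.
#'
#' @param dom a [domain()].
#' @param kappa mode index vector (length d, entries >= 0).
#' @param alpha weighting order (default 0: L2-orthonormal).
#' @return a vectorized function of points.
#' @export
spectral_mode <- function(dom, kappa, alpha = 0) {
  stopifnot(inherits(dom, "nf_domain"), length(kappa) == dom$dim,
            all(kappa >= 0))
  ext <- dom$extent
  scale <- prod(sqrt(ifelse(kappa > 0, 2, 1) / ext)) *
    (1 + sum((pi * kappa / ext)^2))^(-alpha / 2)
  function(x) {
    if (is.null(dim(x))) x <- matrix(x, ncol = 1)
    v <- rep(scale, nrow(x))
    for (i in seq_len(ncol(x)))
      v <- v * cos(kappa[i] * pi * x[, i] / ext[i])
    v
  }
}
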