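#' Spatial domain
#'
#' A bounded axis-aligned box domain \eqn{D \subset R^d}. All partitions,
#' kernels and fields in the package live on such a domain. Only the box
#' geometry is supported: it makes cell measures and diameters exact and
#' every cell trivially convex, which is what the Poincare-based error
#' analysis of the mean-field limit requires.
#'
#' @param dim spatial dimension, an integer >= 1 (1 or 2 in practice).
#' @param extent per-axis side lengths; recycled to length `dim`.
#' @return an object of class `nf_domain` with fields `dim`, `extent`
#'   (numeric vector of side lengths) and `measure` (Lebesgue measure).
#' @examples
#' domain()            # unit interval
#' domain(2)           # unit square
#' domain(1, extent = 2)
#' @export
domain <- function(dim = 1L, extent = 1) {
  dim <- as.integer(dim)
  if (length(dim) != 1L || is.na(dim) || dim < 1L)
    stop("`dim` must be a single integer >= 1", call. = FALSE)
  extent <- rep_len(as.numeric(extent), dim)
  if (any(!is.finite(extent)) || any(extent <= 0))
    stop("all `extent` entries must be positive and finite", call. = FALSE)
  structure(list(dim = dim, extent = extent, measure = prod(extent)),
            class = "nf_domain")
}

#' @export
print.nf_domain <- function(x, ...) {
  cat("<nf_domain> d =", x$dim, " extent = [",
      paste(format(x$extent), collapse = ", "),
      "] |D| =", format(x$measure), "\n")
  invisible(x)
}

#' Uniform cube partition of a domain
#'
#' Tiles the domain with `n` congruent boxes per axis (`n^d` cells in
#' total), each holding one neuron population. Cells are ordered
#' lexicographically in the 0-based grid index, the first axis moving
#' fastest. Cells are half-open on each axis except the last cell, so that
#' every point of the domain belongs to exactly one cell.
#'
#' @param dom an [domain()] object.
#' @param n number of cells per axis, integer >= 1.
#' @param pop_size population sizes l(k): a single integer, a vector of
#'   length `n^d`, or a function of the 1-based cell index.
#' @return an object of class `nf_partition` with matrices `lower`,
#'   `upper` (P x d cell corners), numeric vectors `measures`,
#'   `diameters`, integer vector `pop_sizes`, count `P`, and the `domain`.
#' @examples
#' p <- uniform_partition(domain(), 4, pop_size = 10)
#' partition_stats(p)
#' @export
uniform_partition <- function(dom, n, pop_size = 1L) {
  stopifnot(inherits(dom, "nf_domain"))
  n <- as.integer(n)
  if (length(n) != 1L || is.na(n) || n < 1L)
    stop("`n` must be a single integer >= 1", call. = FALSE)
  d <- dom$dim
  P <- as.integer(n^d)
  idx <- as.matrix(expand.grid(rep(list(0:(n - 1L)), d)))  # first axis fastest
  h <- dom$extent / n
  lower <- sweep(idx, 2, h, `*`)
  upper <- sweep(idx + 1L, 2, h, `*`)
  colnames(lower) <- colnames(upper) <- NULL
  if (is.function(pop_size)) pop_size <- vapply(seq_len(P), pop_size, numeric(1))
  pop_size <- as.integer(rep_len(pop_size, P))
  if (any(is.na(pop_size)) || any(pop_size < 1L))
    stop("population sizes must all be integers >= 1", call. = FALSE)
  structure(list(
    domain = dom,
    lower = lower, upper = upper,
    measures = rep(prod(h), P),
    diameters = rep(sqrt(sum(h^2)), P),
    pop_sizes = pop_size,
    P = P, n = n
  ), class = "nf_partition")
}

#' General partition from explicit cell corners
#'
#' Lower-level constructor used for non-uniform tilings (e.g. cells of
#' unequal length on an interval). Cells must tile the domain; interiors
#' may not overlap. Only minimal containment checks are performed.
#'
#' @param dom an [domain()] object.
#' @param lower,upper P x d matrices of cell corners.
#' @param pop_size population sizes as in [uniform_partition()].
#' @return an `nf_partition`.
#' @export
partition_from_cells <- function(dom, lower, upper, pop_size = 1L) {
  stopifnot(inherits(dom, "nf_domain"))
  lower <- as.matrix(lower); upper <- as.matrix(upper)
  if (!all(dim(lower) == dim(upper)) || ncol(lower) != dom$dim)
    stop("`lower`/`upper` must be P x d matrices", call. = FALSE)
  if (nrow(lower) < 1L) stop("empty partition", call. = FALSE)
  if (any(upper <= lower)) stop("cells must have positive extent", call. = FALSE)
  if (any(lower < -1e-12) || any(sweep(upper, 2, dom$extent) > 1e-12))
    stop("cells must lie inside the domain", call. = FALSE)
  P <- nrow(lower)
  if (is.function(pop_size)) pop_size <- vapply(seq_len(P), pop_size, numeric(1))
  pop_size <- as.integer(rep_len(pop_size, P))
  if (any(is.na(pop_size)) || any(pop_size < 1L))
    stop("population sizes must all be integers >= 1", call. = FALSE)
  edges <- upper - lower
  structure(list(
    domain = dom, lower = lower, upper = upper,
    measures = apply(edges, 1, prod),
    diameters = sqrt(rowSums(edges^2)),
    pop_sizes = pop_size, P = P, n = NA_integer_
  ), class = "nf_partition")
}

#' @export
print.nf_partition <- function(x, ...) {
  s <- partition_stats(x)
  cat("<nf_partition> P =", x$P, "cells on d =", x$domain$dim,
      "domain\n  v- =", format(s$v_minus), " v+ =", format(s$v_plus),
      " delta+ =", format(s$delta_plus),
      " l- =", s$ell_minus, " l+ =", s$ell_plus, "\n")
  invisible(x)
}

#' Scalar partition statistics
#'
#' The quantities that drive every convergence rate in the limit theorems:
#' extreme cell measures v-(n), v+(n), the maximum cell diameter
#' delta+(n), and the extreme population sizes l-(n), l+(n).
#'
#' @param p an `nf_partition`.
#' @return an object of class `nf_partition_stats`: a list with
#'   `v_minus`, `v_plus`, `delta_plus`, `ell_minus`, `ell_plus`.
#' @export
partition_stats <- function(p) {
  stopifnot(inherits(p, "nf_partition"))
  if (p$P < 1L) stop("empty partition", call. = FALSE)
  structure(list(
    v_minus = min(p$measures), v_plus = max(p$measures),
    delta_plus = max(p$diameters),
    ell_minus = min(p$pop_sizes), ell_plus = max(p$pop_sizes)
  ), class = "nf_partition_stats")
}

#' @export
print.nf_partition_stats <- function(x, ...) {
  cat("<nf_partition_stats> v- =", format(x$v_minus),
      "v+ =", format(x$v_plus), "delta+ =", format(x$delta_plus),
      "l- =", x$ell_minus, "l+ =", x$ell_plus, "\n")
  invisible(x)
}

# Gauss-Legendre nodes/weights on [a, b]; Golub-Welsch via symmetric
# tridiagonal eigen-decomposition. Exact for polynomials of degree 2q-1.
gauss_legendre <- function(q, a = -1, b = 1) {
  q <- as.integer(q)
  stopifnot(q >= 1L)
  if (q == 1L) {
    x <- 0; w <- 2
  } else {
    i <- seq_len(q - 1L)
    beta <- i / sqrt(4 * i^2 - 1)
    J <- matrix(0, q, q)
    J[cbind(i, i + 1L)] <- beta
    J[cbind(i + 1L, i)] <- beta
    e <- eigen(J, symmetric = TRUE)
    x <- rev(e$values)
    w <- 2 * rev(e$vectors[1, ])^2
  }
  list(nodes = (b - a) / 2 * x + (a + b) / 2, weights = (b - a) / 2 * w)
}

# Tensor-product Gauss-Legendre rule over a box given by corner vectors.
# Returns nodes as a matrix (points x d) and a weight vector.
tensor_gauss <- function(lower, upper, q) {
  d <- length(lower)
  rules <- lapply(seq_len(d), function(i) gauss_legendre(q, lower[i], upper[i]))
  nodes <- as.matrix(expand.grid(lapply(rules, `[[`, "nodes")))
  colnames(nodes) <- NULL
  wlist <- expand.grid(lapply(rules, `[[`, "weights"))
  list(nodes = nodes, weights = Reduce(`*`, wlist))
}

#' Cell average of a scalar field
#'
#' Computes \eqn{|B|^{-1} \int_B f(x)\,dx} over a box B by tensor-product
#' Gauss-Legendre quadrature; exact for polynomials up to degree
#' `2 * quad_order - 1` per axis, so affine fields average to their value
#' at the centroid.
#'
#' @param fn scalar field; called with a matrix of points (rows = points)
#'   for d > 1, or a numeric vector for d = 1; must return a numeric
#'   vector.
#' @param lower,upper numeric vectors: the box corners.
#' @param quad_order Gauss-Legendre order per axis (default 6).
#' @return the scalar mean value of `fn` over the box.
#' @examples
#' cell_average(function(x) x^2, 0, 1)  # 1/3
#' @export
cell_average <- function(fn, lower, upper, quad_order = 6) {
  g <- tensor_gauss(as.numeric(lower), as.numeric(upper), quad_order)
  x <- if (ncol(g$nodes) == 1L) g$nodes[, 1] else g$nodes
  v <- fn(x)
  if (any(!is.finite(v)))
    stop("`fn` produced non-finite values on the cell", call. = FALSE)
  sum(g$weights * v) / prod(upper - lower)
}

#' Serialize a partition to JSON
#'
#' @param p an `nf_partition`.
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @return invisibly, the JSON string.
#' @export
partition_to_json <- function(p, path = NULL) {
  stopifnot(inherits(p, "nf_partition"))
  obj <- list(dim = p$domain$dim, extent = p$domain$extent,
              lower = p$lower, upper = p$upper,
              measures = p$measures, pop_sizes = p$pop_sizes)
  js <- jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE)
  if (!is.null(path)) writeLines(js, path)
  invisible(js)
}

#' Read a partition from JSON written by [partition_to_json()]
#' @param path file path or JSON string.
#' @return an `nf_partition`.
#' @export
partition_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  dom <- domain(obj$dim, obj$extent)
  partition_from_cells(dom, obj$lower, obj$upper, obj$pop_sizes)
}
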