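#' Piecewise-constant field on a partition
#'
#' An element of \eqn{L^2(D)} that is constant on each cell of a
#' partition. This is the image of the coordinate map: the state of the
#' jump process embeds into \eqn{L^2(D)} as the piecewise-constant field
#' of active fractions per cell.
#'
#' @param partition an `nf_partition`.
#' @param coef numeric vector of per-cell values (length P).
#' @return an object of classes `nf_piecewise_field`, `nf_field`.
#' @export
piecewise_field <- function(partition, coef) {
  stopifnot(inherits(partition, "nf_partition"))
  coef <- as.numeric(coef)
  if (length(coef) != partition$P)
    stop("`coef` must have one value per cell", call. = FALSE)
  if (any(!is.finite(coef)))
    stop("field coefficients must be finite", call. = FALSE)
  structure(list(partition = partition, coef = coef),
            class = c("nf_piecewise_field", "nf_field"))
}

#' Field sampled on a quadrature grid
#'
#' An \eqn{L^2(D)} element represented by its values at quadrature nodes
#' together with the quadrature weights; integrals against it are computed
#' as weighted sums. This is the representation used by the deterministic
#' solver.
#'
#' @param nodes matrix of node coordinates (points x d), or a numeric
#'   vector for d = 1.
#' @param weights quadrature weights, one per node.
#' @param values field values at the nodes.
#' @param dom the [domain()] the grid covers.
#' @return an object of classes `nf_grid_field`, `nf_field`.
#' @export
grid_field <- function(nodes, weights, values, dom) {
  stopifnot(inherits(dom, "nf_domain"))
  if (is.null(dim(nodes))) nodes <- matrix(nodes, ncol = 1)
  values <- as.numeric(values)
  if (nrow(nodes) != length(weights) || length(values) != length(weights))
    stop("nodes, weights and values must agree in length", call. = FALSE)
  if (any(!is.finite(values)))
    stop("field values must be finite", call. = FALSE)
  structure(list(nodes = nodes, weights = as.numeric(weights),
                 values = values, domain = dom),
            class = c("nf_grid_field", "nf_field"))
}

#' @export
print.nf_piecewise_field <- function(x, ...) {
  cat("<nf_piecewise_field> P =", x$partition$P,
      " range = [", format(min(x$coef)), ",", format(max(x$coef)), "]\n")
  invisible(x)
}

#' @export
print.nf_grid_field <- function(x, ...) {
  cat("<nf_grid_field>", nrow(x$nodes), "nodes, range = [",
      format(min(x$values)), ",", format(max(x$values)), "]\n")
  invisible(x)
}

#' Evaluate a field at points
#' @param field an `nf_field`.
#' @param x points (vector for d = 1, matrix rows otherwise).
#' @return numeric vector of field values.
#' @export
field_eval <- function(field, x) {
  UseMethod("field_eval")
}

#' @export
field_eval.nf_piecewise_field <- function(field, x) {
  p <- field$partition
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  out <- numeric(nrow(x))
  for (i in seq_len(nrow(x))) {
    xi <- x[i, ]
    inside <- which(apply(p$lower, 1, function(lo) all(xi >= lo - 1e-12)) &
                    apply(p$upper, 1, function(hi) all(xi <= hi + 1e-12)))
    # half-open convention: prefer the cell whose upper corner is strictly
    # above x unless x sits on the domain boundary
    k <- inside[1]
    for (j in inside) {
      if (all(xi < p$upper[j, ] - 1e-12) || all(p$upper[j, ] >= p$domain$extent - 1e-12)) {
        k <- j
        break
      }
    }
    out[i] <- field$coef[k]
  }
  out
}

#' @export
field_eval.nf_grid_field <- function(field, x) {
  if (ncol(field$nodes) != 1L)
    stop("field_eval on grid fields is implemented for d = 1 only", call. = FALSE)
  stats::approx(field$nodes[, 1], field$values, xout = as.numeric(x),
                rule = 2)$y
}

#' Composite Gauss-Legendre grid on a domain
#'
#' Splits each axis of the domain into `panels` equal panels and places a
#' Gauss-Legendre rule of order `q` on each; the tensor product of the
#' per-axis rules forms the grid. Such a grid integrates piecewise-smooth
#' integrands accurately and, when the panels coincide with partition
#' cells, represents piecewise-constant fields exactly.
#'
#' @param dom a [domain()].
#' @param panels panels per axis.
#' @param q Gauss-Legendre order per panel.
#' @return list with `nodes` (matrix points x d), `weights`, `domain`.
#' @export
gauss_grid <- function(dom, panels = 8, q = 6) {
  stopifnot(inherits(dom, "nf_domain"))
  axes <- lapply(seq_len(dom$dim), function(i) {
    edges <- seq(0, dom$extent[i], length.out = panels + 1)
    nodes <- numeric(0); weights <- numeric(0)
    for (j in seq_len(panels)) {
      g <- gauss_legendre(q, edges[j], edges[j + 1])
      nodes <- c(nodes, g$nodes); weights <- c(weights, g$weights)
    }
    list(nodes = nodes, weights = weights)
  })
  nodes <- as.matrix(expand.grid(lapply(axes, `[[`, "nodes")))
  colnames(nodes) <- NULL
  w <- Reduce(`*`, expand.grid(lapply(axes, `[[`, "weights")))
  list(nodes = nodes, weights = as.numeric(w), domain = dom)
}

#' Per-cell quadrature grid aligned with a partition
#'
#' Gauss-Legendre nodes of order `q` per axis inside every cell of the
#' partition, with a map from node to owning cell. Running the
#' deterministic solver on this grid makes the comparison between the
#' embedded jump process and the macroscopic solution exact per cell.
#'
#' @param p an `nf_partition`.
#' @param q Gauss-Legendre order per axis and cell.
#' @return list with `nodes`, `weights`, `cell` (1-based owning cell per
#'   node), `domain`.
#' @export
partition_grid <- function(p, q = 4) {
  stopifnot(inherits(p, "nf_partition"))
  nodes <- NULL; weights <- numeric(0); cell <- integer(0)
  for (k in seq_len(p$P)) {
    g <- tensor_gauss(p$lower[k, ], p$upper[k, ], q)
    nodes <- rbind(nodes, g$nodes)
    weights <- c(weights, g$weights)
    cell <- c(cell, rep.int(k, length(g$weights)))
  }
  list(nodes = nodes, weights = weights, cell = cell, domain = p$domain)
}
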