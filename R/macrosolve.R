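# Deterministic solvers for the Wilson-Cowan equation
#   tau nu_t = -nu + f( int_D w(x,y) nu(t,y) dy + I(t,x) )
# and for the bounded-state-space limit equation
#   tau nu_t = -nu + (1 - nu) f( ... ).
#
# Method of lines on a fixed quadrature grid. The default integrator is
# exponential Euler: the linear decay -nu/tau is integrated exactly (the
# variation-of-constants structure of the equation), only the gain term is
# frozen per step, so constant-gain problems are solved exactly and the
# pointwise invariant region [0, ||f||_0] is preserved step by step.

#' Solve the Wilson-Cowan equation
#'
#' @param tau decay time constant (> 0).
#' @param gain an `nf_gain`.
#' @param kernel an `nf_kernel`.
#' @param input an `nf_input`.
#' @param nu0 initial field: function of points or a single number.
#' @param T horizon (> 0).
#' @param dom the [domain()]; defaults to the unit interval.
#' @param grid optional grid (list with `nodes`, `weights`) such as
#'   [gauss_grid()] or [partition_grid()]; overrides `grid_size`.
#' @param grid_size nodes used to build a default composite
#'   Gauss-Legendre grid (panels of order 6).
#' @param dt time step (> 0); the step actually used divides T exactly.
#' @param integrator `"expeuler"` (default) or `"rk4"`.
#' @param variant `"standard"` or `"bounded"` (the `(1 - nu) f` limit of
#'   the bounded-state-space master equation).
#' @param t_out times to record (subset of the step mesh; defaults to at
#'   most 201 equispaced step times including 0 and T).
#' @return an object of class `nf_macro`: `times`, `grid`, matrix
#'   `values` (times x nodes), the model ingredients, `K` (kernel
#'   quadrature matrix) and solver metadata.
#' @export
solve_wilson_cowan <- function(tau, gain, kernel, input = input_constant(0),
                               nu0 = 0, T = 1, dom = domain(),
                               grid = NULL, grid_size = 48, dt = 1e-3,
                               integrator = c("expeuler", "rk4"),
                               variant = c("standard", "bounded"),
                               t_out = NULL) {
  stopifnot(tau > 0, T > 0, dt > 0)
  integrator <- match.arg(integrator)
  variant <- match.arg(variant)
  if (is.null(grid)) {
    panels <- max(1L, round(grid_size / 6))
    grid <- gauss_grid(dom, panels = panels, q = 6)
  }
  nodes <- grid$nodes
  if (is.null(dim(nodes))) nodes <- matrix(nodes, ncol = 1)
  x <- if (ncol(nodes) == 1) nodes[, 1] else nodes
  N <- nrow(nodes)
  K <- kernel_matrix(kernel, nodes, grid$weights)
  v <- if (is.function(nu0)) as.numeric(nu0(x)) else rep_len(nu0, N)
  if (any(!is.finite(v))) stop("non-finite initial field", call. = FALSE)

  nsteps <- max(1L, ceiling(T / dt))
  h <- T / nsteps
  step_times <- seq(0, T, length.out = nsteps + 1L)
  if (is.null(t_out)) {
    keep <- if (nsteps + 1L <= 201L) seq_len(nsteps + 1L) else
      unique(round(seq(1L, nsteps + 1L, length.out = 201L)))
  } else {
    keep <- vapply(t_out, function(tt) which.min(abs(step_times - tt)),
                   integer(1))
  }
  times <- step_times[keep]
  values <- matrix(NA_real_, length(keep), N)
  Fv <- function(vv, tt) {
    z <- as.numeric(K %*% vv) + input$fn(tt, x)
    if (any(!is.finite(z)))
      stop("quadrature produced non-finite values", call. = FALSE)
    fz <- gain$fn(z)
    if (variant == "bounded") (1 - vv) * fz else fz
  }
  rhs <- function(vv, tt) (-vv + Fv(vv, tt)) / tau
  E <- exp(-h / tau)
  ki <- 1L
  for (m in seq_len(nsteps + 1L)) {
    if (ki <= length(keep) && m == keep[ki]) {
      values[ki, ] <- v
      ki <- ki + 1L
    }
    if (m > nsteps) break
    tm <- step_times[m]
    if (integrator == "expeuler") {
      v <- E * v + (1 - E) * Fv(v, tm)
    } else {
      k1 <- rhs(v, tm)
      k2 <- rhs(v + h / 2 * k1, tm + h / 2)
      k3 <- rhs(v + h / 2 * k2, tm + h / 2)
      k4 <- rhs(v + h * k3, tm + h)
      v <- v + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
  }
  structure(list(times = times, grid = grid, values = values, tau = tau,
                 gain = gain, kernel = kernel, input = input, K = K,
                 variant = variant, integrator = integrator, dt = h,
                 domain = grid$domain),
            class = "nf_macro")
}

#' Solve the bounded-state-space limit equation
#'
#' Convenience wrapper for `solve_wilson_cowan(variant = "bounded")`:
#' `tau nu_t = -nu + (1 - nu) f(...)`, whose solution stays in `[0, 1]`
#' for initial data in `[0, 1]`.
#' @inheritParams solve_wilson_cowan
#' @param ... passed on to [solve_wilson_cowan()].
#' @export
solve_bounded_wc <- function(tau, gain, kernel, input = input_constant(0),
                             nu0 = 0, T = 1, ...) {
  solve_wilson_cowan(tau, gain, kernel, input, nu0, T,
                     variant = "bounded", ...)
}

#' @export
print.nf_macro <- function(x, ...) {
  cat("<nf_macro>", x$variant, "variant,", nrow(x$values), "times x",
      ncol(x$values), "nodes, T =", max(x$times),
      " integrator =", x$integrator, "\n")
  invisible(x)
}

#' @export
plot.nf_macro <- function(x, times = NULL, ...) {
  if (ncol(x$grid$nodes) != 1)
    stop("plotting implemented for d = 1", call. = FALSE)
  sel <- if (is.null(times)) unique(round(seq(1, length(x$times),
                                              length.out = 6))) else
    vapply(times, function(tt) which.min(abs(x$times - tt)), integer(1))
  graphics::matplot(x$grid$nodes[, 1], t(x$values[sel, , drop = FALSE]),
                    type = "l", lty = 1, xlab = "x", ylab = "nu(t, x)", ...)
  graphics::legend("topright", legend = paste0("t=", signif(x$times[sel], 3)),
                   col = seq_along(sel), lty = 1, cex = 0.7)
  invisible(x)
}

#' Extract the solution at a time as a grid field
#' @param macro an `nf_macro`.
#' @param t time; the nearest recorded time is used.
#' @return an `nf_grid_field`.
#' @export
macro_field <- function(macro, t) {
  i <- which.min(abs(macro$times - t))
  grid_field(macro$grid$nodes, macro$grid$weights, macro$values[i, ],
             macro$domain)
}

# index of the recorded time nearest t
macro_time_index <- function(macro, t) which.min(abs(macro$times - t))

# gain-term field F(nu(t), t) at recorded time index i
macro_F_values <- function(macro, i) {
  x <- if (ncol(macro$grid$nodes) == 1) macro$grid$nodes[, 1] else
    macro$grid$nodes
  z <- as.numeric(macro$K %*% macro$values[i, ]) + macro$input$fn(macro$times[i], x)
  macro$gain$fn(z)
}
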