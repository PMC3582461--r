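# Gain functions, kernels, inputs, their partition discretizations and the
# jump rates of the master equation.

new_gain <- function(fn, L, sup, kind, params) {
  structure(list(fn = fn, L = L, sup = sup, kind = kind, params = params),
            class = "nf_gain")
}

#' Gain (response) functions
#'
#' A gain function maps summed synaptic input to a non-negative activity
#' rate. All presets are bounded and globally Lipschitz, the contract the
#' limit theorems need: the declared `sup` (the supremum norm) feeds the
#' thinning majorant of the exact simulator, and the declared Lipschitz
#' constant `L` enters the Gronwall constants.
#'
#' * `gain_constant(c)`: f == c, Lipschitz constant 0.
#' * `gain_affine(beta1, beta2, c_max)`: the clipped-affine gain
#'   `min(c_max, max(0, beta1 z + beta2))`. On states where the clip is
#'   inactive the gain is exactly affine, which is what makes the moment
#'   systems close exactly.
#' * `gain_sigmoid(beta1, beta2)`: the logistic gain
#'   `1 / (1 + exp(-(beta1 z + beta2)))`, Lipschitz constant `beta1 / 4`.
#' * `gain_tanh(beta1, beta2)`: `(tanh(beta1 z + beta2) + 1) / 2`,
#'   Lipschitz constant `beta1 / 2`.
#'
#' @param c,c_max,beta1,beta2 preset parameters; `beta1 >= 0`.
#' @return an object of class `nf_gain` with fields `fn` (vectorized
#'   evaluator), `L`, `sup`, `kind`, `params`.
#' @name gains
NULL

#' @rdname gains
#' @export
gain_constant <- function(c) {
  stopifnot(is.finite(c), c >= 0)
  force(c)
  new_gain(function(z) rep_len(c, length(z)), 0, c, "constant", list(c = c))
}

#' @rdname gains
#' @export
gain_affine <- function(beta1, beta2, c_max = 1) {
  stopifnot(is.finite(beta1), is.finite(beta2), c_max > 0)
  new_gain(function(z) pmin(c_max, pmax(0, beta1 * z + beta2)),
           abs(beta1), c_max, "affine",
           list(beta1 = beta1, beta2 = beta2, c_max = c_max))
}

#' @rdname gains
#' @export
gain_sigmoid <- function(beta1, beta2 = 0) {
  stopifnot(beta1 >= 0)
  new_gain(function(z) 1 / (1 + exp(-(beta1 * z + beta2))),
           beta1 / 4, 1, "sigmoid", list(beta1 = beta1, beta2 = beta2))
}

#' @rdname gains
#' @export
gain_tanh <- function(beta1, beta2 = 0) {
  stopifnot(beta1 >= 0)
  new_gain(function(z) (tanh(beta1 * z + beta2) + 1) / 2,
           beta1 / 2, 1, "tanh", list(beta1 = beta1, beta2 = beta2))
}

#' @export
print.nf_gain <- function(x, ...) {
  cat("<nf_gain>", x$kind, " L =", format(x$L), " sup =", format(x$sup), "\n")
  invisible(x)
}

#' Validate the declared gain metadata by dense sampling
#'
#' Checks non-negativity, the declared supremum bound and the declared
#' Lipschitz constant on a dense sample of the given interval. The
#' declared metadata is trusted by the thinning majorant, so presets are
#' validated rather than estimated.
#'
#' @param gain an `nf_gain`.
#' @param interval sampling interval.
#' @param n number of sample points.
#' @return `TRUE` invisibly; errors on violation.
#' @export
validate_gain <- function(gain, interval = c(-20, 20), n = 4001) {
  z <- seq(interval[1], interval[2], length.out = n)
  v <- gain$fn(z)
  if (any(v < 0)) stop("gain takes negative values", call. = FALSE)
  if (any(v > gain$sup + 1e-12)) stop("gain exceeds declared sup norm", call. = FALSE)
  dv <- abs(diff(v)) / diff(z)[1]
  if (any(dv > gain$L + 1e-9))
    stop("gain violates declared Lipschitz constant", call. = FALSE)
  invisible(TRUE)
}

#' Connectivity kernels
#'
#' The kernel `w(x, y)` states the connectivity strength from a neuron at
#' `y` to a neuron at `x`; it must be square-integrable on `D x D`.
#' `kernel_constant` gives all-to-all coupling of strength `w0`;
#' `kernel_gaussian` the translation-invariant Gaussian profile
#' `w0 * exp(-|x - y|^2 / (2 sigma^2))`; `kernel_custom` wraps a user
#' function `f(x, y)` vectorized over paired points.
#'
#' @param w0 coupling strength.
#' @param sigma Gaussian width.
#' @param f function of two point sets (equal-length vectors for d = 1,
#'   matrices with matching rows otherwise), vectorized elementwise.
#' @return an object of class `nf_kernel` with `fn` and `kind`.
#' @name kernels
NULL

new_kernel <- function(fn, kind, params = list()) {
  structure(list(fn = fn, kind = kind, params = params), class = "nf_kernel")
}

#' @rdname kernels
#' @export
kernel_constant <- function(w0 = 1) {
  force(w0)
  new_kernel(function(x, y) {
    n <- if (is.null(dim(x))) length(x) else nrow(x)
    rep_len(w0, n)
  }, "constant", list(w0 = w0))
}

#' @rdname kernels
#' @export
kernel_gaussian <- function(w0 = 1, sigma = 0.2) {
  stopifnot(sigma > 0)
  new_kernel(function(x, y) {
    if (is.null(dim(x))) d2 <- (x - y)^2 else d2 <- rowSums((x - y)^2)
    w0 * exp(-d2 / (2 * sigma^2))
  }, "gaussian", list(w0 = w0, sigma = sigma))
}

#' @rdname kernels
#' @export
kernel_custom <- function(f) new_kernel(f, "custom")

#' L2(D x D) norm of a kernel by quadrature
#' @param kernel an `nf_kernel`.
#' @param dom a [domain()].
#' @param q quadrature nodes per axis.
#' @return scalar norm estimate.
#' @export
kernel_l2_norm <- function(kernel, dom, q = 32) {
  g <- gauss_grid(dom, panels = 4, q = ceiling(q / 4))
  N <- nrow(g$nodes)
  xi <- g$nodes[rep(seq_len(N), each = N), , drop = FALSE]
  yj <- g$nodes[rep(seq_len(N), times = N), , drop = FALSE]
  vals <- kernel$fn(if (ncol(xi) == 1) xi[, 1] else xi,
                    if (ncol(yj) == 1) yj[, 1] else yj)
  W <- matrix(vals, N, N, byrow = TRUE)
  sqrt(sum(outer(g$weights, g$weights) * W^2))
}

#' External input fields
#'
#' The input `I(t, x)` is the external drive a neuron at `x` receives at
#' time `t`. `input_constant` is constant in space and time;
#' `input_spatial` is a time-constant spatial profile;
#' `input_sine` is `base(x) + amp(x) * sin(omega t + phase)`, a smooth
#' time modulation the exact simulator handles by per-interval
#' quadrature; `input_custom` wraps an arbitrary `f(t, x)`.
#'
#' @param c constant value.
#' @param fx,base,amp spatial profiles: functions of points (vectorized),
#'   or scalars.
#' @param omega,phase temporal angular frequency and phase.
#' @param f function `f(t, x)` with scalar `t`, vectorized in `x`.
#' @return an object of class `nf_input` with `fn(t, x)`, `time_kind`
#'   (`"constant"` or `"smooth"`) and `kind`.
#' @name inputs
NULL

new_input <- function(fn, time_kind, kind, params = list()) {
  structure(list(fn = fn, time_kind = time_kind, kind = kind, params = params),
            class = "nf_input")
}

as_profile <- function(p) {
  if (is.function(p)) return(p)
  force(p)
  function(x) {
    n <- if (is.null(dim(x))) length(x) else nrow(x)
    rep_len(p, n)
  }
}

#' @rdname inputs
#' @export
input_constant <- function(c = 0) {
  force(c)
  new_input(function(t, x) {
    n <- if (is.null(dim(x))) length(x) else nrow(x)
    rep_len(c, n)
  }, "constant", "constant", list(c = c))
}

#' @rdname inputs
#' @export
input_spatial <- function(fx) {
  fx <- as_profile(fx)
  new_input(function(t, x) fx(x), "constant", "spatial")
}

#' @rdname inputs
#' @export
input_sine <- function(base = 0, amp = 0, omega = 1, phase = 0) {
  basef <- as_profile(base); ampf <- as_profile(amp)
  new_input(function(t, x) basef(x) + ampf(x) * sin(omega * t + phase),
            "smooth", "sine",
            list(base = basef, amp = ampf, omega = omega, phase = phase))
}

#' @rdname inputs
#' @export
input_custom <- function(f, time_kind = "smooth") new_input(f, time_kind, "custom")

#' Discretize a kernel to population weights
#'
#' Computes the discrete weight matrix
#' \eqn{\bar W_{kj} = |D_k|^{-1} \int_{D_k} \int_{D_j} w(x,y)\,dy\,dx}
#' by tensor-product Gauss-Legendre quadrature with `quad_order` nodes
#' per axis and cell.
#'
#' @param kernel an `nf_kernel`.
#' @param p an `nf_partition`.
#' @param quad_order quadrature order per axis (default 6).
#' @return a P x P numeric matrix.
#' @export
discretize_weights <- function(kernel, p, quad_order = 6) {
  stopifnot(inherits(kernel, "nf_kernel"), inherits(p, "nf_partition"))
  g <- partition_grid(p, quad_order)
  N <- nrow(g$nodes)
  xi <- g$nodes[rep(seq_len(N), each = N), , drop = FALSE]
  yj <- g$nodes[rep(seq_len(N), times = N), , drop = FALSE]
  vals <- kernel$fn(if (ncol(xi) == 1) xi[, 1] else xi,
                    if (ncol(yj) == 1) yj[, 1] else yj)
  W <- matrix(vals, N, N, byrow = TRUE)  # W[i, j] = w(x_i, y_j)
  if (any(!is.finite(W)))
    stop("kernel quadrature produced non-finite values", call. = FALSE)
  # aggregate nodes to cells: A[i, k] = weight_i * 1{node i in cell k}
  A <- matrix(0, N, p$P)
  A[cbind(seq_len(N), g$cell)] <- g$weights
  Wbar <- t(A) %*% W %*% A / p$measures
  unname(as.matrix(Wbar))
}

#' Discretize an input field to per-population inputs
#'
#' \eqn{\bar I_k(t) = |D_k|^{-1} \int_{D_k} I(t,x)\,dx} per cell.
#'
#' @param input an `nf_input`.
#' @param p an `nf_partition`.
#' @param t time.
#' @param quad_order quadrature order per axis.
#' @return numeric vector of length P.
#' @export
discretize_input <- function(input, p, t, quad_order = 6) {
  stopifnot(inherits(input, "nf_input"), t >= 0)
  g <- partition_grid(p, quad_order)
  x <- if (ncol(g$nodes) == 1) g$nodes[, 1] else g$nodes
  v <- input$fn(t, x)
  if (any(!is.finite(v)))
    stop("input produced non-finite values", call. = FALSE)
  # partition_grid emits nodes cell-major with q^d nodes per cell
  colSums(matrix(g$weights * v, ncol = p$P)) / p$measures
}

#' Microscopic master-equation model
#'
#' Bundles a partition with the time constant, gain, discretized weights
#' and inputs: everything the jump rates of the master equation need. The
#' `rate_scheme` chooses between the standard model on the unbounded state
#' space and the bounded variant whose activation rate carries the
#' indicator `theta_k < l(k)` so that counts never exceed the population
#' size.
#'
#' @param p an `nf_partition`.
#' @param tau decay time constant (> 0).
#' @param gain an `nf_gain`.
#' @param kernel an `nf_kernel`.
#' @param input an `nf_input`.
#' @param rate_scheme `"unbounded"` (default) or `"bounded"`.
#' @param quad_order quadrature order for the discretizations.
#' @return an object of class `nf_micro_model` with `W_bar`, `input_bar`
#'   (function of t returning the per-cell input vector) and the
#'   constituent objects.
#' @export
micro_model <- function(p, tau, gain, kernel, input = input_constant(0),
                        rate_scheme = c("unbounded", "bounded"),
                        quad_order = 6) {
  stopifnot(inherits(p, "nf_partition"), tau > 0,
            inherits(gain, "nf_gain"), inherits(kernel, "nf_kernel"),
            inherits(input, "nf_input"))
  rate_scheme <- match.arg(rate_scheme)
  W_bar <- discretize_weights(kernel, p, quad_order)
  if (input$time_kind == "constant") {
    ibar0 <- discretize_input(input, p, 0, quad_order)
    input_bar <- function(t) ibar0
    input_desc <- list(kind = "constant", base = ibar0)
  } else if (input$kind == "sine") {
    base <- discretize_profile(input$params$base, p, quad_order)
    amp <- discretize_profile(input$params$amp, p, quad_order)
    omega <- input$params$omega; phase <- input$params$phase
    input_bar <- function(t) base + amp * sin(omega * t + phase)
    input_desc <- list(kind = "sine", base = base, amp = amp,
                       omega = omega, phase = phase)
  } else {
    input_bar <- function(t) discretize_input(input, p, t, quad_order)
    input_desc <- list(kind = "general")
  }
  structure(list(partition = p, tau = tau, gain = gain, kernel = kernel,
                 input = input, W_bar = W_bar, input_bar = input_bar,
                 input_desc = input_desc, rate_scheme = rate_scheme,
                 quad_order = quad_order),
            class = "nf_micro_model")
}

discretize_profile <- function(fx, p, quad_order) {
  discretize_input(input_spatial(fx), p, 0, quad_order)
}

#' @export
print.nf_micro_model <- function(x, ...) {
  cat("<nf_micro_model> P =", x$partition$P, " tau =", x$tau,
      " gain =", x$gain$kind, " scheme =", x$rate_scheme, "\n")
  invisible(x)
}

check_state <- function(m, theta) {
  theta <- as.numeric(theta)
  if (length(theta) != m$partition$P)
    stop("state length must equal the number of populations", call. = FALSE)
  if (any(theta < 0) || any(theta != floor(theta)))
    stop("state counts must be non-negative integers", call. = FALSE)
  theta
}

#' Per-population activation rates
#'
#' The rate of the event `theta_k -> theta_k + 1`:
#' `l(k)/tau * f(sum_j Wbar_kj theta_j / l(j) + Ibar_k(t))`, multiplied
#' under the bounded scheme by the indicator `theta_k < l(k)`.
#'
#' @param m an `nf_micro_model`.
#' @param theta integer state vector.
#' @param t time.
#' @return numeric vector of length P (all rates); see
#'   [activation_rate()] for a single population.
#' @export
activation_rates <- function(m, theta, t = 0) {
  theta <- check_state(m, theta)
  l <- m$partition$pop_sizes
  z <- as.numeric(m$W_bar %*% (theta / l)) + m$input_bar(t)
  r <- l / m$tau * m$gain$fn(z)
  if (m$rate_scheme == "bounded") r <- r * (theta < l)
  r
}

#' @rdname activation_rates
#' @param k population index (1-based).
#' @export
activation_rate <- function(m, theta, t = 0, k) {
  activation_rates(m, theta, t)[k]
}

#' Total instantaneous jump rate
#'
#' `lambda(theta, t) = sum_k theta_k / tau + sum_k activation_rate(k)`;
#' zero exactly when no event can occur (absorption).
#'
#' @inheritParams activation_rates
#' @return scalar rate.
#' @export
total_rate <- function(m, theta, t = 0) {
  theta <- check_state(m, theta)
  sum(theta) / m$tau + sum(activation_rates(m, theta, t))
}

#' Post-jump event distribution
#'
#' The discrete distribution over the 2P events `(k, -1)` (deactivation,
#' probability `theta_k / (tau lambda)`) and `(k, +1)` (activation,
#' probability `activation_rate(k) / lambda`). Events are ordered all
#' deaths by k, then all births by k.
#'
#' @inheritParams activation_rates
#' @return a data.frame with columns `cell`, `delta` (-1/+1), `prob`.
#' @export
transition_probabilities <- function(m, theta, t = 0) {
  theta <- check_state(m, theta)
  act <- activation_rates(m, theta, t)
  lam <- sum(theta) / m$tau + sum(act)
  if (lam <= 0)
    stop("total rate is zero: no event possible (absorbing state)",
         call. = FALSE)
  P <- m$partition$P
  data.frame(cell = rep(seq_len(P), 2L),
             delta = rep(c(-1L, 1L), each = P),
             prob = c(theta / m$tau, act) / lam)
}

#' Thinning majorant of the total rate
#'
#' `tau^{-1} (sum_k theta_k + ||f||_0 sum_k l(k))`, an upper bound for
#' the total rate at every time, used to propose candidate jump times.
#'
#' @inheritParams activation_rates
#' @return scalar majorant.
#' @export
rate_majorant <- function(m, theta) {
  theta <- check_state(m, theta)
  (sum(theta) + m$gain$sup * sum(m$partition$pop_sizes)) / m$tau
}

#' Kernel quadrature matrix on a grid
#'
#' Matrix `K` with `K[i, j] = w(x_i, x_j) omega_j` so that `K %*% v`
#' approximates `int w(x_i, y) v(y) dy`.
#'
#' @param kernel an `nf_kernel`.
#' @param nodes grid nodes (matrix points x d or vector).
#' @param weights quadrature weights.
#' @return N x N matrix.
#' @export
kernel_matrix <- function(kernel, nodes, weights) {
  if (is.null(dim(nodes))) nodes <- matrix(nodes, ncol = 1)
  N <- nrow(nodes)
  xi <- nodes[rep(seq_len(N), each = N), , drop = FALSE]
  yj <- nodes[rep(seq_len(N), times = N), , drop = FALSE]
  vals <- kernel$fn(if (ncol(xi) == 1) xi[, 1] else xi,
                    if (ncol(yj) == 1) yj[, 1] else yj)
  W <- matrix(vals, N, N, byrow = TRUE)
  if (any(!is.finite(W)))
    stop("kernel evaluation produced non-finite values", call. = FALSE)
  sweep(W, 2, weights, `*`)
}

#' Nemytzkii operator of the mean-field equation
#'
#' `(F g)(x) = f( int_D w(x, y) g(y) dy + I(t, x) )` evaluated at the
#' grid nodes of `g`. Lipschitz in `g` with constant `L ||w||_{L2 x L2}`.
#'
#' @param gain an `nf_gain`.
#' @param kernel an `nf_kernel`.
#' @param input an `nf_input`.
#' @param g an `nf_grid_field`.
#' @param t time.
#' @return an `nf_grid_field` on the same grid.
#' @export
nemytzkii_F <- function(gain, kernel, input, g, t = 0) {
  stopifnot(inherits(g, "nf_grid_field"))
  K <- kernel_matrix(kernel, g$nodes, g$weights)
  x <- if (ncol(g$nodes) == 1) g$nodes[, 1] else g$nodes
  z <- as.numeric(K %*% g$values) + input$fn(t, x)
  if (any(!is.finite(z)))
    stop("quadrature produced non-finite synaptic input", call. = FALSE)
  grid_field(g$nodes, g$weights, gain$fn(z), g$domain)
}

#' Discrete Nemytzkii operator
#'
#' The piecewise-constant field of per-cell gains
#' `sum_k fbar_k(theta, t) 1_{D_k}`: the drift the embedded jump process
#' feels, up to the linear decay.
#'
#' @inheritParams activation_rates
#' @return an `nf_piecewise_field`.
#' @export
discrete_nemytzkii <- function(m, theta, t = 0) {
  theta <- check_state(m, theta)
  l <- m$partition$pop_sizes
  z <- as.numeric(m$W_bar %*% (theta / l)) + m$input_bar(t)
  piecewise_field(m$partition, m$gain$fn(z))
}
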