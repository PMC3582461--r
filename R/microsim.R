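# Exact simulation of the space-time jump process (Theta_t, t), the
# coordinate map into L^2(D), and initial-condition construction.

#' Initial state matching a target activity field
#'
#' For each cell, the integer count in `0..l(k)` whose active fraction is
#' nearest to the cell average of `nu0`, ties broken toward the smaller
#' count. The embedded initial field then converges to `nu0` in L2 as the
#' partition is refined.
#'
#' @param p an `nf_partition`.
#' @param nu0 scalar field on the domain (function of points, vectorized)
#'   or a single number.
#' @param quad_order quadrature order for the cell averages.
#' @return integer vector of initial counts, length P.
#' @export
make_initial_state <- function(p, nu0, quad_order = 6) {
  stopifnot(inherits(p, "nf_partition"))
  if (!is.function(nu0)) {
    v0 <- nu0
    nu0 <- function(x) {
      n <- if (is.null(dim(x))) length(x) else nrow(x)
      rep_len(v0, n)
    }
  }
  vapply(seq_len(p$P), function(k) {
    a <- cell_average(nu0, p$lower[k, ], p$upper[k, ], quad_order)
    l <- p$pop_sizes[k]
    i <- ceiling(l * a - 0.5)  # nearest multiple of 1/l, ties to smaller
    max(0L, min(l, as.integer(i)))
  }, integer(1))
}

#' Coordinate map: embed a state into L2(D)
#'
#' \eqn{\nu^n(\theta) = \sum_k (\theta_k / l(k)) 1_{D_k}}: the
#' piecewise-constant field of active fractions.
#'
#' @param p an `nf_partition`.
#' @param theta integer count vector.
#' @return an `nf_piecewise_field`.
#' @export
embed_state <- function(p, theta) {
  theta <- as.numeric(theta)
  if (length(theta) != p$P)
    stop("state length must equal the number of cells", call. = FALSE)
  if (any(theta < 0)) stop("counts must be non-negative", call. = FALSE)
  piecewise_field(p, theta / p$pop_sizes)
}

gain_descriptor <- function(gain) {
  switch(gain$kind,
    constant = list(kind = 0L, par = c(gain$params$c, 0, 0)),
    affine = list(kind = 1L, par = c(gain$params$beta1, gain$params$beta2,
                                     gain$params$c_max)),
    sigmoid = list(kind = 2L, par = c(gain$params$beta1, gain$params$beta2, 0)),
    tanh = list(kind = 3L, par = c(gain$params$beta1, gain$params$beta2, 0)),
    NULL)
}

#' Simulate the jump process exactly
#'
#' Samples one path of the inhomogeneous continuous-time Markov chain on
#' `[0, T]` by thinning: candidate times are proposed from the majorant
#' rate (constant between jumps) and accepted with probability
#' true-rate / majorant, so the sample is exact, also under
#' time-dependent input. Along the way the per-cell occupation integrals
#' `A_k(t) = int_0^t theta_k ds` and effective-gain integrals
#' `B_k(t) = int_0^t fbar_k(theta_s, s) ds` are accumulated exactly
#' (6-point Gauss-Legendre per constant-state interval when the input
#' varies in time); they feed the martingale decomposition and the
#' quadratic-variation oracle.
#'
#' The compiled path covers the gain presets and constant/sinusoidal
#' inputs; `engine = "r"` runs a pure-R implementation of the identical
#' algorithm consuming the identical random-number sequence (used as a
#' cross-check and for custom gain or input closures).
#'
#' @param m an `nf_micro_model`.
#' @param init integer vector of initial counts.
#' @param T time horizon (> 0).
#' @param seed integer seed; if `NULL` the current RNG state is used.
#' @param mesh sorted vector of record times in `[0, T]`; defaults to
#'   101 equispaced points including 0 and T.
#' @param record_jumps store jump times/cells/signs (memory per jump).
#' @param engine `"auto"`, `"cpp"` or `"r"`.
#' @return an object of class `nf_trajectory`: `mesh`, matrices `counts`,
#'   `A`, `B` (P x length(mesh)), `final` counts, `n_jumps`,
#'   `n_rejected`, optional `jump_times`/`jump_cells`/`jump_deltas`,
#'   plus `model`, `init`, `T`, `seed`.
#' @export
simulate_pdmp <- function(m, init, T, seed = NULL, mesh = NULL,
                          record_jumps = FALSE,
                          engine = c("auto", "cpp", "r")) {
  stopifnot(inherits(m, "nf_micro_model"))
  engine <- match.arg(engine)
  if (!is.numeric(T) || length(T) != 1L || !is.finite(T) || T <= 0)
    stop("`T` must be a positive number", call. = FALSE)
  init <- check_state(m, init)
  if (m$rate_scheme == "bounded" && any(init > m$partition$pop_sizes))
    stop("bounded scheme: initial counts must not exceed l(k)", call. = FALSE)
  if (is.null(mesh)) mesh <- seq(0, T, length.out = 101L)
  mesh <- sort(as.numeric(mesh))
  if (any(mesh < 0) || any(mesh > T + 1e-12))
    stop("`mesh` must lie in [0, T]", call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  gd <- gain_descriptor(m$gain)
  fast <- !is.null(gd) && m$input_desc$kind %in% c("constant", "sine")
  if (engine == "cpp" && !fast)
    stop("compiled engine requires a preset gain and constant/sine input",
         call. = FALSE)
  use_cpp <- (engine == "cpp") || (engine == "auto" && fast)
  P <- m$partition$P
  if (use_cpp) {
    idesc <- m$input_desc
    base <- idesc$base
    amp <- if (idesc$kind == "sine") idesc$amp else numeric(P)
    omega <- if (idesc$kind == "sine") idesc$omega else 0
    phase <- if (idesc$kind == "sine") idesc$phase else 0
    res <- pdmp_simulate_cpp(init, as.numeric(m$partition$pop_sizes),
                             m$W_bar, m$tau, gd$kind, gd$par, m$gain$sup,
                             base, amp, omega, phase, idesc$kind == "sine",
                             T, mesh, m$rate_scheme == "bounded",
                             record_jumps)
  } else {
    res <- pdmp_simulate_r(m, init, T, mesh, record_jumps)
  }
  structure(c(res, list(mesh = mesh, model = m, init = init, T = T,
                        seed = seed, engine = if (use_cpp) "cpp" else "r")),
            class = "nf_trajectory")
}

# 6-point Gauss-Legendre on [0, 1]; identical constants to the compiled core
.glx6 <- c(0.03376524289842399, 0.16939530676686776, 0.38069040695840155,
           0.6193095930415985, 0.8306046932331322, 0.966234757101576)
.glw6 <- c(0.08566224618958517, 0.1803807865240693, 0.23395696728634552,
           0.23395696728634552, 0.1803807865240693, 0.08566224618958517)

# Pure-R reference implementation of the thinning simulator; consumes the
# same RNG draws in the same order as the compiled core.
pdmp_simulate_r <- function(m, init, T, mesh, record_jumps) {
  P <- m$partition$P
  l <- as.numeric(m$partition$pop_sizes)
  tau <- m$tau
  f0 <- m$gain$sup
  f <- m$gain$fn
  bounded <- m$rate_scheme == "bounded"
  time_dep <- m$input_desc$kind != "constant"
  ibar <- m$input_bar
  W <- m$W_bar
  theta <- as.numeric(init)
  u <- as.numeric(W %*% (theta / l))
  su <- sum(theta)
  sl <- sum(l)
  A <- B <- numeric(P)
  M <- length(mesh)
  countsM <- AM <- BM <- matrix(0, P, M)
  jt <- numeric(0); jc <- integer(0); jd <- integer(0)
  tlast <- 0; mi <- 1L
  fvals <- f(u + ibar(0))

  accumulate <- function(from, to) {
    dt <- to - from
    if (dt <= 0) return()
    A <<- A + theta * dt
    ind <- if (bounded) as.numeric(theta < l) else 1
    if (!time_dep) {
      B <<- B + fvals * ind * dt
    } else {
      for (q in 1:6) {
        s <- from + .glx6[q] * dt
        B <<- B + .glw6[q] * dt * f(u + ibar(s)) * ind
      }
    }
  }
  advance_to <- function(tnew) {
    while (mi <= M && mesh[mi] <= tnew + 1e-14) {
      accumulate(tlast, mesh[mi])
      tlast <<- mesh[mi]
      countsM[, mi] <<- theta; AM[, mi] <<- A; BM[, mi] <<- B
      mi <<- mi + 1L
    }
    if (tnew > tlast) {
      accumulate(tlast, tnew)
      tlast <<- tnew
    }
  }

  t <- 0
  n_jumps <- 0; n_rejected <- 0
  repeat {
    lambda_bar <- (su + f0 * sl) / tau
    if (lambda_bar <= 0) { advance_to(T); break }
    tc <- t + stats::rexp(1) / lambda_bar  # same arithmetic as compiled core
    if (tc >= T) { advance_to(T); break }
    advance_to(tc)
    t <- tc
    if (time_dep) fvals <- f(u + ibar(t))
    ind <- if (bounded) as.numeric(theta < l) else 1
    birth_w <- l * fvals * ind
    wsum <- su + sum(birth_w)
    u1 <- stats::runif(1)
    if (u1 * (su + f0 * sl) > wsum) { n_rejected <- n_rejected + 1; next }
    r <- stats::runif(1) * wsum
    cum <- cumsum(c(theta, birth_w))
    ev <- which(r <= cum + 1e-300)[1]
    if (is.na(ev)) ev <- 2L * P
    if (ev <= P) { cell <- ev; delta <- -1 } else { cell <- ev - P; delta <- 1 }
    theta[cell] <- theta[cell] + delta
    su <- su + delta
    u <- u + W[, cell] * (delta / l[cell])
    if (!time_dep) fvals <- f(u + ibar(0))
    n_jumps <- n_jumps + 1
    if (record_jumps) {
      jt <- c(jt, t); jc <- c(jc, as.integer(cell)); jd <- c(jd, as.integer(delta))
    }
  }
  out <- list(counts = countsM, A = AM, B = BM, final = theta,
              n_jumps = n_jumps, n_rejected = n_rejected)
  if (record_jumps) {
    out$jump_times <- jt; out$jump_cells <- jc; out$jump_deltas <- jd
  }
  out
}

#' @export
print.nf_trajectory <- function(x, ...) {
  cat("<nf_trajectory> P =", nrow(x$counts), " T =", x$T,
      " jumps =", x$n_jumps, " rejected =", x$n_rejected,
      " engine =", x$engine, "\n")
  invisible(x)
}

#' Replicate seed stream
#'
#' Deterministic per-replicate seed derived from a base seed, so that
#' ensembles are reproducible replicate-by-replicate.
#' @param seed base integer seed.
#' @param r replicate index (1-based).
#' @return integer seed below 2^31.
#' @export
replicate_seed <- function(seed, r) {
  as.integer((as.numeric(seed) * 1000003 + r) %% 2147483647)
}

#' Simulate an ensemble of independent trajectories
#'
#' Runs `reps` independent paths with per-replicate seeds from
#' [replicate_seed()]. If `reduce` is supplied it is applied to each
#' trajectory and only its value retained (memory-bounded ensembles).
#'
#' @inheritParams simulate_pdmp
#' @param reps number of replicates.
#' @param reduce optional function applied to each `nf_trajectory`.
#' @return list of trajectories or reduced values, length `reps`.
#' @export
simulate_ensemble <- function(m, init, T, reps, seed, mesh = NULL,
                              record_jumps = FALSE, reduce = NULL,
                              engine = c("auto", "cpp", "r")) {
  engine <- match.arg(engine)
  lapply(seq_len(reps), function(r) {
    sim <- simulate_pdmp(m, init, T, seed = replicate_seed(seed, r),
                         mesh = mesh, record_jumps = record_jumps,
                         engine = engine)
    if (is.null(reduce)) sim else reduce(sim)
  })
}

#' Check the mean upper bound on an ensemble
#'
#' The component means of the process satisfy
#' `E Theta_t^k <= l(k) (1 + ||f||_0)` for all t whenever the initial
#' means do not exceed l(k). Verifies the bound (plus 3 standard errors
#' of Monte Carlo slack) on an ensemble and reports the largest ratio
#' of ensemble mean to bound.
#'
#' @param m an `nf_micro_model`.
#' @param sims list of `nf_trajectory` on a common mesh (>= 100 paths).
#' @return list with `max_ratio`, `ok` and the worst (cell, time) pair.
#' @export
mean_upper_bound <- function(m, sims) {
  stopifnot(length(sims) >= 100L)
  R <- length(sims)
  counts <- vapply(sims, `[[`, sims[[1]]$counts, "counts")  # P x M x R
  mu <- apply(counts, c(1, 2), mean)
  se <- apply(counts, c(1, 2), stats::sd) / sqrt(R)
  bound <- m$partition$pop_sizes * (1 + m$gain$sup)
  ratio <- mu / bound
  ok <- all(mu <= bound + 3 * se)
  worst <- which(ratio == max(ratio), arr.ind = TRUE)[1, ]
  list(max_ratio = max(ratio), ok = ok,
       cell = unname(worst[1]), mesh_index = unname(worst[2]))
}
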