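test_that("constant gain is solved to the closed form", {
  # nu(t,x) = c + (nu0 - c) e^{-t/tau}
  mac <- solve_wilson_cowan(2, gain_constant(0.5), kernel_gaussian(),
                            nu0 = 0.1, T = 1, dt = 1e-3)
  exact <- 0.5 + (0.1 - 0.5) * exp(-mac$times / 2)
  expect_lt(max(abs(sweep(mac$values, 1, exact))), 1e-8)

  # fixed point: nu0 == c stays put
  mac2 <- solve_wilson_cowan(1, gain_constant(0.3), kernel_constant(1),
                             nu0 = 0.3, T = 2, dt = 1e-2)
  expect_lt(max(abs(mac2$values - 0.3)), 1e-12)
})

test_that("zero kernel decouples into per-node ODEs solved by deSolve", {
  gain <- gain_sigmoid(3, -1)
  inp <- input_spatial(function(x) x)
  mac <- solve_wilson_cowan(0.8, gain, kernel_constant(0), inp,
                            nu0 = function(x) 0.2 + 0.3 * x, T = 1.5,
                            grid_size = 12, dt = 1e-3, integrator = "rk4")
  x <- mac$grid$nodes[, 1]
  for (i in c(1, 5, 9)) {
    ode <- deSolve::ode(y = c(v = 0.2 + 0.3 * x[i]),
                        times = c(0, 1.5),
                        func = function(t, y, parms)
                          list((-y + gain$fn(x[i])) / 0.8),
                        rtol = 1e-10, atol = 1e-12)
    expect_lt(abs(mac$values[nrow(mac$values), i] - ode[2, "v"]), 1e-6)
  }
})

test_that("affine gain matches the matrix-exponential linear solution", {
  # on the grid the RK4 solution of the affine system should match
  # expm of the frozen linear operator to high accuracy
  b1 <- 0.4; b2 <- 0.3; tau <- 1
  mac <- solve_wilson_cowan(tau, gain_affine(b1, b2, 1), kernel_constant(0.5),
                            nu0 = function(x) 0.3 + 0.2 * cos(pi * x),
                            T = 1, grid_size = 24, dt = 1e-3,
                            integrator = "rk4")
  N <- ncol(mac$values)
  A <- (b1 * mac$K - diag(N)) / tau
  b <- rep(b2, N) / tau
  aug <- rbind(cbind(A, b), 0)
  v0 <- mac$values[1, ]
  ref <- as.numeric((Matrix::expm(aug * 1) %*% c(v0, 1))[1:N])
  expect_lt(max(abs(mac$values[nrow(mac$values), ] - ref)), 1e-6)
})

test_that("solutions preserve the invariant region [0, ||f||_0]", {
  mac <- solve_wilson_cowan(0.5, gain_sigmoid(5, -2), kernel_gaussian(1, 0.2),
                            input_constant(0.3),
                            nu0 = function(x) 0.9 * (x < 0.5), T = 3,
                            dt = 2e-3)
  expect_gte(min(mac$values), -1e-8)
  expect_lte(max(mac$values), 1 + 1e-8)
})

test_that("exponential Euler self-converges at first order", {
  run <- function(dt) solve_wilson_cowan(1, gain_sigmoid(4, -1),
                                         kernel_gaussian(1, 0.3),
                                         input_constant(0.2),
                                         nu0 = function(x) 0.5 * x,
                                         T = 1, grid_size = 12, dt = dt,
                                         t_out = 1)$values
  ref <- run(1e-4)
  e1 <- max(abs(run(4e-3) - ref))
  e2 <- max(abs(run(2e-3) - ref))
  expect_gt(e1 / e2, 1.6)  # O(dt): halving dt roughly halves the error
  expect_lt(e1 / e2, 2.6)
})

test_that("bounded-scheme equation has fixed point c / (1 + c)", {
  c0 <- 0.5
  mac <- solve_bounded_wc(0.5, gain_constant(c0), kernel_constant(1),
                          nu0 = 0.9, T = 10, dt = 1e-3, t_out = 10)
  expect_lt(max(abs(mac$values - c0 / (1 + c0))), 1e-6)

  # zero gain: pure decay from the boundary
  mac0 <- solve_bounded_wc(2, gain_constant(0), kernel_constant(1),
                           nu0 = 1, T = 1, dt = 1e-3)
  expect_lt(max(abs(sweep(mac0$values, 1, exp(-mac0$times / 2)))), 1e-8)
  # solution stays in [0, 1]
  macb <- solve_bounded_wc(1, gain_sigmoid(5, 0), kernel_gaussian(),
                           nu0 = function(x) x, T = 2, dt = 2e-3)
  expect_gte(min(macb$values), -1e-8)
  expect_lte(max(macb$values), 1 + 1e-8)
})

test_that("dependence on the initial condition obeys the Gronwall bound", {
  gain <- gain_sigmoid(4, -1); kern <- kernel_gaussian(1, 0.25); tau <- 1
  wnorm <- kernel_l2_norm(kern, domain())
  T <- 1
  s1 <- solve_wilson_cowan(tau, gain, kern, nu0 = function(x) 0.4 + 0.1 * x,
                           T = T, grid_size = 24, dt = 1e-3, t_out = T)
  s2 <- solve_wilson_cowan(tau, gain, kern,
                           nu0 = function(x) 0.4 + 0.1 * x + 0.01 * cos(pi * x),
                           T = T, grid_size = 24, dt = 1e-3, t_out = T)
  w <- s1$grid$weights
  d0 <- sqrt(sum(w * (0.01 * cos(pi * s1$grid$nodes[, 1]))^2))
  dT <- sqrt(sum(w * (s1$values[1, ] * 0 + s2$values[nrow(s2$values), ] -
                        s1$values[nrow(s1$values), ])^2))
  gronwall <- exp((gain$L * wnorm - 1) * T / tau)
  expect_lte(dT / d0, gronwall * 1.05)
})
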