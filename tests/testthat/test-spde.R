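test_that("epsilon_from_partition follows the square-root scaling", {
  p <- uniform_partition(domain(), 16, 100)
  expect_equal(epsilon_from_partition(p), 1 / 40)
  p2 <- uniform_partition(domain(), 16, 200)
  expect_equal(epsilon_from_partition(p2),
               epsilon_from_partition(p) / sqrt(2))
})

test_that("the diffusion coefficient field matches closed forms", {
  g <- fn_grid_field(function(x) rep(0.5, length(x)))
  d <- diffusion_field_g(g, 0, 1, gain_constant(0.5), kernel_constant(1),
                         input_constant(0))
  expect_equal(d$values, rep(sqrt(1), length(d$values)))
  expect_equal(sum(d$weights * d$values^2), 2 * 0.5, tolerance = 1e-12)
  g0 <- fn_grid_field(function(x) rep(0, length(x)))
  d0 <- diffusion_field_g(g0, 0, 1, gain_constant(0), kernel_constant(1),
                          input_constant(0))
  expect_equal(d0$values, rep(0, length(d0$values)))
  expect_equal(attr(d0, "n_clipped"), 0)
})

test_that("zero noise reproduces the deterministic solver", {
  s0 <- integrate_spde(1, gain_sigmoid(5, -2), kernel_gaussian(1, 0.2),
                       input_constant(0.3),
                       nu0 = function(x) 0.2 + 0.2 * cos(pi * x),
                       epsilon = 0, T = 1, grid_size = 32, dt = 5e-3,
                       replicates = 2, seed = 1)
  expect_equal(s0$mean_values, s0$deterministic, tolerance = 1e-12)
  # and the internal deterministic path agrees with solve_wilson_cowan on
  # the same grid and step
  grid <- list(nodes = s0$nodes, weights = s0$weights, domain = domain())
  mac <- solve_wilson_cowan(1, gain_sigmoid(5, -2), kernel_gaussian(1, 0.2),
                            input_constant(0.3),
                            nu0 = function(x) 0.2 + 0.2 * cos(pi * x),
                            T = 1, grid = grid, dt = 5e-3,
                            t_out = s0$times)
  expect_lt(max(abs(s0$deterministic - mac$values)), 1e-8)
})

test_that("linear-noise variance matches the OU closed form", {
  phi <- function(x) rep(1, length(x))
  eps <- 0.1; c0 <- 0.5; tau <- 1; T <- 1
  s <- integrate_spde(tau, gain_constant(c0), kernel_constant(1),
                      nu0 = c0, epsilon = eps, T = T, grid_size = 32,
                      dt = 5e-3, replicates = 1000, seed = 11,
                      phis = list(phi))
  v <- var(s$pairings[, 1])
  vex <- eps^2 * c0 * (1 - exp(-2 * T / tau))
  se <- v * sqrt(2 / (nrow(s$pairings) - 1))
  expect_lte(abs(v - vex), 3 * se + 1e-12)
  # additive noise with affine drift: ensemble mean is unbiased
  mdet <- sum(s$weights * s$deterministic[nrow(s$deterministic), ])
  mu <- mean(s$pairings[, 1])
  expect_lte(abs(mu - mdet), 3 * sd(s$pairings[, 1]) / sqrt(1000))
})

test_that("both approximations collapse to the deterministic limit", {
  dev <- vapply(c(0.2, 0.1, 0.05), function(eps) {
    s <- integrate_spde(1, gain_sigmoid(5, -2), kernel_gaussian(1, 0.2),
                        input_constant(0.3),
                        nu0 = function(x) 0.2 + 0.2 * cos(pi * x),
                        epsilon = eps, T = 1, grid_size = 32, dt = 1e-2,
                        replicates = 150, seed = 7, variant = "langevin")
    vT <- s$mean_values[nrow(s$mean_values), ]
    dT <- s$deterministic[nrow(s$deterministic), ]
    # mean L2 distance of paths from the deterministic solution
    sqrt(sum(s$weights * (vT - dT)^2))
  }, numeric(1))
  expect_true(all(diff(dev) < 0))
})

test_that("SPDE ensembles are seed-deterministic and report clipping", {
  run <- function() integrate_spde(1, gain_constant(0.2), kernel_constant(1),
                                   nu0 = 0.2, epsilon = 0.15, T = 0.5,
                                   grid_size = 16, dt = 1e-2,
                                   replicates = 20, seed = 5,
                                   phis = list(function(x) rep(1, length(x))),
                                   variant = "langevin")
  a <- run(); b <- run()
  expect_identical(a$pairings, b$pairings)
  expect_gte(a$clip_fraction, 0)
})
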