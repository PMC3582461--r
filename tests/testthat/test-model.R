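test_that("kernel discretization reproduces closed-form double integrals", {
  p <- uniform_partition(domain(), 4, 10)
  W <- discretize_weights(kernel_constant(1), p)
  expect_equal(W, matrix(0.25, 4, 4), tolerance = 1e-12)

  # w(x,y) = x + y on cells [0, .5), [.5, 1): Wbar_11 =
  # (1/0.5) int_0^.5 int_0^.5 (x+y) dy dx = 0.25
  p2 <- uniform_partition(domain(), 2, 10)
  W2 <- discretize_weights(kernel_custom(function(x, y) x + y), p2)
  expect_equal(W2[1, 1], 0.25, tolerance = 1e-12)
  expect_equal(W2[2, 2], 0.75, tolerance = 1e-12)

  # antisymmetric kernel vanishes on the diagonal
  W3 <- discretize_weights(kernel_custom(function(x, y) x - y), p2)
  expect_equal(diag(W3), c(0, 0), tolerance = 1e-12)
})

test_that("separable kernels factorize into independent 1-D quadratures", {
  p <- uniform_partition(domain(), 3, 10)
  a <- function(x) cos(2 * x); b <- function(y) exp(y)
  W <- discretize_weights(kernel_custom(function(x, y) a(x) * b(y)), p)
  abar <- vapply(seq_len(p$P), function(k)
    cell_average(a, p$lower[k, ], p$upper[k, ]), numeric(1))
  bint <- vapply(seq_len(p$P), function(j)
    cell_average(b, p$lower[j, ], p$upper[j, ]) * p$measures[j], numeric(1))
  expect_equal(W, outer(abar, bint), tolerance = 1e-10)
})

test_that("input discretization averages the field per cell", {
  p <- uniform_partition(domain(), 2, 10)
  expect_equal(discretize_input(input_constant(3), p, 0), c(3, 3))
  expect_equal(discretize_input(input_spatial(function(x) x), p, 0),
               c(0.25, 0.75), tolerance = 1e-12)
  inp <- input_custom(function(t, x) rep(sin(t), length(x)))
  expect_equal(discretize_input(inp, p, 1.3), rep(sin(1.3), 2),
               tolerance = 1e-12)
})

test_that("jump rates match the master-equation formulas", {
  p <- uniform_partition(domain(), 2, 10)
  m <- micro_model(p, 1, gain_constant(0.5), kernel_constant(1))
  theta <- c(2, 3)
  expect_equal(activation_rates(m, theta, 0), c(5, 5))
  expect_equal(activation_rate(m, theta, 0, 2), 5)
  expect_equal(total_rate(m, theta, 0), 15)
  tp <- transition_probabilities(m, theta, 0)
  expect_equal(tp$prob, c(2, 3, 5, 5) / 15)
  expect_equal(sum(tp$prob), 1, tolerance = 1e-12)

  # zero gain, zero state: absorbing
  m0 <- micro_model(p, 1, gain_sigmoid(5, -50), kernel_constant(0))
  expect_lt(activation_rate(m0, c(0, 0), 0, 1), 1e-10)
  m00 <- micro_model(p, 1, gain_constant(0), kernel_constant(1))
  expect_equal(total_rate(m00, c(0, 0), 0), 0)
  expect_error(transition_probabilities(m00, c(0, 0), 0), "absorbing")

  # 1/tau scaling
  m2 <- micro_model(p, 2, gain_constant(0.5), kernel_constant(1))
  expect_equal(total_rate(m2, theta, 0), total_rate(m, theta, 0) / 2)

  expect_error(total_rate(m, c(-1, 0), 0), "non-negative")
})

test_that("bounded scheme truncates the activation rate at l(k)", {
  p <- uniform_partition(domain(), 2, 10)
  m <- micro_model(p, 1, gain_constant(0.5), kernel_constant(1),
                   rate_scheme = "bounded")
  r <- activation_rates(m, c(10, 3), 0)
  expect_equal(r[1], 0)
  expect_equal(r[2], 5)
})

test_that("total rate never exceeds the thinning majorant", {
  m <- sigmoid_model(n = 4, l = 20)
  set.seed(5)
  for (i in 1:20) {
    theta <- rpois(4, 10)
    t <- runif(1, 0, 3)
    expect_lte(total_rate(m, theta, t), rate_majorant(m, theta) + 1e-12)
  }
})

test_that("gain presets validate their declared metadata", {
  expect_true(validate_gain(gain_constant(0.5)))
  expect_true(validate_gain(gain_affine(0.4, 0.3, 1)))
  expect_true(validate_gain(gain_sigmoid(5, -2)))
  expect_true(validate_gain(gain_tanh(2, 0)))
})

test_that("the Nemytzkii operator is Lipschitz with constant L ||w||", {
  gain <- gain_sigmoid(5, -2)
  kern <- kernel_gaussian(1, 0.2)
  inp <- input_constant(0.3)
  wnorm <- kernel_l2_norm(kern, domain())
  set.seed(11)
  for (i in 1:10) {
    g1 <- fn_grid_field(function(x) runif(1) + runif(1) * cos(pi * x))
    g2 <- fn_grid_field(function(x) runif(1) + runif(1) * sin(2 * x))
    F1 <- nemytzkii_F(gain, kern, inp, g1)
    F2 <- nemytzkii_F(gain, kern, inp, g2)
    dF <- grid_field(g1$nodes, g1$weights, F1$values - F2$values, domain())
    dg <- grid_field(g1$nodes, g1$weights, g1$values - g2$values, domain())
    expect_lte(l2_norm(dF), gain$L * wnorm * l2_norm(dg) + 1e-10)
  }
})

test_that("constant gain collapses the Nemytzkii operator to a constant", {
  g <- fn_grid_field(function(x) sin(3 * x))
  Fg <- nemytzkii_F(gain_constant(0.7), kernel_gaussian(), input_constant(0), g)
  expect_equal(Fg$values, rep(0.7, length(g$values)))
  # zero kernel and input: F g == f(0) everywhere
  f <- gain_sigmoid(3, 1)
  F0 <- nemytzkii_F(f, kernel_constant(0), input_constant(0), g)
  expect_equal(F0$values, rep(f$fn(0), length(g$values)), tolerance = 1e-12)
})

test_that("discrete Nemytzkii converges to the continuous operator", {
  # per-cell gain field matches F(nu^n) up to O(delta_+) for smooth w, I
  dev <- vapply(c(4L, 16L), function(n) {
    m <- sigmoid_model(n = n, l = 10)
    theta <- round(seq(2, 8, length.out = n))
    fld <- discrete_nemytzkii(m, theta, 0)
    g <- partition_grid(m$partition, 6)
    gf <- grid_field(g$nodes, g$weights,
                     field_eval(embed_state(m$partition, theta), g$nodes[, 1]),
                     domain())
    Fg <- nemytzkii_F(m$gain, m$kernel, m$input, gf)
    pc_vals <- rep(fld$coef, each = 6)
    max(abs(pc_vals - Fg$values))
  }, numeric(1))
  expect_lt(dev[2], dev[1])
  expect_lt(dev[2], 0.1)
})
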