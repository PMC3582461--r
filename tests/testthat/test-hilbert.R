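test_that("L2 norms of piecewise fields are exact", {
  p1 <- uniform_partition(domain(), 1, 1)
  expect_equal(l2_norm(piecewise_field(p1, 1)), 1)
  p2 <- uniform_partition(domain(), 2, 1)
  expect_equal(l2_norm(piecewise_field(p2, c(1, -1))), 1)
  p4 <- uniform_partition(domain(), 4, 1)
  expect_equal(l2_norm(piecewise_field(p4, 1:4)), sqrt(7.5))
})

test_that("single cosine modes have the closed-form dual norms", {
  f <- fn_grid_field(function(x) cos(pi * x), panels = 16, q = 8)
  for (a in c(0, 0.5, 1, 2)) {
    expect_equal(neg_sobolev_norm(f, a, K = 16),
                 sqrt(1 / 2) * (1 + pi^2)^(-a / 2), tolerance = 1e-9)
  }
  # constants live in mode zero only: alpha-independent norm |c| sqrt(|D|)
  p <- uniform_partition(domain(), 4, 1)
  cf <- piecewise_field(p, rep(-2, 4))
  for (a in c(0, 1, 3))
    expect_equal(neg_sobolev_norm(cf, a, K = 32), 2, tolerance = 1e-12)
})

test_that("dual norms are monotone non-increasing in alpha", {
  set.seed(3)
  p <- uniform_partition(domain(), 8, 1)
  for (i in 1:5) {
    f <- piecewise_field(p, rnorm(8))
    n0 <- neg_sobolev_norm(f, 0.2, K = 128)
    n1 <- neg_sobolev_norm(f, 0.7, K = 128)
    n2 <- neg_sobolev_norm(f, 1.5, K = 128)
    expect_lte(n1, n0 + 1e-12)
    expect_lte(n2, n1 + 1e-12)
    expect_lte(n0, l2_norm(f) + 1e-12)  # projection never exceeds L2
  }
})

test_that("alpha = 0 reproduces the L2 norm of the projection", {
  p <- uniform_partition(domain(), 4, 1)
  f <- piecewise_field(p, c(0.3, -0.1, 0.5, 0.2))
  expect_equal(neg_sobolev_norm(f, 0, K = 512), l2_norm(f),
               tolerance = 1e-2)
})

test_that("doubling the mode cutoff barely moves partition-field norms", {
  p <- uniform_partition(domain(), 8, 1)
  set.seed(9)
  f <- piecewise_field(p, runif(8))
  a <- neg_sobolev_norm(f, 1, K = 256)
  b <- neg_sobolev_norm(f, 1, K = 512)
  expect_lt(abs(a - b) / a, 0.01)
})

test_that("the truncated pairing equals the L2 inner product for band-limited factors", {
  phi <- fn_grid_field(function(x) sqrt(2) * cos(3 * pi * x))
  set.seed(21)
  g <- fn_grid_field(function(x) 0.4 + 0.3 * cos(pi * x) - 0.2 * cos(5 * pi * x))
  direct <- sum(phi$weights * phi$values * g$values)
  expect_equal(spectral_pairing(phi, g, K = 64), direct, tolerance = 1e-10)
})

test_that("Poincare ratios match closed forms and respect the bound", {
  expect_equal(poincare_ratio(function(x) cos(pi * x),
                              function(x) -pi * sin(pi * x)),
               1 / pi, tolerance = 1e-10)
  expect_equal(poincare_ratio(function(x) x, function(x) rep(1, length(x))),
               sqrt(1 / 12), tolerance = 1e-10)
  expect_equal(poincare_ratio(function(x) cos(2 * pi * x),
                              function(x) -2 * pi * sin(2 * pi * x)),
               1 / (2 * pi), tolerance = 1e-10)
  expect_error(poincare_ratio(function(x) rep(1, length(x)),
                              function(x) rep(0, length(x))), "undefined")
  # no sampled smooth field beats the first nonconstant mode
  set.seed(14)
  for (i in 1:10) {
    a <- rnorm(4)
    fn <- function(x) a[1] * cos(pi * x) + a[2] * cos(2 * pi * x) +
      a[3] * sin(3 * x) + a[4] * x
    gr <- function(x) -a[1] * pi * sin(pi * x) -
      a[2] * 2 * pi * sin(2 * pi * x) + a[3] * 3 * cos(3 * x) + a[4]
    expect_lte(poincare_ratio(fn, gr), 1 / pi + 1e-6)
  }
})

test_that("indicator dual norms scale with the cell measure", {
  dom <- domain()
  # the full domain is a constant: sqrt(|D|) at every alpha
  for (a in c(0, 0.5, 2))
    expect_equal(indicator_dual_norm(0, 1, dom, a, K = 64), 1,
                 tolerance = 1e-12)
  # alpha = 0: sqrt(|cell|) up to spectral truncation
  expect_equal(indicator_dual_norm(0, 0.25, dom, 0, K = 1024), 0.5,
               tolerance = 1e-3)
  # scaling across a refining family: ||1_cell||^2 / (|cell| v_+^{2a})
  # stays bounded (d = 1, alpha = 0.25)
  a <- 0.25
  ratios <- vapply(c(4L, 8L, 16L, 32L), function(n) {
    v <- 1 / n
    indicator_dual_norm(0, v, dom, a, K = 512)^2 / (v * v^(2 * a))
  }, numeric(1))
  expect_lt(max(ratios) / min(ratios), 5)
  expect_lt(max(ratios), 5)
})

test_that("underresolved partition fields are flagged", {
  p <- uniform_partition(domain(), 32, 1)
  f <- piecewise_field(p, rep(1, 32))
  expect_warning(neg_sobolev_norm(f, 1, K = 16), "underresolved")
})

test_that("spectral modes are L2-orthonormal and alpha-rescaled", {
  dom <- domain()
  g <- gauss_grid(dom, 16, 8)
  for (k in 0:3) {
    phi <- spectral_mode(dom, k)
    expect_equal(sum(g$weights * phi(g$nodes[, 1])^2), 1, tolerance = 1e-12)
  }
  phi0 <- spectral_mode(dom, 2)
  phia <- spectral_mode(dom, 2, alpha = 1.5)
  sc <- (1 + (2 * pi)^2)^(-0.75)
  expect_equal(phia(0.3), sc * phi0(0.3), tolerance = 1e-12)
})

test_that("dual norms extend to two-dimensional fields", {
  dom2 <- domain(2L)
  p <- uniform_partition(dom2, 2, 1)
  cf <- piecewise_field(p, rep(3, 4))
  # constants occupy mode (0,0) only: alpha-independent norm |c| sqrt(|D|)
  for (a in c(0, 1))
    expect_equal(neg_sobolev_norm(cf, a, K = 16), 3, tolerance = 1e-12)
  f <- piecewise_field(p, c(1, -1, -1, 1))
  expect_lte(neg_sobolev_norm(f, 1, K = 32), neg_sobolev_norm(f, 0.5, K = 32))
  expect_lte(neg_sobolev_norm(f, 0.5, K = 32), l2_norm(f) + 1e-12)
})
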