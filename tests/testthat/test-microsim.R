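test_that("initial states pick the nearest representable fraction", {
  p <- uniform_partition(domain(), 4, 10)
  expect_equal(make_initial_state(p, 0), rep(0L, 4))
  expect_equal(make_initial_state(p, 0.5), rep(5L, 4))
  # |0.2 - 0.24| < |0.3 - 0.24|: ties and rounding go to the closer, then
  # smaller count
  expect_equal(make_initial_state(p, 0.24), rep(2L, 4))
  expect_equal(make_initial_state(p, function(x) pmin(1, pmax(0, x))),
               c(1L, 4L, 6L, 9L))
})

test_that("the coordinate map embeds counts as active fractions", {
  p <- uniform_partition(domain(), 4, 10)
  expect_equal(embed_state(p, rep(0, 4))$coef, rep(0, 4))
  expect_equal(embed_state(p, p$pop_sizes)$coef, rep(1, 4))
  f <- embed_state(p, rep(3, 4))
  expect_equal(l2_norm(f)^2, 0.3^2 * 1, tolerance = 1e-12)
  expect_error(embed_state(p, rep(1, 3)), "length")
})

test_that("compiled and reference simulators are draw-for-draw identical", {
  # constant input
  m <- sigmoid_model(n = 3, l = 15)
  s1 <- simulate_pdmp(m, c(3, 4, 5), 2, seed = 42, record_jumps = TRUE)
  s2 <- simulate_pdmp(m, c(3, 4, 5), 2, seed = 42, record_jumps = TRUE,
                      engine = "r")
  expect_equal(s1$engine, "cpp")
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$jump_times, s2$jump_times)
  expect_identical(s1$jump_cells, s2$jump_cells)
  expect_equal(s1$A, s2$A, tolerance = 1e-13)
  expect_equal(s1$B, s2$B, tolerance = 1e-13)

  # time-dependent input exercises the per-interval quadrature
  mt <- sigmoid_model(n = 2, l = 12,
                      input = input_sine(base = 0.3, amp = 0.4, omega = 3))
  t1 <- simulate_pdmp(mt, c(2, 2), 1.5, seed = 9, record_jumps = TRUE)
  t2 <- simulate_pdmp(mt, c(2, 2), 1.5, seed = 9, record_jumps = TRUE,
                      engine = "r")
  expect_identical(t1$counts, t2$counts)
  expect_identical(t1$jump_times, t2$jump_times)
  expect_equal(t1$B, t2$B, tolerance = 1e-12)

  # bounded scheme too
  mb <- sigmoid_model(n = 2, l = 8, rate_scheme = "bounded")
  b1 <- simulate_pdmp(mb, c(8, 0), 1, seed = 3, record_jumps = TRUE)
  b2 <- simulate_pdmp(mb, c(8, 0), 1, seed = 3, record_jumps = TRUE,
                      engine = "r")
  expect_identical(b1$counts, b2$counts)
})

test_that("seed determinism gives bitwise-identical trajectories", {
  m <- sigmoid_model(n = 2, l = 20)
  a <- simulate_pdmp(m, c(5, 5), 1, seed = 123, record_jumps = TRUE)
  b <- simulate_pdmp(m, c(5, 5), 1, seed = 123, record_jumps = TRUE)
  expect_identical(a$jump_times, b$jump_times)
  expect_identical(a$counts, b$counts)
  expect_true(replicate_seed(1, 1) < 2^31)
  expect_identical(replicate_seed(77, 3), replicate_seed(77, 3))
})

test_that("pure death decays like the exponential closed form", {
  p <- uniform_partition(domain(), 1, 40)
  m <- micro_model(p, 1, gain_constant(0), kernel_constant(1))
  mesh <- c(0.5, 1, 2)
  R <- 400
  cnt <- vapply(seq_len(R), function(r)
    simulate_pdmp(m, 30L, 2, seed = replicate_seed(17, r),
                  mesh = mesh)$counts[1, ], numeric(3))
  mu <- rowMeans(cnt)
  se <- apply(cnt, 1, sd) / sqrt(R)
  expect_true(all(abs(mu - 30 * exp(-mesh)) <= 3 * se + 1e-9))
})

test_that("constant gain makes thinning rejection-free", {
  m <- id_model(l = 30, c = 0.5)
  s <- simulate_pdmp(m, 10L, 5, seed = 2)
  expect_gt(s$n_jumps, 0)
  expect_equal(s$n_rejected, 0)
})

test_that("first waiting times are exponential at the initial total rate", {
  # from a fixed state the first waiting time is exactly Exp(lambda(theta0))
  m <- id_model(l = 20, c = 0.5)
  lam <- total_rate(m, 10L, 0)   # (10 + 10) / 1
  expect_equal(lam, 20)
  first <- vapply(seq_len(2000), function(r) {
    s <- simulate_pdmp(m, 10L, 2, seed = replicate_seed(31, r),
                      record_jumps = TRUE)
    s$jump_times[1]
  }, numeric(1))
  expect_gt(stats::ks.test(first, "pexp", lam)$p.value, 0.01)
})

test_that("the compensated counts are mean-zero also under smooth input", {
  m <- sigmoid_model(n = 2, l = 30,
                     input = input_sine(base = 0.2, amp = 0.5, omega = 2))
  p <- m$partition
  theta0 <- make_initial_state(p, 0.3)
  pc <- cell_pairing(p, function(x) rep(1, length(x)))
  R <- 300
  X <- vapply(seq_len(R), function(r) {
    s <- simulate_pdmp(m, theta0, 1.5, seed = replicate_seed(5, r), mesh = 1.5)
    martingale_pairing(extract_martingale(s), pc)
  }, numeric(1))
  expect_lte(abs(mean(X)), 3 * sd(X) / sqrt(R))
})

test_that("bounded-scheme counts never exceed the population size", {
  m <- sigmoid_model(n = 2, l = 6, rate_scheme = "bounded",
                     input = input_constant(3))  # strong drive
  s <- simulate_pdmp(m, c(6, 6), 3, seed = 8,
                     mesh = seq(0, 3, length.out = 200), record_jumps = TRUE)
  expect_true(all(s$counts <= 6))
  expect_true(all(s$final <= 6))
})

test_that("ensemble means respect the l(k)(1 + ||f||_0) bound", {
  m <- id_model(l = 20, c = 1)
  sims <- simulate_ensemble(m, 20L, 3, reps = 120, seed = 19,
                            mesh = seq(0, 3, length.out = 11))
  chk <- mean_upper_bound(m, sims)
  expect_true(chk$ok)
  expect_lte(chk$max_ratio, 1 + 1e-9)
})

test_that("simulation input is validated", {
  m <- id_model()
  expect_error(simulate_pdmp(m, 5L, -1, seed = 1), "positive")
  expect_error(simulate_pdmp(m, -1L, 1, seed = 1), "non-negative")
  expect_error(simulate_pdmp(m, 5L, 1, seed = 1, mesh = c(0, 2)), "0, T")
})
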