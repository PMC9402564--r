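test_that("force-length sigmoid hits midpoint, saturation and deep tail", {
  p <- af_params()
  expect_equal(af_force_law(p$l0, p), p$f0 / 2)
  expect_equal(af_force_law(1000, p), p$f0, tolerance = 1e-12)
  expect_equal(af_force_law(1, p), 1e-12 / (1 + exp(79)), tolerance = 1e-12)
  # strictly increasing until the sigmoid saturates to f0 in double precision
  f <- af_force_law(1:110, p)
  expect_true(all(diff(f) > 0))
  f_all <- af_force_law(1:500, p)
  expect_true(all(f_all > 0 & f_all <= p$f0))
  expect_error(af_force_law(0, p), ">= 1")
})

test_that("expected tension interpolates the force law", {
  p <- af_params(m = 200)
  conc <- numeric(200); conc[p$l0] <- 1
  expect_equal(af_expected_force(conc, p), p$f0 / 2)
  far <- af_params(m = 300, l0 = 10)
  u <- c(numeric(200), rep(0.01, 100))  # mass only far above l0
  expect_equal(af_expected_force(u, far), far$f0, tolerance = 1e-6)
})

test_that("formation entropy has the Shannon extremes", {
  p <- af_params(m = 100)
  expect_equal(af_formation_entropy(rep(0.01, 100), p), p$kb * p$N * log(100))
  conc <- numeric(100); conc[37] <- 1
  expect_equal(af_formation_entropy(conc, p), 0)
  expect_error(af_formation_entropy(rep(0.01, 99), p), "sum to 1")
})

test_that("Stirling form exceeds the exact small-N state count (N = 6 case)", {
  p6 <- af_params(N = 6L, m = 2L)
  sf <- af_formation_entropy(c(1 / 3, 2 / 3), p6)
  expect_equal(sf / p6$kb, -6 * ((1 / 3) * log(1 / 3) + (2 / 3) * log(2 / 3)))
  exact <- af_exact_log_states(c(2, 4))
  expect_equal(exact, log(15))
  # the Stirling gap is large at N = 6: ~3.819 vs ln 15 ~ 2.708
  expect_gt(sf / p6$kb, exact)
})

test_that("dispersion entropy is the coverage-weighted mean", {
  p1 <- af_params(m = 1)
  expect_equal(af_dispersion_entropy(1, p1), p1$kb_prime * p1$N)
  p2 <- af_params(m = 2)
  expect_equal(af_dispersion_entropy(c(0.5, 0.5), p2), p2$kb_prime * p2$N)
  pbig <- af_params(m = 1000)
  conc <- numeric(1000); conc[1000] <- 1
  expect_equal(af_dispersion_entropy(conc, pbig),
               pbig$kb_prime * pbig$N * 101 / 1000)
  # bounded by the coverage-efficiency range
  g <- af_dispersion_coefficients(10, 1000)
  u <- rep(1e-3, 1000)
  sd_u <- af_dispersion_entropy(u, pbig, g)
  expect_gte(sd_u, pbig$kb_prime * pbig$N * min(g$ratio))
  expect_lte(sd_u, pbig$kb_prime * pbig$N * max(g$ratio))
})

test_that("total entropy is the exact sum and carries the realized tension", {
  p <- af_params(m = 50)
  u <- rep(0.02, 50)
  rep_ <- af_total_entropy(u, p)
  expect_identical(rep_$S, rep_$S_f + rep_$S_d)
  expect_equal(rep_$F, af_expected_force(u, p))
  # kb' = 0 kills the dispersion term
  rep0 <- af_total_entropy(u, af_update(p, kb_ratio = 0))
  expect_identical(rep0$S_d, 0)
  expect_identical(rep0$S, rep0$S_f)
  # single class: S_f = 0, S = S_d = kb' N
  p1 <- af_params(m = 1)
  rep1 <- af_total_entropy(1, p1)
  expect_equal(rep1$S, p1$kb_prime * p1$N)
})
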