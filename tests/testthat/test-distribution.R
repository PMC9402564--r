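test_that("degenerate single class gives a point mass", {
  d <- af_stationary_distribution(af_params(m = 1))
  expect_equal(d$p, 1)
  expect_equal(d$n, af_params()$N)
})

test_that("weak-force, kb'=0 regime is indistinguishable from uniform", {
  # exponent magnitude ~ V*lam*f0/(2*T*N*kb) ~ 1e-11
  d <- af_stationary_distribution(af_params(kb_ratio = 0, m = 100))
  expect_true(all(abs(d$p - 0.01) < 1e-9))
})

test_that("normalization and positivity hold across random parameter sets", {
  set.seed(42)
  for (k in 1:25) {
    p <- random_params()
    d <- af_stationary_distribution(p)
    expect_lt(abs(sum(d$p) - 1), 1e-12)
    expect_lt(abs(sum(d$n) - p$N), p$N * 1e-12)
    expect_true(all(d$p > 0))
    expect_true(is.finite(d$log_partition))
  }
})

test_that("log partition matches a direct sum when exponents are moderate", {
  p <- af_params(kb_ratio = 4, m = 500)
  d <- af_stationary_distribution(p)
  direct <- log(sum(exp(d$exponent_dispersion + d$exponent_force)))
  expect_equal(d$log_partition, direct, tolerance = 1e-12)
  # and p reproduces the exponent form
  expect_equal(log(d$p),
               d$exponent_dispersion + d$exponent_force - d$log_partition,
               tolerance = 1e-10)
})

test_that("extreme dispersion weights cannot overflow the exponentials", {
  # max-subtraction keeps everything finite; far classes may underflow to 0
  # but never to NaN/Inf, and normalization survives
  d <- af_stationary_distribution(af_params(kb_ratio = 2000, m = 400))
  expect_true(all(is.finite(d$p)))
  expect_lt(abs(sum(d$p) - 1), 1e-12)
  expect_true(is.finite(d$log_partition))
  d2 <- af_stationary_distribution(af_params(kb_ratio = 0, f0 = 1,
                                             lam = 50, m = 400))
  expect_true(all(is.finite(d2$p)))
  expect_lt(abs(sum(d2$p) - 1), 1e-12)
})

test_that("raising the dispersion weight skews toward short filaments", {
  p1 <- af_stationary_distribution(af_params(kb_ratio = 1))$p[1]
  p10 <- af_stationary_distribution(af_params(kb_ratio = 10))$p[1]
  expect_gt(p10, p1)
})

test_that("a strong tension constraint suppresses classes above l0", {
  base <- af_params()
  long <- which(af_lengths(base) > base$l0)
  weak <- af_stationary_distribution(base)
  strong <- af_stationary_distribution(af_update(base, f0 = 1))
  expect_lt(mean(strong$p[long]), mean(weak$p[long]))
})

test_that("kb'=0 with saturating force yields two flat plateaus split at l0", {
  p <- af_params(kb_ratio = 0, f0 = 1, m = 200)
  d <- af_stationary_distribution(p)
  # 1e-6 flatness needs l_i at least ~20 classes from l0, where the
  # residual force exponent 14 * plogis(-20) ~ 3e-8 is negligible
  short <- d$p[d$lengths <= p$l0 - 20]
  long <- d$p[d$lengths >= p$l0 + 20]
  expect_lt((max(short) - min(short)) / min(short), 1e-6)
  expect_lt((max(long) - min(long)) / min(long), 1e-6)
  expect_gt(min(short), max(long))
  # plateau ratio equals the force-exponent scale V*lam*f0/(2*T*N*kb)
  scale <- p$V * p$lam * p$f0 / (2 * p$T_kelvin * p$N * p$kb)
  expect_equal(log(d$p[1] / d$p[200]), scale, tolerance = 1e-3)
})

test_that("the per-class table exposes consistent derived columns", {
  p <- af_params(kb_ratio = 4, m = 50)
  d <- af_stationary_distribution(p)
  tab <- as.data.frame(d)
  expect_identical(names(tab),
                   c("class_index", "length", "A_coeff", "force_N",
                     "exponent_dispersion", "exponent_force", "probability",
                     "monomer_count", "filament_count"))
  expect_equal(tab$monomer_count, tab$probability * p$N)
  expect_equal(tab$filament_count, tab$monomer_count / tab$length)
  expect_equal(sum(tab$probability), 1, tolerance = 1e-12)
})

test_that("step detector finds the sigmoid midpoint", {
  for (l0 in c(20, 80)) {
    d <- af_stationary_distribution(
      af_params(kb_ratio = 0, f0 = 1, l0 = l0, m = 200))
    expect_lte(abs(af_step_location(d$p) - l0), 2)
  }
})
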