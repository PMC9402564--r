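test_that("exact multinomial state counts from log-factorials", {
  expect_equal(af_exact_log_states(c(50)), 0)           # one arrangement
  expect_equal(af_exact_log_states(c(1, 1)), log(2))
  expect_equal(af_exact_log_states(c(2, 4)), log(15))
  expect_gte(af_exact_log_states(c(7, 0, 3)), 0)
  expect_error(af_exact_log_states(c(1.5, 2)), "integers")
  expect_error(af_exact_log_states(c(-1, 2)), "integers")
})

test_that("Stirling formation entropy tracks the exact count at large N", {
  # N = 1e5 over 5 classes, every class well occupied: within 1%
  n <- c(30000L, 25000L, 20000L, 15000L, 10000L)
  par <- af_params(N = sum(n), m = 5L)
  sf <- af_formation_entropy(n / sum(n), par) / par$kb
  lw <- af_exact_log_states(n)
  expect_lt(abs(sf - lw) / lw, 0.01)
})

test_that("the Stirling gap shrinks monotonically with N at fixed proportions", {
  gaps <- sapply(c(300L, 3000L, 30000L, 300000L), function(N) {
    n <- c(N / 3, 2 * N / 3)
    par <- af_params(N = N, m = 2L)
    sf <- af_formation_entropy(n / N, par) / par$kb
    lw <- af_exact_log_states(n)
    abs(sf - lw) / lw
  })
  expect_true(all(diff(gaps) < 0))
})

test_that("Lagrangian reduces to the entropy on the feasible set", {
  p <- af_params(m = 40)
  u <- rep(1 / 40, 40)
  Fu <- af_expected_force(u, p)
  expect_equal(af_lagrangian(u, alpha = 1e-18, beta = 1e-20, p, F_target = Fu),
               af_total_entropy(u, p)$S)
  expect_equal(af_lagrangian(u, 0, 0, p, F_target = 0),
               af_total_entropy(u, p)$S)
  # infeasible p pays the normalization penalty linearly in beta
  v <- rep(1 / 20, 40)  # sums to 2
  expect_equal(af_lagrangian(v, 0, 1e-20, p, F_target = 0) -
                 af_lagrangian(v, 0, 0, p, F_target = 0), -1e-20)
})

test_that("closed form is a stationary point of the Lagrangian at alpha = V*lam/(2T)", {
  p <- af_params()
  d <- af_stationary_distribution(p)
  resid <- af_stationarity_residual(d$p, p)
  expect_lt(as.numeric(resid), 1e-8 * p$kb * p$N)
  # the solved beta makes all gradient components a common constant
  expect_lt(max(abs(attr(resid, "gradient"))), 1e-8 * p$kb * p$N)
})

test_that("uniform p is not stationary when the dispersion term varies", {
  p <- af_params(kb_ratio = 10, m = 100)
  resid <- af_stationarity_residual(rep(0.01, 100), p)
  expect_gt(as.numeric(resid), 1e-3 * p$kb * p$N)
})

test_that("single-point simplex has zero residual with beta solved", {
  p <- af_params(m = 1)
  expect_equal(as.numeric(af_stationarity_residual(1, p)), 0)
})

test_that("m = 2 maximizer is pinned by the two constraints alone", {
  # with two classes the constraints determine p: p2 = (F - f1)/(f2 - f1)
  p <- af_params(m = 2L, f0 = 1, l0 = 1, kb_ratio = 4)
  f <- af_force_law(1:2, p)
  F_target <- 0.6
  p2 <- (F_target - f[1]) / (f[2] - f[1])
  orc <- af_constrained_maximize(p, F_target = F_target)
  expect_true(orc$converged)
  expect_equal(orc$p_opt, c(1 - p2, p2), tolerance = 1e-10)
})

test_that("pure Shannon regime recovers the uniform distribution", {
  p <- af_params(kb_ratio = 0, m = 40L)  # force inert at f0 = 1e-12, m << l0
  orc <- af_constrained_maximize(p)
  expect_true(orc$converged)
  expect_equal(orc$p_opt, rep(1 / 40, 40), tolerance = 1e-9)
})

test_that("Newton maximizer recovers the closed form (the oracle test)", {
  for (r in c(1, 4, 10)) {
    p <- af_params(m = 50L, kb_ratio = r)
    orc <- af_constrained_maximize(p, seed = 11L)
    pc <- af_stationary_distribution(p)$p
    expect_true(orc$converged)
    expect_lt(max(abs(orc$p_opt - pc) / pc), 1e-6)
    expect_lt(orc$max_gradient_residual, 1e-8 * p$kb * p$N)
  }
})

test_that("recovered tension multiplier equals V*lam/(2T) in a force-active regime", {
  p <- af_params(m = 50L, f0 = 1, l0 = 20)
  orc <- af_constrained_maximize(p, seed = 5L)
  alpha_true <- p$V * p$lam / (2 * p$T_kelvin)
  expect_true(orc$converged)
  expect_lt(abs(orc$alpha - alpha_true) / alpha_true, 1e-4)
  # closed form and oracle also agree here, where the force term is strong
  pc <- af_stationary_distribution(p)$p
  expect_lt(max(abs(orc$p_opt - pc) / pc), 1e-6)
})

test_that("strict concavity: ten random starts land on the same maximizer", {
  p <- af_params(m = 30L, kb_ratio = 10)
  orc <- af_constrained_maximize(p, n_starts = 10L, seed = 99L)
  expect_true(orc$converged)
  expect_lt(orc$start_spread, 1e-8)
})

test_that("oracle guards its problem size and the seed makes reruns identical", {
  expect_error(af_constrained_maximize(af_params(m = 200L)), "m <= 60")
  p <- af_params(m = 40L, kb_ratio = 6)
  a <- af_constrained_maximize(p, n_starts = 2L, seed = 123L)
  b <- af_constrained_maximize(p, n_starts = 2L, seed = 123L)
  expect_identical(a$p_opt, b$p_opt)
})

test_that("verification suite passes end to end", {
  rep_ <- af_verify(af_params(m = 300L))
  expect_true(attr(rep_, "ok"))
  expect_true(all(rep_$status == "pass"))
  expect_identical(names(rep_),
                   c("check_name", "tolerance", "observed", "status"))
})
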