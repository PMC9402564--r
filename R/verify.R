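#' Run the model verification suite
#'
#' Certifies the closed-form stationary distribution against the
#' independent variational machinery: normalization, equality of the
#' closed-form and literal-sum coverage coefficients, the `1/a` coverage
#' limit, Lagrangian stationarity at `alpha = V*lam/(2*T)`, agreement with
#' the equality-constrained Newton maximizer (probabilities and tension
#' multiplier), and Stirling-vs-exact state-count consistency.
#'
#' @param params Base `"af_params"` for the normalization/stationarity
#'   checks (the oracle comparisons truncate to `oracle_m` classes).
#' @param oracle_m Problem size for the Newton-oracle comparisons.
#' @param seed Seed for the oracle's random starts.
#' @return A `data.frame` with columns `check_name`, `tolerance`,
#'   `observed`, `status` (`"pass"`/`"fail"`), and attribute `"ok"`
#'   (logical: all passed).
#' @examples
#' \donttest{
#' af_verify(af_params(m = 300))
#' }
#' @export
af_verify <- function(params = af_params(), oracle_m = 50L, seed = 1L) {
  stopifnot(inherits(params, "af_params"))
  rows <- list()
  add <- function(name, tol, obs) {
    rows[[length(rows) + 1L]] <<- data.frame(
      check_name = name, tolerance = tol, observed = obs,
      status = if (is.finite(obs) && obs <= tol) "pass" else "fail")
  }

  d <- af_stationary_distribution(params)
  add("normalization_abs_error", 1e-12, abs(sum(d$p) - 1))

  coef_diff <- max(vapply(c(1L, 2L, 3L, 5L, 10L, 17L), function(a) {
    max(abs(af_dispersion_coefficients(a, 500L)$A -
              af_dispersion_coefficients_literal(a, 500L)$A))
  }, numeric(1)))
  add("coverage_coefficient_max_abs_diff", 0, coef_diff)

  lim <- af_dispersion_coefficients(10L, 1000L)
  add("coverage_ratio_limit_abs_dev_x_m", 2,
      1000 * abs(lim$ratio[1000] - 0.1))

  resid <- af_stationarity_residual(d$p, params)
  add("stationarity_residual_over_kbN", 1e-8,
      as.numeric(resid) / (params$kb * params$N))

  small <- af_update(params, m = oracle_m)
  orc <- af_constrained_maximize(small, n_starts = 3L, seed = seed)
  pc <- af_stationary_distribution(small)$p
  add("oracle_vs_closed_form_max_rel_error", 1e-6,
      max(abs(orc$p_opt - pc) / pc))

  forced <- af_update(params, m = oracle_m, f0 = 1, l0 = 20)
  orc_f <- af_constrained_maximize(forced, seed = seed)
  alpha_true <- params$V * params$lam / (2 * params$T_kelvin)
  add("force_multiplier_rel_error", 1e-4,
      abs(orc_f$alpha - alpha_true) / alpha_true)

  nbig <- c(30000L, 25000L, 20000L, 15000L, 10000L)
  pbig <- nbig / sum(nbig)
  par_big <- af_params(N = sum(nbig), m = length(nbig))
  sf <- af_formation_entropy(pbig, par_big) / par_big$kb
  lw <- af_exact_log_states(nbig)
  add("stirling_rel_gap", 0.01, abs(sf - lw) / lw)

  out <- do.call(rbind, rows)
  attr(out, "ok") <- all(out$status == "pass")
  out
}
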