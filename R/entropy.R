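#' Formation entropy of the monomer partition
#'
#' Stirling form of the Boltzmann entropy `kb * ln W` of distributing `N`
#' monomers over length classes, where `W` is the multinomial state count:
#' `S_f = -kb * N * sum_i p_i * ln(p_i)`. Zero-probability classes
#' contribute 0 (the `p ln p -> 0` limit). `S_f` is maximal, `kb*N*ln(m)`,
#' for the uniform distribution and zero when all monomers sit in one class.
#'
#' @param p Probability vector over length classes (must sum to 1 within
#'   1e-9).
#' @param params An `"af_params"` object supplying `kb` and `N`.
#' @return Formation entropy in J/K.
#' @seealso [af_exact_log_states()] for the exact (non-Stirling) state
#'   count used to validate this approximation.
#' @examples
#' pp <- af_params(m = 100)
#' af_formation_entropy(rep(0.01, 100), pp) / (pp$kb * pp$N)  # = ln 100
#' @export
af_formation_entropy <- function(p, params) {
  stopifnot(inherits(params, "af_params"))
  check_probability(p)
  plogp <- ifelse(p > 0, p * log(p), 0)
  -params$kb * params$N * sum(plogp)
}

#' Dispersion entropy of a filament population
#'
#' `S_d = kb' * N * sum_i (A_i / l_i) * p_i`: an entropy-like measure of
#' how many cytoplasmic compartments the population can cover, weighted by
#' the per-monomer coverage efficiency `A_i/l_i`. Short filaments disperse
#' monomers more efficiently, so `S_d` rewards short length classes.
#'
#' @inheritParams af_formation_entropy
#' @param geom An `"af_dispersion"` object; defaults to the coefficients for
#'   `params$a` and `length(p)` classes.
#' @return Dispersion entropy in J/K, bounded between `kb' * N * min(A/l)`
#'   and `kb' * N * max(A/l)`.
#' @examples
#' pp <- af_params(m = 2)
#' af_dispersion_entropy(c(0.5, 0.5), pp) / (pp$kb_prime * pp$N)
#' @export
af_dispersion_entropy <- function(p, params, geom = NULL) {
  stopifnot(inherits(params, "af_params"))
  check_probability(p)
  if (is.null(geom)) geom <- af_dispersion_coefficients(params$a, length(p))
  stopifnot(inherits(geom, "af_dispersion"), geom$m >= length(p))
  params$kb_prime * params$N * sum(geom$ratio[seq_along(p)] * p)
}

#' Overall entropy report for a length distribution
#'
#' Evaluates the two entropies and their sum `S = S_f + S_d` (the model's
#' objective function), together with the expected filament tension `F`
#' realized by `p`.
#'
#' @inheritParams af_dispersion_entropy
#' @return An object of class `"af_entropy"`: list with `S_f`, `S_d`, `S`
#'   (J/K) and `F` (newtons).
#' @examples
#' pp <- af_params(m = 50)
#' af_total_entropy(rep(1 / 50, 50), pp)
#' @export
af_total_entropy <- function(p, params, geom = NULL) {
  stopifnot(inherits(params, "af_params"))
  if (is.null(geom)) geom <- af_dispersion_coefficients(params$a, length(p))
  S_f <- af_formation_entropy(p, params)
  S_d <- af_dispersion_entropy(p, params, geom)
  structure(list(S_f = S_f, S_d = S_d, S = S_f + S_d,
                 F = af_expected_force(p, params)),
            class = "af_entropy")
}

#' @export
print.af_entropy <- function(x, ...) {
  cat("Entropy report\n")
  cat(sprintf("  S_f (formation)  : %.6g J/K\n", x$S_f))
  cat(sprintf("  S_d (dispersion) : %.6g J/K\n", x$S_d))
  cat(sprintf("  S   (total)      : %.6g J/K\n", x$S))
  cat(sprintf("  F   (tension)    : %.6g N\n", x$F))
  invisible(x)
}
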