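#' Sigmoid force-length relation of a filament
#'
#' Tension borne by a filament of length class `i`:
#' `f_i = f0 / (1 + exp(l0 - l_i))`. Filaments much shorter than `l0`
#' barely engage the actomyosin meshwork and bear almost no force; around
#' `l0` the force rises steeply (reaching `f0/2` exactly at `l_i = l0`);
#' long filaments saturate at the myosin-limited maximum `f0`. Evaluated
#' through [stats::plogis()] so both tails underflow gracefully.
#'
#' @param i Positive numeric vector of length-class indices (`l_i = i`).
#' @param params An `"af_params"` object supplying `f0` and `l0`.
#' @return Forces in newtons, same length as `i`, each in `[0, f0]`.
#' @examples
#' p <- af_params()
#' af_force_law(p$l0, p)       # exactly f0/2 at the midpoint
#' af_force_law(c(1, 1000), p) # vanishing vs saturated
#' @export
af_force_law <- function(i, params) {
  stopifnot(inherits(params, "af_params"))
  if (!is.numeric(i) || any(!is.finite(i)) || any(i < 1))
    stop("'i' must be numeric with all entries >= 1", call. = FALSE)
  params$f0 * stats::plogis(i - params$l0)
}

#' Expected filament tension under a length distribution
#'
#' `F = sum_i p_i f_i`, the mean tension per monomer-weighted length class.
#' Holding `F` constant is the model's expression of tensional homeostasis.
#'
#' @param p Probability vector over length classes `1..m`.
#' @param params An `"af_params"` object.
#' @return Expected tension in newtons, in `[0, f0]`.
#' @examples
#' p <- af_params(m = 200)
#' af_expected_force(rep(1 / 200, 200), p)
#' @export
af_expected_force <- function(p, params) {
  stopifnot(inherits(params, "af_params"))
  check_probability(p)
  sum(p * af_force_law(seq_along(p), params))
}

check_probability <- function(p, tol = 1e-9) {
  if (!is.numeric(p) || any(!is.finite(p)))
    stop("'p' must be a finite numeric vector", call. = FALSE)
  if (any(p < 0)) stop("'p' must be non-negative", call. = FALSE)
  if (abs(sum(p) - 1) > tol)
    stop(sprintf("'p' must sum to 1 (got %.12g)", sum(p)), call. = FALSE)
  invisible(p)
}
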