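#' Model parameters for the actin-filament length-distribution model
#'
#' Bundles every scalar parameter of the constrained maximum-entropy model
#' and validates its domain. Defaults are the reference parameter set for a
#' typical adherent nonmuscle cell: `N = 1000` monomers, physiological
#' temperature `T = 309.5` K, cell volume `V = 6e-16` m^3, prestrain
#' `lam = 0.2`, compartment size `a = 10` monomer lengths, maximum filament
#' force `f0 = 1e-12` N, sigmoid midpoint `l0 = 80` monomer lengths and
#' Boltzmann constant `kb = 1.38e-23` J/K.
#'
#' Lengths are measured in monomer units: the effective monomer diameter is
#' normalized to 1, so length class `i` has length `l_i = i`. The dispersion
#' entropy weight `kb_prime` is specified through the dimensionless ratio
#' `kb_ratio = kb_prime/kb`, the quantity that actually enters the stationary
#' distribution's exponent; `kb_prime` is derived internally.
#'
#' @param N Positive integer. Total number of actin monomers in the cell.
#' @param T_kelvin Positive real, kelvin. Cell temperature.
#' @param V Positive real, m^3. Cell volume.
#' @param lam Non-negative real, dimensionless. Preexisting cellular strain.
#' @param a Positive integer, monomer lengths. Cytoplasmic compartment size.
#' @param f0 Non-negative real, newtons. Maximum force a filament can bear.
#' @param l0 Positive real, monomer lengths. Length at which the
#'   force-length sigmoid has maximum slope (force reaches `f0/2`).
#' @param kb Positive real, J/K. Boltzmann constant.
#' @param kb_ratio Non-negative real. Ratio `kb_prime/kb` weighting the
#'   dispersion entropy against the formation entropy. Default 4, a
#'   representative regime where both entropies matter.
#' @param m Positive integer `<= N`. Index of the longest length class
#'   retained (truncation of the length axis). Defaults to `N`, the longest
#'   conceivable filament (all monomers in one chain).
#'
#' @return An object of class `"af_params"`: a named list with the fields
#'   above plus the derived `kb_prime = kb_ratio * kb`.
#'
#' @examples
#' p <- af_params()
#' p$kb_prime / p$kb   # the dispersion-entropy weight ratio
#' af_params(kb_ratio = 10, m = 500)
#' @export
af_params <- function(N = 1000L, T_kelvin = 309.5, V = 6e-16, lam = 0.2,
                      a = 10L, f0 = 1e-12, l0 = 80, kb = 1.38e-23,
                      kb_ratio = 4, m = N) {
  chk_scalar <- function(x, name) {
    if (length(x) != 1L || !is.numeric(x) || !is.finite(x))
      stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  for (nm in c("N", "T_kelvin", "V", "lam", "a", "f0", "l0", "kb",
               "kb_ratio", "m")) {
    chk_scalar(get(nm), nm)
  }
  chk_count <- function(x, name) {
    if (x < 1 || x != round(x))
      stop(sprintf("'%s' must be a positive integer (got %s)", name, x),
           call. = FALSE)
  }
  chk_count(N, "N")
  chk_count(a, "a")
  chk_count(m, "m")
  if (m > N) stop("'m' must not exceed 'N': a filament cannot contain more monomers than exist",
                  call. = FALSE)
  if (T_kelvin <= 0) stop("'T_kelvin' must be positive", call. = FALSE)
  if (V <= 0) stop("'V' must be positive", call. = FALSE)
  if (lam < 0) stop("'lam' must be non-negative", call. = FALSE)
  if (f0 < 0) stop("'f0' must be non-negative", call. = FALSE)
  if (l0 <= 0) stop("'l0' must be positive", call. = FALSE)
  if (kb <= 0) stop("'kb' must be positive", call. = FALSE)
  if (kb_ratio < 0) stop("'kb_ratio' must be non-negative", call. = FALSE)

  structure(
    list(N = as.integer(N), T_kelvin = T_kelvin, V = V, lam = lam,
         a = as.integer(a), f0 = f0, l0 = l0, kb = kb,
         kb_ratio = kb_ratio, kb_prime = kb_ratio * kb, m = as.integer(m)),
    class = "af_params"
  )
}

#' Update a parameter set
#'
#' Returns a new validated [af_params()] object with the named fields
#' replaced. `kb_prime` is always rederived from `kb_ratio * kb`; supply
#' `kb_ratio`, not `kb_prime`. If `N` changes and `m` is not supplied, `m`
#' is capped at the new `N`.
#'
#' @param params An `"af_params"` object.
#' @param ... Named fields to replace (any argument of [af_params()]).
#' @return A new `"af_params"` object.
#' @examples
#' af_update(af_params(), f0 = 1, l0 = 20)
#' @export
af_update <- function(params, ...) {
  stopifnot(inherits(params, "af_params"))
  new <- list(...)
  bad <- setdiff(names(new), c("N", "T_kelvin", "V", "lam", "a", "f0", "l0",
                               "kb", "kb_ratio", "m"))
  if (length(bad))
    stop("unknown parameter field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  cur <- params[c("N", "T_kelvin", "V", "lam", "a", "f0", "l0", "kb",
                  "kb_ratio", "m")]
  cur[names(new)] <- new
  if ("N" %in% names(new) && !("m" %in% names(new)))
    cur$m <- min(cur$m, cur$N)
  do.call(af_params, cur)
}

#' @export
print.af_params <- function(x, ...) {
  cat("Actin-filament length-distribution model parameters\n")
  cat(sprintf("  N (monomers)          : %d\n", x$N))
  cat(sprintf("  m (longest class)     : %d\n", x$m))
  cat(sprintf("  T (K)                 : %g\n", x$T_kelvin))
  cat(sprintf("  V (m^3)               : %g\n", x$V))
  cat(sprintf("  lambda (prestrain)    : %g\n", x$lam))
  cat(sprintf("  a (compartment size)  : %d\n", x$a))
  cat(sprintf("  f0 (N)                : %g\n", x$f0))
  cat(sprintf("  l0 (monomer lengths)  : %g\n", x$l0))
  cat(sprintf("  kb (J/K)              : %g\n", x$kb))
  cat(sprintf("  kb'/kb                : %g\n", x$kb_ratio))
  invisible(x)
}

#' Length grid of the model
#'
#' Filament lengths are integer multiples of the monomer diameter
#' (normalized to 1), so the grid for `m` classes is simply `1:m`.
#'
#' @param params An `"af_params"` object (or a positive integer `m`).
#' @return Integer vector of lengths `l_i = i`, `i = 1..m`.
#' @examples
#' af_lengths(af_params(m = 5))
#' @export
af_lengths <- function(params) {
  m <- if (inherits(params, "af_params")) params$m else as.integer(params)
  stopifnot(length(m) == 1L, is.finite(m), m >= 1)
  seq_len(m)
}
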