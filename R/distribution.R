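#' Stationary (maximum-entropy) length distribution
#'
#' Closed-form solution of the constrained entropy maximization: the
#' probability that a monomer belongs to length class `i` is
#'
#'   `p_i = exp[(kb' * A_i/l_i - V*lam/(2*T*N) * f_i) / kb] / Z`
#'
#' with `Z` the normalizing sum. The first exponent term is the dispersion
#' reward for short filaments; the second is the tension-constraint penalty,
#' which suppresses classes longer than `l0` once `f0` is large enough for
#' the force scale `V*lam*f0 / (2*T*N*kb)` to reach order one. The exponent
#' is evaluated in log-space with max-subtraction, so arbitrarily large
#' dispersion weights or forces cannot overflow.
#'
#' @param params An `"af_params"` object.
#' @param geom Optional `"af_dispersion"` object for `params$a` and
#'   `params$m` classes (computed if missing).
#' @return An object of class `"af_distribution"`: list with
#'   \describe{
#'     \item{p}{probability vector over classes `1..m` (sums to 1; all
#'       entries strictly positive)}
#'     \item{n}{monomer counts `N * p` (continuum relaxation: real valued)}
#'     \item{lengths}{`1:m`}
#'     \item{A}{coverage coefficients}
#'     \item{force}{per-class tension `f_i` in newtons}
#'     \item{exponent_dispersion, exponent_force}{the two dimensionless
#'       exponent components `kb'/kb * A_i/l_i` and
#'       `-V*lam/(2*T*N*kb) * f_i`, exposed so magnitude balance can be
#'       audited}
#'     \item{log_partition}{`log(Z)` computed by shifted log-sum-exp}
#'     \item{params}{the input parameter set}
#'   }
#' @examples
#' d <- af_stationary_distribution(af_params(kb_ratio = 4, m = 300))
#' head(d$p)
#' sum(d$p)
#' @export
af_stationary_distribution <- function(params, geom = NULL) {
  stopifnot(inherits(params, "af_params"))
  if (is.null(geom)) geom <- af_dispersion_coefficients(params$a, params$m)
  stopifnot(inherits(geom, "af_dispersion"), geom$m == params$m,
            geom$a == params$a)
  m <- params$m
  i <- seq_len(m)
  f <- af_force_law(i, params)
  # dimensionless exponent: (kb' A_i/l_i - V lam/(2 T N) f_i) / kb
  e_disp <- params$kb_ratio * geom$ratio
  force_coef <- params$V * params$lam / (2 * params$T_kelvin * params$N * params$kb)
  e_force <- -force_coef * f
  e <- e_disp + e_force
  shift <- max(e)
  w <- exp(e - shift)
  Z_shifted <- sum(w)
  p <- w / Z_shifted
  structure(
    list(p = p, n = params$N * p, lengths = i, A = geom$A, force = f,
         exponent_dispersion = e_disp, exponent_force = e_force,
         log_partition = log(Z_shifted) + shift, params = params),
    class = "af_distribution"
  )
}

#' @export
print.af_distribution <- function(x, ...) {
  m <- length(x$p)
  cat(sprintf("Stationary actin-filament length distribution (m = %d classes)\n", m))
  cat(sprintf("  kb'/kb = %g, f0 = %g N, l0 = %g, a = %d, lambda = %g\n",
              x$params$kb_ratio, x$params$f0, x$params$l0, x$params$a,
              x$params$lam))
  cat(sprintf("  p_1 = %.6g, p_m = %.6g, sum(p) = %.12g\n",
              x$p[1], x$p[m], sum(x$p)))
  cat(sprintf("  expected tension F = %.6g N, log Z = %.6g\n",
              sum(x$p * x$force), x$log_partition))
  invisible(x)
}

#' Tabulate a length distribution
#'
#' Flattens an `"af_distribution"` into the standard per-class table with
#' one row per length class: coverage coefficient, force, the two exponent
#' components, probability, monomer count and filament count
#' (`n_i / l_i`, real valued under the continuum relaxation).
#'
#' @param x An `"af_distribution"` object.
#' @param row.names,optional,... Ignored; present for S3 compatibility.
#' @return A `data.frame` with columns `class_index`, `length`, `A_coeff`,
#'   `force_N`, `exponent_dispersion`, `exponent_force`, `probability`,
#'   `monomer_count`, `filament_count`.
#' @examples
#' head(as.data.frame(af_stationary_distribution(af_params(m = 10))))
#' @export
as.data.frame.af_distribution <- function(x, row.names = NULL,
                                          optional = FALSE, ...) {
  data.frame(
    class_index = x$lengths,
    length = x$lengths,
    A_coeff = x$A,
    force_N = x$force,
    exponent_dispersion = x$exponent_dispersion,
    exponent_force = x$exponent_force,
    probability = x$p,
    monomer_count = x$n,
    filament_count = x$n / x$lengths
  )
}

#' Locate the stepwise drop in a length distribution
#'
#' When the tension constraint dominates (`kb' = 0`, large `f0`), the
#' distribution is a two-plateau step: flat above and below a threshold at
#' the sigmoid midpoint `l0`. This helper finds the step as the class index
#' `i` maximizing the adjacent probability ratio `p_i / p_{i+1}`.
#'
#' @param p Probability vector (length >= 2).
#' @return Integer index of the largest adjacent drop (the last class of
#'   the high plateau).
#' @examples
#' d <- af_stationary_distribution(af_params(kb_ratio = 0, f0 = 1, l0 = 20, m = 200))
#' af_step_location(d$p)
#' @export
af_step_location <- function(p) {
  if (inherits(p, "af_distribution")) p <- p$p
  stopifnot(is.numeric(p), length(p) >= 2, all(p > 0))
  drops <- p[-length(p)] / p[-1]
  which.max(drops)
}
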