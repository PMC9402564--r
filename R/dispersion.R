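#' Compartment-coverage coefficients (closed form)
#'
#' The cytoplasm is modeled as a 1D array of compartments, each `a` monomer
#' lengths wide. `A_i` is the maximum number of compartments a single
#' straight filament of length class `i` can touch. A one-monomer filament
#' always fits inside one compartment (`A_1 = 1`); beyond that one extra
#' compartment becomes reachable every `a` length classes, so for `i >= 2`
#'
#'   `A_i = floor((i - 2)/a) + 2`.
#'
#' The per-monomer coverage efficiency `A_i / l_i` is large for short
#' filaments and decreases toward the limit `1/a` as `i` grows: monomers
#' locked in long filaments disperse less efficiently.
#'
#' @param a Positive integer. Compartment size in monomer lengths.
#' @param m Positive integer. Number of length classes.
#' @return An object of class `"af_dispersion"`: list with `a`, `m`, integer
#'   vector `A` (length `m`) and `ratio = A / (1:m)`.
#' @seealso [af_dispersion_coefficients_literal()] for the block-sum
#'   transcription used as an independent oracle in the tests.
#' @examples
#' af_dispersion_coefficients(a = 10, m = 12)$A
#' @export
af_dispersion_coefficients <- function(a, m) {
  a <- check_pos_int(a, "a")
  m <- check_pos_int(m, "m")
  i <- seq_len(m)
  A <- ifelse(i == 1L, 1L, (i - 2L) %/% a + 2L)
  A <- as.integer(A)
  structure(list(a = a, m = m, A = A, ratio = A / i),
            class = "af_dispersion")
}

#' Compartment-coverage coefficients (literal block sum)
#'
#' Direct transcription of the coverage count as a sum over coefficient
#' blocks: class 1 has coefficient 1; block `j = 1, 2, ...` spans classes
#' `i = 2 + a*(j-1)` through `1 + a*j` and carries coefficient `j + 1`;
#' the final block is truncated at `m`. Kept deliberately naive and
#' independent of the closed form so the two can cross-check each other.
#'
#' @inheritParams af_dispersion_coefficients
#' @return An `"af_dispersion"` object, identical in content to
#'   [af_dispersion_coefficients()].
#' @examples
#' identical(af_dispersion_coefficients_literal(3, 20)$A,
#'           af_dispersion_coefficients(3, 20)$A)
#' @export
af_dispersion_coefficients_literal <- function(a, m) {
  a <- check_pos_int(a, "a")
  m <- check_pos_int(m, "m")
  A <- integer(m)
  A[1L] <- 1L
  j <- 1L
  repeat {
    lo <- 2L + a * (j - 1L)
    if (lo > m) break
    hi <- min(1L + a * j, m)
    A[lo:hi] <- j + 1L
    j <- j + 1L
  }
  structure(list(a = a, m = m, A = A, ratio = A / seq_len(m)),
            class = "af_dispersion")
}

#' @export
print.af_dispersion <- function(x, ...) {
  cat(sprintf("Compartment coverage coefficients: a = %d, m = %d\n", x$a, x$m))
  cat(sprintf("  A_1 = %d, A_m = %d, A_m/l_m = %.6g (limit 1/a = %.6g)\n",
              x$A[1], x$A[x$m], x$ratio[x$m], 1 / x$a))
  invisible(x)
}

#' Total compartment coverage of a filament population
#'
#' Weighted count `G = sum_i A_i * n_i / l_i` of the maximum number of
#' cytoplasmic compartments the whole filament population can cover, where
#' `n_i / l_i` is the number of filaments in length class `i`.
#'
#' @param n Non-negative numeric vector of monomer counts per length class.
#' @param geom An `"af_dispersion"` object with at least `length(n)` classes.
#' @return The coverage `G` (a non-negative real).
#' @examples
#' g <- af_dispersion_coefficients(10, 5)
#' af_total_coverage(c(1000, 0, 0, 0, 0), g)  # all monomers as singletons
#' @export
af_total_coverage <- function(n, geom) {
  stopifnot(inherits(geom, "af_dispersion"))
  if (!is.numeric(n) || any(!is.finite(n)))
    stop("'n' must be a finite numeric vector", call. = FALSE)
  if (any(n < 0)) stop("'n' must be non-negative", call. = FALSE)
  if (length(n) > geom$m)
    stop("'n' has more classes than the dispersion geometry", call. = FALSE)
  i <- seq_along(n)
  sum(geom$A[i] * n / i)
}

check_pos_int <- function(x, name) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x) || x < 1 ||
      x != round(x))
    stop(sprintf("'%s' must be a positive integer", name), call. = FALSE)
  as.integer(x)
}
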