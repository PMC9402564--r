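#' Exact multinomial state count (log scale)
#'
#' Number of ways `ln W = ln[N! / (n_1! n_2! ... n_m!)]` to assign `N`
#' distinguishable monomers to length classes with the given occupation
#' counts, computed through exact log-factorials ([lfactorial()]), with no
#' Stirling approximation. This is the reference against which the Stirling
#' form of the formation entropy is validated.
#'
#' @param n Vector of non-negative integer monomer counts.
#' @return `ln W`, a non-negative real.
#' @examples
#' af_exact_log_states(c(2, 4))   # ln 15
#' af_exact_log_states(c(10, 0))  # 0: a single arrangement
#' @export
af_exact_log_states <- function(n) {
  if (!is.numeric(n) || any(!is.finite(n)))
    stop("'n' must be a finite numeric vector", call. = FALSE)
  if (any(n < 0) || any(n != round(n)))
    stop("'n' must contain non-negative integers", call. = FALSE)
  lfactorial(sum(n)) - sum(lfactorial(n))
}

# Entropy objective for arbitrary positive vectors (no normalization check):
# needed by the Lagrangian, whose argument need not be feasible.
entropy_raw <- function(p, params, geom) {
  plogp <- ifelse(p > 0, p * log(p), 0)
  -params$kb * params$N * sum(plogp) +
    params$kb_prime * params$N * sum(geom$ratio[seq_along(p)] * p)
}

#' Lagrangian of the constrained entropy maximization
#'
#' `L(p; alpha, beta) = S(p) - alpha*(sum(p*f) - F_target) - beta*(sum(p) - 1)`
#' where `S` is the total entropy. `p` need not be feasible; on the
#' feasible set `L` reduces to `S` exactly.
#'
#' @param p Positive numeric vector (not necessarily normalized).
#' @param alpha,beta Lagrange multipliers on the tension and normalization
#'   constraints (units J/(K N) and J/K respectively).
#' @param params An `"af_params"` object.
#' @param geom Optional `"af_dispersion"` object (computed if missing).
#' @param F_target Target expected tension in newtons.
#' @return The Lagrangian value in J/K.
#' @examples
#' pp <- af_params(m = 4)
#' p <- rep(0.25, 4)
#' af_lagrangian(p, 0, 0, pp, F_target = 0) == af_total_entropy(p, pp)$S
#' @export
af_lagrangian <- function(p, alpha, beta, params, geom = NULL, F_target) {
  stopifnot(inherits(params, "af_params"))
  if (is.null(geom)) geom <- af_dispersion_coefficients(params$a, length(p))
  if (any(p < 0)) stop("'p' must be non-negative", call. = FALSE)
  f <- af_force_law(seq_along(p), params)
  entropy_raw(p, params, geom) -
    alpha * (sum(p * f) - F_target) - beta * (sum(p) - 1)
}

#' Stationarity residual of the Lagrangian
#'
#' Max-norm of the analytic gradient
#' `dL/dp_i = -kb*N*(ln p_i + 1) + kb'*N*A_i/l_i - alpha*f_i - beta`
#' at a candidate distribution. At the true stationary point with
#' `alpha = V*lam/(2*T)` the residual vanishes up to floating-point
#' rounding; a large residual flags a non-stationary `p`.
#'
#' @param p Strictly positive probability vector.
#' @param params An `"af_params"` object.
#' @param geom Optional `"af_dispersion"` object.
#' @param alpha Multiplier on the tension constraint. Defaults to the
#'   model's closed-form value `V*lam/(2*T)`.
#' @param beta Multiplier on the normalization constraint, or `NULL` to
#'   solve for the value minimizing the residual (the midrange of the
#'   remaining per-component gradients).
#' @return The residual `max_i |dL/dp_i|` in J/K, with attributes `"beta"`
#'   (the beta used) and `"gradient"` (the full gradient vector).
#' @examples
#' pp <- af_params(m = 100)
#' d <- af_stationary_distribution(pp)
#' af_stationarity_residual(d$p, pp) / (pp$kb * pp$N)  # ~ 0
#' @export
af_stationarity_residual <- function(p, params, geom = NULL,
                                     alpha = NULL, beta = NULL) {
  stopifnot(inherits(params, "af_params"))
  if (any(p <= 0))
    stop("stationarity residual requires strictly positive 'p' (log divergence at 0)",
         call. = FALSE)
  if (is.null(geom)) geom <- af_dispersion_coefficients(params$a, length(p))
  if (is.null(alpha)) alpha <- params$V * params$lam / (2 * params$T_kelvin)
  f <- af_force_law(seq_along(p), params)
  base <- -params$kb * params$N * (log(p) + 1) +
    params$kb_prime * params$N * geom$ratio[seq_along(p)] - alpha * f
  if (is.null(beta)) beta <- (max(base) + min(base)) / 2
  g <- base - beta
  structure(max(abs(g)), beta = beta, gradient = g)
}

#' Numerically maximize the entropy under the homeostasis constraints
#'
#' Independent verification oracle: maximizes the total entropy
#' `S(p) = S_f + S_d` over the probability simplex subject to the expected
#' tension equality `sum(p*f) = F_target`, using an infeasible-start
#' equality-constrained Newton method with a diagonal-Hessian Schur solve
#' and fraction-to-boundary damping to keep `p > 0`. The solver works only
#' from the entropy and constraint definitions; it never evaluates the
#' closed-form stationary distribution, so agreement between the two is a
#' genuine cross-check. The objective is strictly concave, so the
#' constrained maximizer is unique and runs from different feasible starts
#' must coincide.
#'
#' The tension constraint row is scaled by `f0` for conditioning, and the
#' recovered multipliers are mapped back to the Lagrangian convention:
#' `alpha` (tension) and `beta` (normalization). When the per-class forces
#' are numerically indistinguishable over the retained classes (relative
#' spread below `force_spread_tol`), the tension constraint is inert: it is
#' dropped from the Newton system and `alpha` is reported as `NA`.
#'
#' @param params An `"af_params"` object with `m <= max_m`.
#' @param F_target Target expected tension (newtons). Defaults to the
#'   tension realized by the closed-form stationary distribution, the
#'   model's homeostatic set point (the target itself is a single number;
#'   the optimization path stays independent of the closed form).
#' @param geom Optional `"af_dispersion"` object.
#' @param n_starts Number of random feasible starts (uniform positive
#'   vectors, normalized). The best run is returned; the maximum deviation
#'   between starts is reported in `start_spread`.
#' @param seed Integer seed for the random starts (deterministic reruns).
#' @param tol Convergence tolerance on the max-norm of the scaled KKT
#'   residual (dimensionless; objective scaled by `kb*N`).
#' @param max_iter Newton iteration cap per start.
#' @param max_m Guard on problem size keeping the oracle honest and fast.
#' @param force_spread_tol Relative force spread below which the tension
#'   constraint is treated as inert.
#' @return An object of class `"af_oracle"`: list with `p_opt`,
#'   `converged`, `iterations`, `max_gradient_residual` (J/K, the
#'   stationarity residual at `p_opt` under the recovered multipliers),
#'   `objective_value` (entropy `S` at `p_opt`, J/K), `alpha`, `beta`,
#'   `F_target`, `start_spread`, `seed`.
#' @examples
#' pp <- af_params(m = 30, kb_ratio = 4)
#' res <- af_constrained_maximize(pp)
#' res$converged
#' @export
af_constrained_maximize <- function(params, F_target = NULL, geom = NULL,
                                    n_starts = 1L, seed = 1L,
                                    tol = 1e-12, max_iter = 200L,
                                    max_m = 60L,
                                    force_spread_tol = 1e-9) {
  stopifnot(inherits(params, "af_params"))
  m <- params$m
  if (m > max_m)
    stop(sprintf("oracle limited to m <= %d classes (got m = %d); raise 'max_m' deliberately",
                 max_m, m), call. = FALSE)
  if (is.null(geom)) geom <- af_dispersion_coefficients(params$a, m)
  i <- seq_len(m)
  f <- af_force_law(i, params)
  if (is.null(F_target))
    F_target <- sum(af_stationary_distribution(params, geom)$p * f)

  if (m == 1L) {
    return(structure(list(p_opt = 1, converged = TRUE, iterations = 0L,
                          max_gradient_residual = 0,
                          objective_value = entropy_raw(1, params, geom),
                          alpha = NA_real_, beta = NA_real_,
                          F_target = F_target, start_spread = 0,
                          seed = seed),
                     class = "af_oracle"))
  }

  r <- params$kb_ratio
  g <- geom$ratio
  # scaled objective: phi(p) = -S/(kb N) = sum p log p - r sum g p
  grad_phi <- function(p) log(p) + 1 - r * g

  # constraint rows; tension row scaled by f0 and dropped when inert
  use_force <- params$f0 > 0 &&
    (max(f) - min(f)) > force_spread_tol * max(params$f0, max(f))
  if (use_force) {
    ft <- f / params$f0
    Ft <- F_target / params$f0
    if (F_target < min(f) || F_target > max(f))
      stop("F_target is not attainable: must lie within [min f_i, max f_i]",
           call. = FALSE)
    Amat <- rbind(rep(1, m), ft)
    b <- c(1, Ft)
  } else {
    Amat <- matrix(1, nrow = 1, ncol = m)
    b <- 1
  }
  k <- nrow(Amat)

  residuals <- function(p, nu) {
    list(rd = grad_phi(p) + drop(crossprod(Amat, nu)),
         rp = drop(Amat %*% p) - b)
  }
  res_norm <- function(rr) sqrt(sum(rr$rd^2) + sum(rr$rp^2))

  solve_from <- function(p0) {
    p <- p0
    nu <- rep(0, k)
    converged <- FALSE
    it <- 0L
    for (it in seq_len(max_iter)) {
      rr <- residuals(p, nu)
      if (max(abs(rr$rd)) < tol && max(abs(rr$rp)) < tol) {
        converged <- TRUE
        break
      }
      hinv <- p                       # H = diag(1/p)
      AH <- Amat * rep(hinv, each = k)      # A %*% H^{-1} (k x m)
      S2 <- AH %*% t(Amat)                  # Schur complement (k x k)
      rhs <- rr$rp - drop(AH %*% rr$rd)
      dnu <- tryCatch(solve(S2, rhs), error = function(e) qr.solve(S2, rhs))
      dp <- -hinv * (rr$rd + drop(crossprod(Amat, dnu)))
      # fraction-to-boundary: keep p strictly positive
      neg <- dp < 0
      tmax <- if (any(neg)) min(1, 0.99 * min(-p[neg] / dp[neg])) else 1
      t <- tmax
      nrm0 <- res_norm(rr)
      repeat {
        rr_t <- residuals(p + t * dp, nu + t * dnu)
        if (res_norm(rr_t) <= (1 - 0.25 * t) * nrm0 || t < 1e-12) break
        t <- t / 2
      }
      p <- p + t * dp
      nu <- nu + t * dnu
      if (t < 1e-12) break
    }
    rr <- residuals(p, nu)
    list(p = p, nu = nu, converged = converged, iterations = it,
         kkt = max(abs(rr$rd), abs(rr$rp)))
  }

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  runs <- vector("list", n_starts)
  for (s in seq_len(n_starts)) {
    u <- stats::runif(m, min = 0.1, max = 1)
    runs[[s]] <- solve_from(u / sum(u))
  }
  ok <- vapply(runs, `[[`, logical(1), "converged")
  if (!any(ok)) {
    kkts <- vapply(runs, `[[`, numeric(1), "kkt")
    stop(sprintf("oracle maximizer failed to converge from %d start(s); best KKT residual %.3g (tol %.3g), iterations %s",
                 n_starts, min(kkts),
                 tol, paste(vapply(runs, `[[`, integer(1), "iterations"),
                            collapse = ",")), call. = FALSE)
  }
  objs <- vapply(runs, function(rn)
    if (rn$converged) entropy_raw(rn$p, params, geom) else -Inf, numeric(1))
  best <- runs[[which.max(objs)]]
  start_spread <- if (sum(ok) > 1) {
    ps <- do.call(rbind, lapply(runs[ok], `[[`, "p"))
    max(apply(ps, 2, function(col) diff(range(col))))
  } else 0

  # map scaled multipliers back to the Lagrangian convention:
  # grad S = alpha*f + beta with grad(phi) + A' nu = 0
  beta_hat <- params$kb * params$N * best$nu[1]
  alpha_hat <- if (use_force)
    params$kb * params$N * best$nu[2] / params$f0 else NA_real_
  resid <- af_stationarity_residual(
    best$p, params, geom,
    alpha = if (use_force) alpha_hat else 0, beta = beta_hat)

  structure(list(p_opt = best$p, converged = best$converged,
                 iterations = best$iterations,
                 max_gradient_residual = as.numeric(resid),
                 objective_value = entropy_raw(best$p, params, geom),
                 alpha = alpha_hat, beta = beta_hat,
                 F_target = F_target, start_spread = start_spread,
                 seed = seed),
            class = "af_oracle")
}

#' @export
print.af_oracle <- function(x, ...) {
  cat("Constrained entropy maximization (variational oracle)\n")
  cat(sprintf("  converged: %s in %d Newton iterations (seed %d)\n",
              x$converged, x$iterations, x$seed))
  cat(sprintf("  objective S = %.6g J/K; gradient residual %.3g J/K\n",
              x$objective_value, x$max_gradient_residual))
  cat(sprintf("  multipliers: alpha = %.6g, beta = %.6g; F_target = %.6g N\n",
              x$alpha, x$beta, x$F_target))
  invisible(x)
}
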