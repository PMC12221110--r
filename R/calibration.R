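#' Calibration dataset of (temperature, DO2i) pairs
#'
#' Container for the data used to calibrate the quadratic taDO2i curve:
#' ordered pairs of core temperature (°C, within 20--40) and per-m2 critical
#' DO2i (mL/min/m2, positive). A quadratic fit additionally needs at least 4
#' points with at least 3 distinct temperatures; that requirement is
#' enforced by [fit_quadratic()] so that degenerate inputs are reported as
#' such.
#'
#' @param temp_c numeric vector of core temperatures (°C).
#' @param do2i_per_m2 numeric vector of per-m2 DO2i values (mL/min/m2).
#' @param provenance `"user"` or `"synthetic"`.
#' @return A data frame of class `tado2i_dataset` with columns `temp_c` and
#'   `do2i_per_m2`.
#' @export
calibration_dataset <- function(temp_c, do2i_per_m2,
                                provenance = c("user", "synthetic")) {
  provenance <- match.arg(provenance)
  if (!is.numeric(temp_c) || !is.numeric(do2i_per_m2) ||
      length(temp_c) != length(do2i_per_m2) || length(temp_c) < 1L ||
      anyNA(temp_c) || anyNA(do2i_per_m2)) {
    parameter_error(
      "`temp_c` and `do2i_per_m2` must be equal-length numeric without NA")
  }
  if (any(temp_c < 20 | temp_c > 40)) {
    parameter_error("calibration temperatures must lie within 20-40 °C")
  }
  if (any(do2i_per_m2 <= 0)) {
    parameter_error("DO2i values must be positive")
  }
  structure(
    data.frame(temp_c = as.numeric(temp_c),
               do2i_per_m2 = as.numeric(do2i_per_m2)),
    provenance = provenance,
    class = c("tado2i_dataset", "data.frame")
  )
}

#' Fit the quadratic critical-DO2i curve by least squares
#'
#' Ordinary least squares on the design \eqn{(1, T, T^2)}. Reports
#' \eqn{R^2 = 1 - SS_{res}/SS_{tot}} and the standard error of estimate
#' \eqn{SEE = \sqrt{SS_{res}/(n-3)}} (three estimated coefficients, hence
#' the n-3 residual degrees of freedom).
#'
#' @param data a [calibration_dataset()].
#' @return An object of class `tado2i_fit`: `coeffs` ([quad_coeffs()]),
#'   `r_squared`, `see`, `n`, `fitted`, `residuals`, and the `data` fitted.
#' @export
#' @examples
#' d <- calibration_dataset(24:37, quadratic_per_m2(24:37))
#' fit_quadratic(d)  # recovers the canonical coefficients, R^2 = 1
fit_quadratic <- function(data) {
  if (!inherits(data, "tado2i_dataset")) {
    parameter_error("`data` must be a calibration_dataset()")
  }
  tt <- data$temp_c
  y <- data$do2i_per_m2
  n <- length(y)
  if (n < 4L) {
    degenerate_error(sprintf(
      "quadratic fit needs >= 4 points for a residual degree of freedom (got %d)",
      n))
  }
  if (length(unique(tt)) < 3L) {
    degenerate_error(
      "quadratic fit needs >= 3 distinct temperatures (rank-deficient design)")
  }
  lmfit <- stats::lm(y ~ tt + I(tt^2))
  beta <- unname(stats::coef(lmfit))
  ss_res <- sum(stats::residuals(lmfit)^2)
  ss_tot <- sum((y - mean(y))^2)
  structure(list(
    coeffs = quad_coeffs(a = beta[3], b = beta[2], c = beta[1]),
    r_squared = 1 - ss_res / ss_tot,
    see = sqrt(ss_res / (n - 3)),
    n = n,
    fitted = unname(stats::fitted(lmfit)),
    residuals = unname(stats::residuals(lmfit)),
    data = data
  ), class = "tado2i_fit")
}

#' @export
print.tado2i_fit <- function(x, ...) {
  cat(sprintf(
    "Quadratic calibration fit (n = %d):\n  DO2i = %.4g*T^2 + %.4g*T + %.4g\n  R^2 = %.4f, SEE = %.2f mL/min/m2\n",
    x$n, x$coeffs$a, x$coeffs$b, x$coeffs$c, x$r_squared, x$see))
  if (!is.null(x$ci)) {
    cat(sprintf("  %g%% bootstrap CIs (%d resamples, seed %d):\n",
                100 * x$ci_confidence, x$n_resamples, x$seed))
    for (nm in rownames(x$ci)) {
      cat(sprintf("    %s: [%.4g, %.4g]\n", nm, x$ci[nm, 1], x$ci[nm, 2]))
    }
  }
  invisible(x)
}

# Fast internal OLS for bootstrap resamples (QR via .lm.fit). Returns the
# coefficient vector (c, b, a) or NULL when the resampled design is
# rank-deficient.
.quad_ols <- function(tt, y) {
  if (length(unique(tt)) < 3L) return(NULL)
  X <- cbind(1, tt, tt * tt)
  fit <- stats::.lm.fit(X, y)
  if (fit$rank < 3L) return(NULL)
  fit$coefficients
}

#' Bootstrap confidence intervals for the quadratic coefficients
#'
#' Case-resampling bootstrap: rows of the dataset are resampled with
#' replacement `n_resamples` times, the quadratic is refitted to each
#' resample, and percentile intervals at the requested confidence level are
#' taken over the resampled coefficients. Resamples whose design is
#' rank-deficient (fewer than 3 distinct temperatures drawn) are redrawn and
#' counted. Identical seeds give identical intervals; the caller's RNG state
#' is left untouched.
#'
#' @param data a [calibration_dataset()] (at least 6 points).
#' @param n_resamples number of bootstrap resamples (>= 100; 1000 is the
#'   conventional choice).
#' @param confidence confidence level in (0, 1), default 0.95.
#' @param seed integer RNG seed (mandatory: no hidden global state).
#' @return An object of class `tado2i_bootstrap`: `ci` (3 x 2 matrix, rows
#'   `a`, `b`, `c`), `estimates` (the full-data point estimates), `se`
#'   (bootstrap standard errors), `n_resamples`, `confidence`, `seed`,
#'   `redraws`.
#' @export
bootstrap_coefficients <- function(data, n_resamples = 1000,
                                   confidence = 0.95, seed) {
  if (missing(seed)) parameter_error("`seed` is required")
  full_fit <- fit_quadratic(data)
  n <- full_fit$n
  if (n < 6L) {
    parameter_error(sprintf(
      "bootstrap needs >= 6 points for resampling stability (got %d)", n))
  }
  stopifnot_scalar_number(n_resamples, "n_resamples")
  if (n_resamples < 100) {
    parameter_error("`n_resamples` must be >= 100")
  }
  stopifnot_scalar_number(confidence, "confidence")
  if (confidence <= 0 || confidence >= 1) {
    parameter_error("`confidence` must lie in (0, 1)")
  }
  tt <- data$temp_c
  y <- data$do2i_per_m2
  boot <- matrix(NA_real_, nrow = n_resamples, ncol = 3L)
  redraws <- 0L
  with_preserved_seed(seed, {
    for (i in seq_len(n_resamples)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        beta <- .quad_ols(tt[idx], y[idx])
        if (!is.null(beta)) break
        redraws <- redraws + 1L
        if (redraws > 100L * n_resamples) {
          degenerate_error("bootstrap resamples persistently rank-deficient")
        }
      }
      boot[i, ] <- beta
    }
  })
  alpha <- (1 - confidence) / 2
  # boot columns are (c, b, a); report in (a, b, c) order
  ord <- c(3L, 2L, 1L)
  ci <- t(apply(boot[, ord, drop = FALSE], 2, stats::quantile,
                probs = c(alpha, 1 - alpha), names = FALSE))
  dimnames(ci) <- list(c("a", "b", "c"), c("lower", "upper"))
  est <- c(a = full_fit$coeffs$a, b = full_fit$coeffs$b, c = full_fit$coeffs$c)
  se <- apply(boot[, ord, drop = FALSE], 2, stats::sd)
  names(se) <- c("a", "b", "c")
  structure(list(ci = ci, estimates = est, se = se,
                 n_resamples = as.integer(n_resamples),
                 confidence = confidence, seed = as.integer(seed),
                 redraws = redraws),
            class = "tado2i_bootstrap")
}

#' @export
print.tado2i_bootstrap <- function(x, ...) {
  cat(sprintf(
    "Bootstrap CIs: %g%% percentile, %d resamples, seed %d (%d redraws)\n",
    100 * x$confidence, x$n_resamples, x$seed, x$redraws))
  for (nm in rownames(x$ci)) {
    cat(sprintf("  %s = %.5g  [%.5g, %.5g]\n",
                nm, x$estimates[nm], x$ci[nm, 1], x$ci[nm, 2]))
  }
  invisible(x)
}

#' Attach bootstrap intervals to a fit
#'
#' Convenience wrapper: runs [fit_quadratic()] and
#' [bootstrap_coefficients()] and returns the fit with `ci`,
#' `ci_confidence`, `n_resamples`, `seed` and `redraws` fields filled in.
#'
#' @inheritParams bootstrap_coefficients
#' @return A `tado2i_fit` with confidence-interval fields.
#' @export
calibrate <- function(data, n_resamples = 1000, confidence = 0.95, seed) {
  fit <- fit_quadratic(data)
  bs <- bootstrap_coefficients(data, n_resamples = n_resamples,
                               confidence = confidence, seed = seed)
  fit$ci <- bs$ci
  fit$ci_confidence <- confidence
  fit$boot_se <- bs$se
  fit$n_resamples <- bs$n_resamples
  fit$seed <- bs$seed
  fit$redraws <- bs$redraws
  fit
}
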