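# Detection of "high male stillbirth" cohorts: residuals of the fitted
# sex-ratio model above the 99.5% band (multiplier x SD, default 2.83), in
# two modes. Simple mode thresholds the residuals directly. Iterative mode
# implements additive-outlier (AO) detection in the Chang-Tiao-Chen style:
# the AO lambda statistic is computed at every time point under the fitted
# ARMA, the largest exceedance is removed from the series, the model is
# refit, and the cycle repeats until no statistic exceeds the critical value.

# coefficients c_j of pi(B) = phi(B)/theta(B), c_0 = 1: the AO signature
# that a unit additive outlier leaves on subsequent residuals.
pi_weights <- function(fit, max_len) {
  phi <- numeric(0)
  if (length(fit$spec$ar_lags)) {
    phi <- numeric(max(fit$spec$ar_lags))
    phi[fit$spec$ar_lags] <- fit$coef[paste0("ar", fit$spec$ar_lags)]
  }
  theta <- numeric(0)
  if (length(fit$spec$ma_lags)) {
    theta <- numeric(max(fit$spec$ma_lags))
    theta[fit$spec$ma_lags] <- fit$coef[paste0("ma", fit$spec$ma_lags)]
  }
  p <- length(phi); q <- length(theta)
  cw <- numeric(max_len)  # c_1 .. c_{max_len}
  for (j in seq_len(max_len)) {
    v <- if (j <= p) -phi[j] else 0
    if (q) for (i in seq_len(min(j, q))) {
      cj <- if (j - i == 0L) 1 else if (j - i <= length(cw)) cw[j - i] else 0
      v <- v - theta[i] * cj
    }
    cw[j] <- v
  }
  # truncate once the signature has died out
  keep <- which(abs(cw) > 1e-10)
  if (length(keep)) cw[seq_len(max(keep))] else numeric(0)
}

residual_scale <- function(e, sigma_method) {
  s <- switch(sigma_method,
              sd = stats::sd(e),
              mad = stats::mad(e, constant = 1.483))
  if (!is.finite(s) || s == 0)
    stop("residual scale estimate is zero; outlier statistics are undefined")
  s
}

# AO statistics for every time point given residuals and the pi-weight
# signature: returns list(omega, lambda)
ao_statistics <- function(e, cw, sigma) {
  n <- length(e)
  x <- c(1, cw)                     # signature x_0 = 1, x_k = c_k
  K <- length(x)
  num <- den <- numeric(n)
  for (k in seq_len(K)) {
    idx <- seq_len(n - k + 1L)
    num[idx] <- num[idx] + x[k] * e[idx + k - 1L]
    den[idx] <- den[idx] + x[k]^2
  }
  omega <- num / den
  lambda <- omega * sqrt(den) / sigma
  list(omega = omega, lambda = lambda)
}

#' Detect high-stillbirth outlier cohorts
#'
#' Flags conception cohorts whose sex-ratio residual lies above
#' `multiplier` x SD (high side; the working hypothesis concerns positive
#' outliers only). In `"simple"` mode residuals are thresholded directly. In
#' `"iterative"` mode the additive-outlier lambda statistic is computed at
#' every time point under the fitted ARMA, the largest absolute exceedance is
#' subtracted from the series, the model is refit, and the procedure repeats
#' (at most `max_iter` times); high-side detections are reported.
#'
#' @param fit A converged [fit_arma()] result with residuals.
#' @param multiplier Critical value in residual-SD units (default 2.83, the
#'   published 99.5% band).
#' @param mode `"simple"` or `"iterative"`.
#' @param sigma_method Residual scale estimator: `"sd"` (sample SD, default)
#'   or `"mad"` (robust, 1.483 x median absolute deviation).
#' @param two_sided Diagnostic option: also report low-side flags (default
#'   `FALSE`).
#' @param max_iter Iteration cap for `"iterative"` mode (default 10).
#' @return An object of class `outlier_result`: `flagged` (cohort keys, high
#'   side unless `two_sided`), `flagged_idx`, `statistic` (per-cohort
#'   standardized statistic), `effects` (estimated outlier effects at flagged
#'   points), `threshold`, `sigma`, `sigma_method`, `mode`, `iterations`,
#'   `adjusted_residuals` (residuals after removal of detected effects).
#' @examples
#' set.seed(1)
#' x <- rnorm(288); x[100] <- x[100] + 10
#' f <- fit_arma(x, arma_spec())
#' detect_high_outliers(f)$flagged_idx
#' @export
detect_high_outliers <- function(fit, multiplier = 2.83,
                                 mode = c("simple", "iterative"),
                                 sigma_method = c("sd", "mad"),
                                 two_sided = FALSE, max_iter = 10L) {
  mode <- match.arg(mode)
  sigma_method <- match.arg(sigma_method)
  stopifnot(inherits(fit, "arma_fit"))
  if (!isTRUE(fit$converged))
    stop("refusing to run outlier detection on a non-converged fit: ", fit$message)
  if (multiplier <= 0) stop("multiplier must be positive")
  e0 <- as.numeric(fit$residuals)
  n <- length(e0)
  keys <- fit$keys

  if (mode == "simple") {
    sigma <- residual_scale(e0, sigma_method)
    stat <- e0 / sigma
    hi <- stat > multiplier
    lo <- two_sided & (stat < -multiplier)
    flagged_idx <- which(hi | lo)
    adj <- e0
    adj[flagged_idx] <- 0
    effects <- e0[flagged_idx]
    iterations <- 0L
    final_stat <- stat
  } else {
    y <- fit$fitted + e0
    cur <- fit
    effects_acc <- numeric(n)
    det_lambda <- rep(NA_real_, n)
    iterations <- 0L
    sigma <- NA_real_
    repeat {
      e <- as.numeric(cur$residuals)
      sigma <- residual_scale(e, sigma_method)
      cw <- pi_weights(cur, n - 1L)
      ao <- ao_statistics(e, cw, sigma)
      lam <- ao$lambda
      # points already adjusted are not re-tested
      lam[effects_acc != 0] <- 0
      t_star <- which.max(abs(lam))
      if (abs(lam[t_star]) <= multiplier || iterations >= max_iter) {
        final_stat <- lam
        final_stat[effects_acc != 0] <- det_lambda[effects_acc != 0]
        break
      }
      effects_acc[t_star] <- effects_acc[t_star] + ao$omega[t_star]
      det_lambda[t_star] <- lam[t_star]
      y[t_star] <- y[t_star] - ao$omega[t_star]
      iterations <- iterations + 1L
      nxt <- fit_arma(y, cur$spec)
      if (!isTRUE(nxt$converged)) {
        # keep the last stable fit; stop iterating
        final_stat <- lam
        final_stat[effects_acc != 0] <- det_lambda[effects_acc != 0]
        break
      }
      if (!is.null(keys))
        nxt$residuals <- monthly_series(as.numeric(nxt$residuals), keys, "ARMA residuals")
      cur <- nxt
    }
    hi <- effects_acc > 0
    lo <- two_sided & (effects_acc < 0)
    flagged_idx <- which(hi | lo)
    effects <- effects_acc[flagged_idx]
    adj <- as.numeric(cur$residuals)
  }

  structure(list(
    flagged = if (!is.null(keys)) keys[flagged_idx] else flagged_idx,
    flagged_idx = flagged_idx,
    statistic = final_stat,
    effects = effects,
    threshold = multiplier,
    sigma = sigma,
    sigma_method = sigma_method,
    mode = mode,
    two_sided = two_sided,
    iterations = iterations,
    adjusted_residuals = adj,
    keys = keys,
    n = n
  ), class = "outlier_result")
}

#' @export
print.outlier_result <- function(x, ...) {
  cat("<outlier_result> mode = ", x$mode, ", threshold = ", x$threshold,
      " x sigma (", x$sigma_method, " = ", signif(x$sigma, 4), ")\n", sep = "")
  cat("  flagged ", length(x$flagged_idx), " of ", x$n, " cohorts",
      if (length(x$flagged_idx))
        paste0(": ", paste(x$flagged, collapse = ", ")) else "", "\n", sep = "")
  invisible(x)
}

#' Intervention dummy from an outlier result
#'
#' @param result An [detect_high_outliers()] result.
#' @param keys Cohort keys of the target window (defaults to the keys the
#'   outliers were detected on).
#' @return A 0/1 [monthly_series()] with exactly `length(result$flagged)`
#'   ones.
#' @export
dummy_series <- function(result, keys = result$keys) {
  stopifnot(inherits(result, "outlier_result"))
  if (is.null(keys)) stop("cohort keys are required to build the dummy series")
  v <- as.numeric(keys %in% result$flagged)
  if (sum(v) != length(result$flagged))
    stop("flagged cohorts fall outside the supplied cohort window")
  monthly_series(v, keys, "high male stillbirth indicator")
}

#' Continuous deviation series net of detected outliers
#'
#' The model residuals with the flagged months' estimated outlier effects
#' removed (iterative mode) or set to the model expectation, i.e. zero
#' (simple mode). Used as the continuous covariate in the null check of
#' [continuous_null_check()].
#'
#' @param fit The [fit_arma()] the outliers were detected on.
#' @param result The matching [detect_high_outliers()] result.
#' @return A [monthly_series()] (numeric if the fit carries no cohort keys).
#' @export
deviation_series <- function(fit, result) {
  stopifnot(inherits(fit, "arma_fit"), inherits(result, "outlier_result"))
  v <- result$adjusted_residuals
  if (!is.null(result$keys))
    monthly_series(v, result$keys, "sex-ratio residuals net of outliers")
  else v
}

#' Serialize an outlier result to JSON
#'
#' @param result An `outlier_result`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_outlier_result <- function(result, path) {
  obj <- list(flagged = result$flagged, flagged_idx = result$flagged_idx,
              statistic = result$statistic, effects = result$effects,
              threshold = result$threshold, sigma = result$sigma,
              sigma_method = result$sigma_method, mode = result$mode,
              iterations = result$iterations)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
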