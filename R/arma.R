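# Box-Jenkins identification and estimation of sparse-lag ARMA models.
#
# The published sex-ratio model carries a single AR term at lag 3 and a
# single MA term at lag 9 with every intermediate lag fixed at zero, so the
# estimator must support subset (sparse) specifications. Numerical likelihood
# optimization is delegated to stats::arima() with a `fixed` mask;
# identification (candidate grid, AIC selection, tie-breaks) and residual
# diagnostics live here.

#' Sparse ARMA specification
#'
#' @param ar_lags Integer set of autoregressive lags (possibly empty).
#' @param ma_lags Integer set of moving-average lags (possibly empty).
#' @param include_constant Estimate a constant (series mean)? Default `TRUE`.
#' @return An object of class `arma_spec`.
#' @examples
#' arma_spec(3, 9)               # the sparse AR{3} + MA{9} model
#' arma_spec(integer(0), integer(0)) # white noise with a mean
#' @export
arma_spec <- function(ar_lags = integer(0), ma_lags = integer(0),
                      include_constant = TRUE) {
  ar_lags <- sort(unique(as.integer(ar_lags)))
  ma_lags <- sort(unique(as.integer(ma_lags)))
  if (length(ar_lags) && any(ar_lags < 1L)) stop("AR lags must be positive")
  if (length(ma_lags) && any(ma_lags < 1L)) stop("MA lags must be positive")
  structure(list(ar_lags = ar_lags, ma_lags = ma_lags,
                 include_constant = isTRUE(include_constant)),
            class = "arma_spec")
}

#' @export
print.arma_spec <- function(x, ...) {
  cat("<arma_spec> ", format(x), "\n", sep = "")
  invisible(x)
}

#' @export
format.arma_spec <- function(x, ...) {
  paste0(
    if (x$include_constant) "c + " else "",
    if (length(x$ar_lags)) paste0("AR{", paste(x$ar_lags, collapse = ","), "}") else "",
    if (length(x$ar_lags) && length(x$ma_lags)) " + " else "",
    if (length(x$ma_lags)) paste0("MA{", paste(x$ma_lags, collapse = ","), "}") else "",
    if (!length(x$ar_lags) && !length(x$ma_lags)) "white noise" else ""
  )
}

n_parameters <- function(spec) {
  length(spec$ar_lags) + length(spec$ma_lags) + as.integer(spec$include_constant)
}

max_lag_of <- function(spec) {
  max(c(0L, spec$ar_lags, spec$ma_lags))
}

#' Candidate grid for Box-Jenkins identification
#'
#' Builds the deduplicated search grid used by [select_model()]: the
#' constant-only (white noise) model, every single-AR-lag and single-MA-lag
#' model up to `max_lag`, every one-AR-lag x one-MA-lag combination, and the
#' dense ARMA(p, q) models for p, q <= min(2, max_lag).
#'
#' @param max_lag Largest lag considered (default 12; about n/24 for a
#'   288-month series).
#' @return List of [arma_spec()] objects.
#' @examples
#' length(candidate_specs(1)) # 4
#' @export
candidate_specs <- function(max_lag = 12L) {
  max_lag <- as.integer(max_lag)
  if (max_lag < 1L) stop("max_lag must be at least 1")
  specs <- list(arma_spec())
  for (l in seq_len(max_lag)) specs[[length(specs) + 1L]] <- arma_spec(ar_lags = l)
  for (l in seq_len(max_lag)) specs[[length(specs) + 1L]] <- arma_spec(ma_lags = l)
  for (i in seq_len(max_lag)) for (j in seq_len(max_lag))
    specs[[length(specs) + 1L]] <- arma_spec(ar_lags = i, ma_lags = j)
  d <- min(2L, max_lag)
  for (p in 0:d) for (q in 0:d)
    specs[[length(specs) + 1L]] <- arma_spec(ar_lags = seq_len(p), ma_lags = seq_len(q))
  sig <- vapply(specs, function(s)
    paste(paste(s$ar_lags, collapse = ","), "|", paste(s$ma_lags, collapse = ",")),
    character(1L))
  specs[!duplicated(sig)]
}

#' Fit a sparse-lag ARMA model
#'
#' Maximum-likelihood estimation (Kalman-filter likelihood via
#' [stats::arima()], `CSS-ML` by default) of an [arma_spec()], with
#' intermediate lags fixed at zero. Non-convergence is flagged on the
#' returned object, never silently replaced by a fallback.
#'
#' @param series Numeric vector or [monthly_series()].
#' @param spec An [arma_spec()].
#' @param method Estimation method passed to [stats::arima()]: `"CSS-ML"`
#'   (default, exact likelihood) or `"CSS"` (conditional sum of squares;
#'   fast, AIC approximated as n log sigma^2 + 2k -- used for screening only).
#' @param lb_lags Lags for the residual Ljung-Box diagnostic (default 12).
#' @return An object of class `arma_fit`: `spec`, `coef` (named estimates
#'   including the constant), `se`, `sigma` (residual SD), `residuals`,
#'   `fitted`, `loglik`, `aic`, `n`, `lb` (Ljung-Box statistic/p-value),
#'   `converged`, `message`.
#' @examples
#' x <- arima.sim(list(ar = c(0, 0, 0.5)), n = 300)
#' fit_arma(x, arma_spec(ar_lags = 3))
#' @export
fit_arma <- function(series, spec, method = c("CSS-ML", "CSS"), lb_lags = 12L) {
  method <- match.arg(method)
  stopifnot(inherits(spec, "arma_spec"))
  x <- as.numeric(series)
  if (any(!is.finite(x))) stop("series contains non-finite values")
  n <- length(x)
  k <- n_parameters(spec)
  if (n <= 5L * max(k, 1L))
    stop("series too short (n = ", n, ") for ", k, " parameters")

  keys0 <- if (inherits(series, "monthly_series")) cohort_keys(series) else NULL
  if (!length(spec$ar_lags) && !length(spec$ma_lags))
    return(fit_constant_only(x, spec, keys0, lb_lags))

  p <- if (length(spec$ar_lags)) max(spec$ar_lags) else 0L
  q <- if (length(spec$ma_lags)) max(spec$ma_lags) else 0L
  fixed <- c(
    ifelse(seq_len(p) %in% spec$ar_lags, NA_real_, 0),
    ifelse(seq_len(q) %in% spec$ma_lags, NA_real_, 0),
    if (spec$include_constant) NA_real_
  )
  if (!length(fixed)) fixed <- NULL

  warn <- character(0)
  af <- withCallingHandlers(
    tryCatch(
      stats::arima(x, order = c(p, 0L, q), include.mean = spec$include_constant,
                   fixed = fixed, transform.pars = FALSE, method = method),
      error = function(e) e),
    warning = function(w) {
      warn <<- c(warn, conditionMessage(w))
      invokeRestart("muffleWarning")
    })

  keys <- if (inherits(series, "monthly_series")) cohort_keys(series) else NULL
  if (inherits(af, "error")) {
    return(structure(list(spec = spec, coef = NULL, se = NULL, sigma = NA_real_,
                          residuals = NULL, fitted = NULL, loglik = NA_real_,
                          aic = NA_real_, n = n, lb = NULL, keys = keys,
                          converged = FALSE,
                          message = conditionMessage(af)),
                     class = "arma_fit"))
  }

  free <- if (is.null(fixed)) logical(0) else is.na(fixed)
  est <- stats::coef(af)
  se <- rep(NA_real_, length(est))
  names(se) <- names(est)
  if (any(free)) {
    v <- diag(af$var.coef)
    se[free] <- sqrt(pmax(v, 0))
  }
  res <- as.numeric(stats::residuals(af))
  # CSS has no exact likelihood; use the Gaussian plug-in so screening AICs
  # are on the same scale as exact ones
  aic <- if (method == "CSS-ML") af$aic
         else n * (log(2 * pi * af$sigma2) + 1) + 2 * (k + 1)
  lb <- NULL
  fitdf <- length(spec$ar_lags) + length(spec$ma_lags)
  if (method == "CSS-ML" && lb_lags > fitdf && lb_lags < n / 2 && stats::sd(res) > 0)
    lb <- whiteness_test(res, lags = lb_lags, fitdf = fitdf)

  structure(list(
    spec = spec,
    coef = est, se = se,
    sigma = sqrt(af$sigma2),
    residuals = if (is.null(keys)) res else monthly_series(res, keys, "ARMA residuals"),
    fitted = x - res,
    loglik = as.numeric(af$loglik),
    aic = aic,
    n = n, keys = keys,
    lb = lb,
    converged = af$code == 0 && !any(grepl("convergence", warn)),
    message = if (length(warn)) paste(warn, collapse = "; ") else ""
  ), class = "arma_fit")
}

# Closed-form Gaussian ML for the lag-free (white noise with/without mean)
# specification; numerically identical to stats::arima(order = c(0,0,0)) but
# exact, fast, and well-defined on a constant series.
fit_constant_only <- function(x, spec, keys, lb_lags) {
  n <- length(x)
  mu <- if (spec$include_constant) mean(x) else 0
  res <- x - mu
  sigma2 <- mean(res^2)
  k <- as.integer(spec$include_constant)
  loglik <- if (sigma2 > 0) -0.5 * n * (log(2 * pi * sigma2) + 1) else Inf
  aic <- -2 * loglik + 2 * (k + 1)
  est <- if (spec$include_constant) c(intercept = mu) else numeric(0)
  se <- if (spec$include_constant) c(intercept = sqrt(sigma2 / n)) else numeric(0)
  lb <- if (lb_lags > 0L && lb_lags < n / 2 && stats::sd(res) > 0)
    whiteness_test(res, lags = lb_lags, fitdf = 0L) else NULL
  structure(list(
    spec = spec, coef = est, se = se, sigma = sqrt(sigma2),
    residuals = if (is.null(keys)) res else monthly_series(res, keys, "ARMA residuals"),
    fitted = x - res, loglik = loglik, aic = aic, n = n, keys = keys,
    lb = lb, converged = TRUE, message = ""
  ), class = "arma_fit")
}

#' @export
print.arma_fit <- function(x, ...) {
  cat("<arma_fit> ", format(x$spec), "  (n = ", x$n, ")\n", sep = "")
  if (!x$converged) {
    cat("  NOT CONVERGED: ", x$message, "\n", sep = "")
    return(invisible(x))
  }
  tab <- cbind(estimate = x$coef, se = x$se)
  print(round(tab[x$se > 0 | is.na(x$se), , drop = FALSE], 4))
  cat("  sigma ", signif(x$sigma, 4), ", loglik ", round(x$loglik, 2),
      ", AIC ", round(x$aic, 2), "\n", sep = "")
  if (!is.null(x$lb))
    cat("  Ljung-Box(", x$lb$lags, "): Q = ", round(x$lb$statistic, 2),
        ", p = ", signif(x$lb$p_value, 3), "\n", sep = "")
  invisible(x)
}

#' Identify the best-fitting model by minimum AIC
#'
#' Fits every candidate specification and returns the converged fit with the
#' lowest AIC; ties are broken by fewer parameters, then by lower maximum
#' lag. For large grids a fast conditional-sum-of-squares screen ranks the
#' candidates first and only the most promising are refit by exact maximum
#' likelihood (the selected AIC is always the exact-likelihood one).
#'
#' @param series Numeric vector or [monthly_series()].
#' @param candidates List of [arma_spec()] (default [candidate_specs()]).
#' @param screen Use the CSS pre-screen when the grid is larger than `keep`?
#'   Default `TRUE`.
#' @param keep Number of screened candidates refit by exact ML (default 15).
#' @return The winning `arma_fit`, with attribute `n_candidates`.
#' @export
select_model <- function(series, candidates = candidate_specs(),
                         screen = TRUE, keep = 15L) {
  if (!length(candidates)) stop("no candidate specifications supplied")
  pool <- candidates
  if (screen && length(candidates) > keep) {
    caic <- vapply(candidates, function(s) {
      f <- fit_arma(series, s, method = "CSS")
      if (isTRUE(f$converged)) f$aic else Inf
    }, numeric(1L))
    ord <- order(caic)
    pool <- candidates[ord[seq_len(min(keep, length(candidates)))]]
    # the white-noise benchmark is cheap and anchors the comparison
    has_wn <- any(vapply(pool, function(s) n_parameters(s) <= 1L, logical(1L)))
    if (!has_wn) pool <- c(pool, list(arma_spec()))
  }
  fits <- lapply(pool, function(s) fit_arma(series, s, method = "CSS-ML"))
  ok <- vapply(fits, function(f) isTRUE(f$converged) && is.finite(f$aic), logical(1L))
  if (!any(ok)) {
    msgs <- vapply(seq_along(fits), function(i)
      paste0(format(pool[[i]]), ": ", fits[[i]]$message), character(1L))
    stop("no candidate model converged:\n  ", paste(msgs, collapse = "\n  "))
  }
  fits <- fits[ok]
  aics <- vapply(fits, `[[`, numeric(1L), "aic")
  npars <- vapply(fits, function(f) n_parameters(f$spec), integer(1L))
  maxlags <- vapply(fits, function(f) max_lag_of(f$spec), integer(1L))
  out <- fits[[pick_best(aics, npars, maxlags)]]
  attr(out, "n_candidates") <- length(candidates)
  out
}

# selection order: minimal AIC, ties by fewer parameters, then lower max lag
pick_best <- function(aics, npars, maxlags) {
  order(aics, npars, maxlags)[1L]
}

#' Ljung-Box portmanteau test of residual whiteness
#'
#' Chi-square test of joint nullity of the first `lags` autocorrelations,
#' with degrees of freedom reduced by the number of fitted ARMA parameters.
#'
#' @param residuals Numeric residual series.
#' @param lags Number of autocorrelations tested (default 12); must be less
#'   than half the series length.
#' @param fitdf Number of AR + MA parameters estimated from the series
#'   (default 0 for a raw series).
#' @return List with `statistic`, `p_value`, `lags`, `fitdf`.
#' @examples
#' whiteness_test(rnorm(288))
#' @export
whiteness_test <- function(residuals, lags = 12L, fitdf = 0L) {
  x <- as.numeric(residuals)
  n <- length(x)
  if (lags >= n / 2) stop("lags must be smaller than half the series length")
  if (lags <= fitdf) stop("lags must exceed fitdf")
  if (stats::sd(x) == 0) stop("constant residual series; whiteness is undefined")
  bt <- stats::Box.test(x, lag = lags, type = "Ljung-Box", fitdf = fitdf)
  list(statistic = unname(bt$statistic), p_value = unname(bt$p.value),
       lags = as.integer(lags), fitdf = as.integer(fitdf))
}

#' Serialize an ARMA fit to JSON
#'
#' @param fit An `arma_fit`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_arma_fit <- function(fit, path) {
  obj <- list(
    spec = list(ar_lags = fit$spec$ar_lags, ma_lags = fit$spec$ma_lags,
                include_constant = fit$spec$include_constant),
    coef = as.list(fit$coef), se = as.list(fit$se),
    sigma = fit$sigma, loglik = fit$loglik, aic = fit$aic, n = fit$n,
    ljung_box = fit$lb, converged = fit$converged, message = fit$message
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
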