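# MacKinnon (2010) response-surface coefficients for finite-sample
# Dickey-Fuller critical values: cv = b0 + b1/T + b2/T^2 + b3/T^3,
# by regression type (n: no deterministic terms, c: constant,
# ct: constant + linear trend) and level.
.df_crit_coefs <- list(
  n = list(`0.01` = c(-2.56574, -2.2358, -3.627, 0),
           `0.05` = c(-1.94100, -0.2686, -3.365, 31.223),
           `0.10` = c(-1.61682, 0.2656, -2.714, 17.432)),
  c = list(`0.01` = c(-3.43035, -6.5393, -16.786, -79.433),
           `0.05` = c(-2.86154, -2.8903, -4.234, -40.040),
           `0.10` = c(-2.56677, -1.5384, -2.809, 0)),
  ct = list(`0.01` = c(-3.95877, -9.0531, -28.428, -134.155),
            `0.05` = c(-3.41049, -4.3904, -9.036, -45.374),
            `0.10` = c(-3.12705, -2.5856, -3.925, -22.380)))

.df_critical_value <- function(regression, alpha, nobs) {
  lev <- sprintf("%.2f", alpha)
  co <- .df_crit_coefs[[regression]][[lev]]
  if (is.null(co)) stop("no Dickey-Fuller critical values for alpha = ", alpha)
  co[1] + co[2] / nobs + co[3] / nobs^2 + co[4] / nobs^3
}

# Build the ADF regression rows for a series with internal missing values.
# Row t regresses diff(y)[t] on y[t-1], optional deterministic terms, and
# p lagged differences; a row is usable only when every value it needs is
# observed, so gaps in the series break lag pairs rather than being
# compressed away.
.adf_design <- function(y, p, regression) {
  T_ <- length(y)
  obs <- !is.na(y)
  t_idx <- (2 + p):T_
  if (!length(t_idx) || length(t_idx) < 1) {
    return(NULL)
  }
  need <- sapply(t_idx, function(t) all(obs[(t - 1 - p):t]))
  t_idx <- t_idx[need]
  if (!length(t_idx)) return(NULL)
  dy <- y[t_idx] - y[t_idx - 1]
  X <- cbind(ylag = y[t_idx - 1])
  if (p > 0) {
    for (j in seq_len(p)) {
      X <- cbind(X, y[t_idx - j] - y[t_idx - j - 1])
      colnames(X)[ncol(X)] <- paste0("dlag", j)
    }
  }
  if (regression %in% c("c", "ct")) X <- cbind(X, const = 1)
  if (regression == "ct") X <- cbind(X, trend = t_idx)
  list(y = dy, X = X, t_idx = t_idx)
}

.adf_ols <- function(d) {
  fit <- stats::lm.fit(d$X, d$y)
  df_resid <- length(d$y) - ncol(d$X)
  if (df_resid <= 0) return(NULL)
  rss <- sum(fit$residuals^2)
  s2 <- rss / df_resid
  XtXinv <- tryCatch(chol2inv(chol(crossprod(d$X))), error = function(e) NULL)
  if (is.null(XtXinv)) return(NULL)
  se <- sqrt(s2 * diag(XtXinv))
  list(coef = fit$coefficients, se = stats::setNames(se, colnames(d$X)),
       tstat = fit$coefficients / se, rss = rss, nobs = length(d$y),
       k = ncol(d$X))
}

#' Augmented Dickey-Fuller unit-root test (gap-aware)
#'
#' Tests the null of a unit root against stationarity, under one of three
#' deterministic specifications: none (`"n"`), constant (`"c"`), or
#' constant plus linear trend (`"ct"`). Missing values are handled
#' conservatively: a regression row is used only when the RT at trial t,
#' t-1, and all lagged differences it needs are observed, so the time axis
#' is never compressed across a gap. The lag order is chosen by AIC over
#' 0..`max_lag` (Schwert bound `floor(12 * (T/100)^0.25)` by default) on
#' the common sample of the largest feasible lag, then the chosen lag is
#' refit on its full sample.
#'
#' @param y Numeric series (NA = missing).
#' @param regression `"n"`, `"c"`, or `"ct"`.
#' @param lags Fixed lag order; `NULL` (default) selects by AIC.
#' @param max_lag Upper bound for lag selection.
#' @param alpha Level for the reported critical value (0.01, 0.05, 0.10).
#' @return List: `statistic` (t on the lagged level), `lag`, `nobs`,
#'   `critical_value`, `reject` (unit root rejected at `alpha`),
#'   `det_coef`, `det_tstat` (constant/trend coefficient and t statistic,
#'   when present), `regression`.
#' @export
adf_test <- function(y, regression = c("c", "n", "ct"), lags = NULL,
                     max_lag = NULL, alpha = 0.05) {
  regression <- match.arg(regression)
  y <- as.numeric(y)
  T_ <- sum(!is.na(y))
  if (is.null(max_lag)) max_lag <- floor(12 * (length(y) / 100)^0.25)
  if (is.null(lags)) {
    # shrink max_lag until the common sample supports the regression
    p_max <- max_lag
    d_max <- NULL
    while (p_max >= 0) {
      d_max <- .adf_design(y, p_max, regression)
      k <- 1 + p_max + (regression != "n") + (regression == "ct")
      if (!is.null(d_max) && length(d_max$y) >= k + 10) break
      p_max <- p_max - 1
    }
    if (p_max < 0 || is.null(d_max)) {
      stop("series too short/gappy for the ADF regression")
    }
    common <- d_max$t_idx
    aic <- rep(NA_real_, p_max + 1)
    for (p in 0:p_max) {
      d <- .adf_design(y, p, regression)
      keep <- d$t_idx %in% common
      d$y <- d$y[keep]; d$X <- d$X[keep, , drop = FALSE]
      f <- .adf_ols(d)
      if (!is.null(f)) {
        n <- f$nobs
        aic[p + 1] <- n * log(f$rss / n) + 2 * f$k
      }
    }
    if (all(is.na(aic))) stop("ADF lag selection failed")
    lags <- which.min(aic) - 1
  }
  d <- .adf_design(y, lags, regression)
  if (is.null(d)) stop("series too short/gappy for the ADF regression")
  f <- .adf_ols(d)
  if (is.null(f) || f$nobs - f$k < 1) {
    stop("series too short/gappy for the ADF regression")
  }
  stat <- unname(f$tstat["ylag"])
  cv <- .df_critical_value(regression, alpha, f$nobs)
  det_coef <- det_tstat <- NA_real_
  if (regression %in% c("c", "ct")) {
    term <- if (regression == "ct") "trend" else "const"
    det_coef <- unname(f$coef[term])
    det_tstat <- unname(f$tstat[term])
  }
  list(statistic = stat, lag = as.integer(lags), nobs = f$nobs,
       critical_value = cv, reject = is.finite(stat) && stat < cv,
       det_coef = det_coef, det_tstat = det_tstat,
       const_tstat = if (regression == "ct") unname(f$tstat["const"]) else
         if (regression == "c") unname(f$tstat["const"]) else NA_real_,
       regression = regression)
}

#' Classify a series' form of stationarity
#'
#' Sequential Dickey-Fuller strategy over the three deterministic
#' specifications, mirroring the three categories used to screen the RT
#' series: fit with constant + trend; if the unit root is rejected and the
#' trend coefficient is significant (|t| > z at `alpha`), the series is
#' `stationary_around_trend`. Otherwise fit with a constant; if rejected
#' and the constant is significant, `stationary_around_mean`. Otherwise
#' fit without deterministic terms; if rejected, `stationary_around_zero`;
#' else `nonstationary`.
#'
#' @param y Numeric series (NA = missing).
#' @param alpha Significance level (default 0.05).
#' @param min_obs Minimum observed lag pairs required (default 20).
#' @param ... Passed to [adf_test()] (e.g. `lags`).
#' @return List of class `stationarity_verdict`: `classification`,
#'   `tests` (the three [adf_test()] results), `alpha`, `detrend`
#'   (TRUE when the trend specification won).
#' @export
adf_classify <- function(y, alpha = 0.05, min_obs = 20L, ...) {
  obs <- !is.na(y)
  n_pairs <- sum(obs[-1] & obs[-length(y)])
  if (n_pairs < min_obs) {
    return(structure(list(classification = "unclassifiable", tests = list(),
                          alpha = alpha, detrend = FALSE),
                     class = "stationarity_verdict"))
  }
  zcrit <- stats::qnorm(1 - alpha / 2)
  tests <- list()
  cls <- "nonstationary"
  detrend <- FALSE
  t_ct <- tryCatch(adf_test(y, "ct", alpha = alpha, ...),
                   error = function(e) NULL)
  tests$ct <- t_ct
  if (!is.null(t_ct) && t_ct$reject && abs(t_ct$det_tstat) > zcrit) {
    cls <- "stationary_around_trend"
    detrend <- TRUE
  } else {
    t_c <- tryCatch(adf_test(y, "c", alpha = alpha, ...),
                    error = function(e) NULL)
    tests$c <- t_c
    if (!is.null(t_c) && t_c$reject && abs(t_c$det_tstat) > zcrit) {
      cls <- "stationary_around_mean"
    } else {
      t_n <- tryCatch(adf_test(y, "n", alpha = alpha, ...),
                      error = function(e) NULL)
      tests$n <- t_n
      if (!is.null(t_n) && t_n$reject) cls <- "stationary_around_zero"
    }
  }
  structure(list(classification = cls, tests = tests, alpha = alpha,
                 detrend = detrend),
            class = "stationarity_verdict")
}

#' @export
print.stationarity_verdict <- function(x, ...) {
  cat("ADF classification:", x$classification, "\n")
  invisible(x)
}

#' Classify every person x block series
#'
#' @param clean The `clean` data.frame from [preprocess_dataset()].
#' @param alpha Significance level.
#' @param ... Passed to [adf_classify()].
#' @return Data.frame: `person`, `block_id`, `classification`,
#'   `statistic` (ADF t of the specification that decided the verdict, or
#'   of the constant specification for nonstationary series), `lag`.
#' @export
classify_all_series <- function(clean, alpha = 0.05, ...) {
  keys <- unique(clean[c("person", "block_id")])
  rows <- vector("list", nrow(keys))
  for (k in seq_len(nrow(keys))) {
    y <- series_vector(clean, keys$person[k], keys$block_id[k])
    v <- adf_classify(y, alpha = alpha, ...)
    pick <- switch(v$classification,
                   stationary_around_trend = v$tests$ct,
                   stationary_around_mean = v$tests$c,
                   stationary_around_zero = v$tests$n,
                   v$tests$c)
    rows[[k]] <- data.frame(
      person = keys$person[k], block_id = keys$block_id[k],
      classification = v$classification,
      statistic = if (is.null(pick)) NA_real_ else pick$statistic,
      lag = if (is.null(pick)) NA_integer_ else pick$lag)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Apply the exclusion rule to stationarity verdicts
#'
#' Persons with any series stationary around zero (an RT series varying
#' around a mean of zero is physiologically impossible and flags corrupt
#' recordings) or unclassifiable are excluded from model fitting; persons
#' with a trend verdict are flagged for detrending.
#'
#' @param verdicts Data.frame from [classify_all_series()].
#' @return List: `kept`, `excluded` (person ids), `detrend_flagged`
#'   (person/block_id rows needing detrending). Idempotent: applying the
#'   rule to the kept subset changes nothing.
#' @export
apply_exclusion <- function(verdicts) {
  bad <- unique(verdicts$person[
    verdicts$classification %in% c("stationary_around_zero", "unclassifiable")])
  trend <- verdicts[verdicts$classification == "stationary_around_trend",
                    c("person", "block_id")]
  list(kept = sort(setdiff(unique(verdicts$person), bad)),
       excluded = sort(bad),
       detrend_flagged = trend)
}

#' Remove a linear trend from a series
#'
#' OLS fit of the observed values on the trial index, subtracted from the
#' series; applied before model fitting to any series whose stationarity
#' verdict was "around a trend".
#'
#' @param y Numeric series (NA = missing).
#' @return Detrended series with the fitted mean level retained (only the
#'   slope component is removed).
#' @export
detrend_series <- function(y) {
  t_idx <- seq_along(y)
  obs <- !is.na(y)
  if (sum(obs) < 3) return(y)
  fit <- stats::lm.fit(cbind(1, t_idx[obs]), y[obs])
  slope <- fit$coefficients[2]
  y - slope * (t_idx - mean(t_idx[obs]))
}
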