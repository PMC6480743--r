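#' Descriptive error-rate table
#'
#' Per-block means and SDs of commission errors and prospective omissions,
#' plus failure rates pooled over the two blocks of each task version:
#' `pooled rate = (mean block-1 count + mean block-2 count) / 2 / 13`,
#' the 13 being the eligible NoGo (or prospective) trials per block.
#' Prospective-memory accuracy is 1 minus the pooled omission rate.
#'
#' @param persons Person-by-block table with `block_id`, `ce`, `po`
#'   columns ([count_errors()] output joined to block ids also works).
#' @param max_count Eligible trials per block (default 13).
#' @return List: `by_block` (data.frame block_id, ce_mean, ce_sd, po_mean,
#'   po_sd), `pooled` (data.frame task, ce_rate, po_rate, pm_accuracy).
#' @export
error_rate_table <- function(persons, max_count = 13) {
  agg <- do.call(rbind, lapply(split(persons, persons$block_id), function(d) {
    data.frame(block_id = d$block_id[1],
               ce_mean = mean(d$ce), ce_sd = stats::sd(d$ce),
               po_mean = if (all(is.na(d$po))) NA_real_ else
                 mean(d$po, na.rm = TRUE),
               po_sd = if (all(is.na(d$po))) NA_real_ else
                 stats::sd(d$po, na.rm = TRUE))
  }))
  rownames(agg) <- NULL
  task_of <- function(b) sub("[0-9]+$", "", b)
  pooled <- do.call(rbind, lapply(split(agg, task_of(agg$block_id)),
                                  function(d) {
    ce_rate <- mean(d$ce_mean) / max_count
    po_rate <- if (all(is.na(d$po_mean))) NA_real_ else
      mean(d$po_mean, na.rm = TRUE) / max_count
    data.frame(task = task_of(d$block_id[1]), ce_rate = ce_rate,
               po_rate = po_rate,
               pm_accuracy = if (is.na(po_rate)) NA_real_ else 1 - po_rate)
  }))
  rownames(pooled) <- NULL
  list(by_block = agg, pooled = pooled)
}

#' Wilcoxon signed-rank test with Pratt zeros and Bonferroni correction
#'
#' Paired two-sided test using the normal approximation with tie
#' correction and continuity correction. Zero differences are handled by
#' the Pratt method: they take part in the ranking of absolute differences
#' but are dropped from the rank sum, which is the conservative choice for
#' count data with many zero differences. The two-sided p-value is
#' multiplied by `n_tests` and capped at 1.
#'
#' @param x,y Paired numeric vectors.
#' @param n_tests Bonferroni multiplier (default 1).
#' @return List: `z`, `p_raw`, `p_corrected`, `n_nonzero`, `statistic`
#'   (the positive-rank sum W+). All-zero differences give `z = 0`,
#'   `p_corrected = 1` and an `undefined = TRUE` flag.
#' @export
wilcoxon_signed_rank <- function(x, y, n_tests = 1L) {
  d <- x - y
  d <- d[!is.na(d)]
  n <- length(d)
  if (n < 1L) stop("no paired observations")
  if (all(d == 0)) {
    return(list(z = 0, p_raw = 1, p_corrected = 1, n_nonzero = 0L,
                statistic = 0, undefined = TRUE))
  }
  r <- rank(abs(d))                 # zeros included in the ranking (Pratt)
  nz <- d != 0
  n0 <- sum(!nz)
  Wpos <- sum(r[d > 0])
  # moments under H0 with zeros removed from the sum (Pratt 1959)
  EW <- (n * (n + 1) / 2 - n0 * (n0 + 1) / 2) / 2
  varW <- (n * (n + 1) * (2 * n + 1) - n0 * (n0 + 1) * (2 * n0 + 1)) / 24
  ties <- table(r[nz])
  ties <- ties[ties > 1]
  if (length(ties)) varW <- varW - sum(ties^3 - ties) / 48
  if (varW <= 0) {
    return(list(z = 0, p_raw = 1, p_corrected = 1, n_nonzero = sum(nz),
                statistic = Wpos, undefined = TRUE))
  }
  dev <- Wpos - EW
  cc <- if (dev > 0) -0.5 else if (dev < 0) 0.5 else 0  # continuity corr.
  z <- (dev + cc) / sqrt(varW)
  p <- 2 * stats::pnorm(-abs(z))
  list(z = z, p_raw = p, p_corrected = min(p * n_tests, 1),
       n_nonzero = sum(nz), statistic = Wpos, undefined = FALSE)
}

#' Back-transform a log-RT value to milliseconds
#'
#' Exact inverse of the preprocessing log transform, reported to 2
#' decimals: `exp(6.25)` is 518.01 ms, `exp(6.38)` is 589.93 ms.
#'
#' @param log_value Value(s) on the natural-log scale.
#' @param digits Rounding (default 2; `Inf` for no rounding).
#' @return Milliseconds.
#' @export
backtransform_ms <- function(log_value, digits = 2) {
  ms <- exp(log_value)
  if (is.finite(digits)) round(ms, digits) else ms
}

#' Render publication-style tables
#'
#' Formats the descriptive error table ("table1"), the single-block
#' fixed/random-effect summaries ("table2"), and the error-regression
#' summaries ("table3") as character data.frames with `estimate (ci_lower
#' to ci_upper)` cells and a significance star when the 95% CI excludes 0.
#' Cells that do not exist for a block (prospective omissions in classical
#' blocks) render as `"na"`.
#'
#' @param error_summary [error_rate_table()] output (for table 1), or
#'   `NULL` to skip.
#' @param fit_summaries Named list (by block/model label) of
#'   [summary.dsem_fit()] data.frames for tables 2-3, or `NULL`.
#' @return List of character data.frames: `table1`, `table2`, `table3`
#'   (those with inputs present).
#' @export
render_tables <- function(error_summary = NULL, fit_summaries = NULL) {
  out <- list()
  fmt <- function(m, lo, hi, star) {
    ifelse(is.na(m), "na",
           sprintf("%.2f%s (%.2f to %.2f)", m, ifelse(star, " *", ""), lo, hi))
  }
  if (!is.null(error_summary)) {
    bb <- error_summary$by_block
    t1 <- data.frame(
      error_type = c("Commission errors", "Prospective omissions"))
    for (b in bb$block_id) {
      row <- bb[bb$block_id == b, ]
      t1[[b]] <- c(sprintf("%.2f (%.2f)", row$ce_mean, row$ce_sd),
                   if (is.na(row$po_mean)) "na" else
                     sprintf("%.2f (%.2f)", row$po_mean, row$po_sd))
    }
    out$table1 <- t1
  }
  if (!is.null(fit_summaries)) {
    t2_params <- c("gamma_mu", "var_mu", "gamma_phi", "var_phi",
                   "gamma_isd", "var_isd",
                   "r_mu_phi", "r_mu_isd", "r_phi_isd")
    t3_params <- c("beta_0", "beta_mu_std", "beta_phi_std", "beta_isd_std",
                   "r2_ce")
    grab <- function(s, params) {
      i <- match(params, s$parameter)
      fmt(s$mean[i], s$ci_lower[i], s$ci_upper[i],
          !is.na(s$significant[i]) & s$significant[i])
    }
    t2 <- data.frame(parameter = t2_params)
    t3 <- data.frame(parameter = t3_params)
    for (lbl in names(fit_summaries)) {
      t2[[lbl]] <- grab(fit_summaries[[lbl]], t2_params)
      t3[[lbl]] <- grab(fit_summaries[[lbl]], t3_params)
    }
    out$table2 <- t2
    out$table3 <- t3
  }
  out
}
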