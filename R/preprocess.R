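#' Drop the first trial of a block
#'
#' The first trial of every block shows a consistently inflated RT and is
#' excluded before any further processing. Remaining trials are relabeled
#' 1..(n-1); the original trial index is retained in `orig_trial` so the
#' actual position on the time axis is always recoverable.
#'
#' @param block_df Data.frame of one person x block, ordered by `trial`.
#' @return The data.frame without its first trial, with `trial` relabeled
#'   and `orig_trial` added. A zero-row result (single-trial input) carries
#'   attribute `"empty_series" = TRUE`.
#' @export
drop_first_trial <- function(block_df) {
  if (nrow(block_df) < 1L) stop("empty block: nothing to drop")
  out <- block_df[-1L, , drop = FALSE]
  out$orig_trial <- out$trial
  out$trial <- seq_len(nrow(out))
  rownames(out) <- NULL
  if (nrow(out) == 0L) attr(out, "empty_series") <- TRUE
  out
}

#' Trim extreme RTs at 3 intraindividual standard deviations
#'
#' Replaces values lying below or above 3 SDs from the mean with `NA`.
#' Mean and SD are computed once over the observed values of the input
#' (single pass; no re-computation after removal), per person per block, on
#' raw (untransformed) RTs of correct trials. With fewer than 2 observed
#' values, or a zero SD, nothing is trimmed.
#'
#' @param rt Numeric vector of raw RTs (NA = no response / incorrect).
#' @param n_sd Trim threshold in SD units (default 3).
#' @return `rt` with trimmed values set to `NA`; attributes `"n_trimmed"`
#'   and `"trim_fraction"` (relative to observed values).
#' @export
trim_outliers <- function(rt, n_sd = 3) {
  obs <- !is.na(rt)
  n_obs <- sum(obs)
  if (n_obs < 2L) {
    warning("fewer than 2 observed values: no trimming applied")
    attr(rt, "n_trimmed") <- 0L
    attr(rt, "trim_fraction") <- 0
    return(rt)
  }
  m <- mean(rt[obs])
  s <- stats::sd(rt[obs])
  out <- rt
  n_trimmed <- 0L
  if (s > 0) {
    bad <- obs & (rt < m - n_sd * s | rt > m + n_sd * s)
    out[bad] <- NA_real_
    n_trimmed <- sum(bad)
  }
  attr(out, "n_trimmed") <- n_trimmed
  attr(out, "trim_fraction") <- n_trimmed / n_obs
  out
}

#' Natural-log transform of RTs
#'
#' @param rt Numeric vector of raw RTs in ms; `NA` stays `NA`.
#' @return `log(rt)`.
#' @export
log_transform <- function(rt) {
  bad <- which(!is.na(rt) & rt <= 0)
  if (length(bad)) {
    stop("nonpositive RT at position(s) ", paste(bad, collapse = ", "),
         ": cannot log-transform")
  }
  log(rt)
}

#' Intraindividual standard deviation of a log-RT series
#'
#' Sample SD (denominator n - 1) over the observed values of one person's
#' block series; the net-variability measure of the analysis.
#'
#' @param x Numeric vector with `NA` for missing trials.
#' @return The iSD, or `NA` (with a warning) when fewer than 2 values are
#'   observed.
#' @export
compute_isd <- function(x) {
  obs <- x[!is.na(x)]
  if (length(obs) < 2L) {
    warning("fewer than 2 observed values: iSD undefined")
    return(NA_real_)
  }
  stats::sd(obs)
}

#' Preprocess a trial table into analysis-ready series
#'
#' Applies the fixed pipeline per person x block: RTs of incorrect trials
#' are set missing, the first trial is dropped, raw RTs are trimmed at
#' mean +/- 3 SD, values are log-transformed, and the iSD is computed over
#' the observed log-RTs. The order (drop-first, trim on raw, then log) is
#' part of the contract; trimming after the log transform would select
#' different trials.
#'
#' @param trials Long-format trial data.frame as produced by
#'   [assemble_dataset()] (columns `person`, `block_id`, `trial`, `rt_ms`,
#'   `correct`).
#' @return List of class `gng_clean`:
#'   * `clean`: data.frame `person`, `block_id`, `trial` (1..116),
#'     `orig_trial`, `log_rt` (NA = missing);
#'   * `isd`: data.frame `person`, `block_id`, `isd`, `n_observed`;
#'   * `trim_report`: per-series trim counts/fractions plus the overall
#'     fraction per block id.
#' @export
preprocess_dataset <- function(trials) {
  req <- c("person", "block_id", "trial", "rt_ms", "correct")
  if (!all(req %in% names(trials))) {
    stop("trials must contain columns: ", paste(req, collapse = ", "))
  }
  trials <- trials[order(trials$block_id, trials$person, trials$trial), ]
  key <- interaction(trials$person, trials$block_id, drop = TRUE)
  parts <- split(trials, key)
  clean_list <- vector("list", length(parts))
  isd_list <- vector("list", length(parts))
  trim_list <- vector("list", length(parts))
  for (k in seq_along(parts)) {
    df <- parts[[k]]
    rt <- df$rt_ms
    rt[!df$correct] <- NA_real_       # only correct-trial RTs are analyzed
    df$rt_ms <- rt
    df <- drop_first_trial(df)
    rt <- trim_outliers(df$rt_ms)
    log_rt <- log_transform(as.numeric(rt))
    isd <- suppressWarnings(compute_isd(log_rt))
    clean_list[[k]] <- data.frame(
      person = df$person, block_id = df$block_id, trial = df$trial,
      orig_trial = df$orig_trial, log_rt = log_rt)
    isd_list[[k]] <- data.frame(
      person = df$person[1], block_id = df$block_id[1], isd = isd,
      n_observed = sum(!is.na(log_rt)))
    trim_list[[k]] <- data.frame(
      person = df$person[1], block_id = df$block_id[1],
      n_trimmed = attr(rt, "n_trimmed"),
      trim_fraction = attr(rt, "trim_fraction"))
  }
  clean <- do.call(rbind, clean_list)
  rownames(clean) <- NULL
  isd <- do.call(rbind, isd_list)
  rownames(isd) <- NULL
  trim <- do.call(rbind, trim_list)
  rownames(trim) <- NULL
  overall <- stats::aggregate(n_trimmed ~ block_id, data = trim, FUN = sum)
  n_obs_blk <- stats::aggregate(n_observed ~ block_id, data = isd, FUN = sum)
  overall$fraction <- overall$n_trimmed /
    (n_obs_blk$n_observed[match(overall$block_id, n_obs_blk$block_id)] +
       overall$n_trimmed)
  structure(list(clean = clean, isd = isd,
                 trim_report = list(per_series = trim, per_block = overall)),
            class = "gng_clean")
}

#' @export
print.gng_clean <- function(x, ...) {
  cat(sprintf("Preprocessed series: %d person-blocks, %.2f%% trials trimmed overall\n",
              nrow(x$isd),
              100 * sum(x$trim_report$per_series$n_trimmed) /
                max(1, sum(x$isd$n_observed) +
                      sum(x$trim_report$per_series$n_trimmed))))
  invisible(x)
}

#' Extract one person-block series as a time-indexed vector
#'
#' @param clean The `clean` data.frame from [preprocess_dataset()].
#' @param person,block_id Series selector.
#' @return Numeric vector (length = trials in the block, usually 116) with
#'   `NA` at missing trials.
#' @export
series_vector <- function(clean, person, block_id) {
  df <- clean[clean$person == person & clean$block_id == block_id, ]
  if (!nrow(df)) stop("no such series: person ", person, ", ", block_id)
  df$log_rt[order(df$trial)]
}
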