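#' Potential scale reduction (PSR) per parameter
#'
#' Gelman-Rubin-style statistic over two or more equal-length chains:
#' `PSR = sqrt((W + B/n) / W)` with `W` the mean within-chain variance and
#' `B` the between-chain variance of chain means (times n). This
#' conservative variant is never below 1 and equals 1 exactly when the
#' chains are identical. Parameters that are numerically constant in all
#' chains get PSR 1.
#'
#' @param draws A `dsem_fit`, or a list of draw matrices with identical
#'   column names (one matrix per chain).
#' @param threshold Flagging threshold (default 1.1).
#' @return Named numeric vector of PSR values; attribute `"flagged"` lists
#'   parameters with PSR above `threshold`.
#' @export
compute_psr <- function(draws, threshold = 1.1) {
  if (inherits(draws, "dsem_fit")) draws <- draws$draws
  if (!is.list(draws) || length(draws) < 2L) {
    stop("PSR needs draws from at least 2 chains")
  }
  n <- min(vapply(draws, nrow, 1L))
  draws <- lapply(draws, function(d) d[seq_len(n), , drop = FALSE])
  m <- length(draws)
  psr <- vapply(colnames(draws[[1]]), function(p) {
    x <- vapply(draws, function(d) d[, p], numeric(n))   # n x m
    W <- mean(apply(x, 2, stats::var))
    B <- n * stats::var(colMeans(x))
    if (!is.finite(W) || W <= 0) {
      if (is.finite(B) && B <= 1e-300) return(1)  # constant everywhere
      return(NA_real_)
    }
    sqrt((W + B / n) / W)
  }, 1)
  attr(psr, "flagged") <- names(psr)[!is.na(psr) & psr > threshold]
  psr
}

# per-draw standardized parameters for a single-block fit
.standardize_single <- function(d, scales, block_id, with_errors) {
  sd_isd <- scales[[paste0("sd_isd.", block_id)]]
  out <- cbind(
    r_mu_phi = d[, "cov_mu_phi"] / sqrt(d[, "var_mu"] * d[, "var_phi"]),
    r_mu_isd = d[, "cov_mu_isd"] / sqrt(d[, "var_mu"] * d[, "var_isd"]),
    r_phi_isd = d[, "cov_phi_isd"] / sqrt(d[, "var_phi"] * d[, "var_isd"]))
  if (with_errors) {
    sd_ce <- scales[[paste0("sd_ce.", block_id)]]
    out <- cbind(
      out,
      beta_mu_std = d[, "beta_mu"] * d[, "sd_mu"] / sd_ce,
      beta_phi_std = d[, "beta_phi"] * d[, "sd_phi"] / sd_ce,
      beta_isd_std = d[, "beta_isd"] * sd_isd / sd_ce)
  }
  out
}

.standardize_two <- function(d, scales, ids, with_covariate) {
  id1 <- ids[1]; id2 <- ids[2]
  s1 <- paste0(".", id1); s2 <- paste0(".", id2)
  sd_isd1 <- scales[[paste0("sd_isd.", id1)]]
  sd_isd2 <- scales[[paste0("sd_isd.", id2)]]
  sd_ce1 <- scales[[paste0("sd_ce.", id1)]]
  sd_ce2 <- scales[[paste0("sd_ce.", id2)]]
  sd_po <- scales[[paste0("sd_po.", id2)]]
  g <- function(nm) d[, nm]
  sd1 <- list(mu = g(paste0("sd_mu", s1)), phi = g(paste0("sd_phi", s1)),
              isd = sd_isd1)
  sd2 <- list(mu = g(paste0("sd_mu", s2)), phi = g(paste0("sd_phi", s2)),
              isd = sd_isd2)
  out <- cbind(
    r_mu_phi = g(paste0("cov_mu_phi", s1)) /
      sqrt(g(paste0("var_mu", s1)) * g(paste0("var_phi", s1))),
    r_mu_isd = g(paste0("cov_mu_isd", s1)) /
      sqrt(g(paste0("var_mu", s1)) * g(paste0("var_isd", s1))),
    r_phi_isd = g(paste0("cov_phi_isd", s1)) /
      sqrt(g(paste0("var_phi", s1)) * g(paste0("var_isd", s1))),
    r_resid_mu_phi = g(paste0("rcov_mu_phi", s2)) /
      sqrt(g(paste0("rvar_mu", s2)) * g(paste0("rvar_phi", s2))),
    r_resid_mu_isd = g(paste0("rcov_mu_isd", s2)) /
      sqrt(g(paste0("rvar_mu", s2)) * g(paste0("rvar_isd", s2))),
    r_resid_phi_isd = g(paste0("rcov_phi_isd", s2)) /
      sqrt(g(paste0("rvar_phi", s2)) * g(paste0("rvar_isd", s2))))
  cols <- list()
  for (o in c("mu", "phi", "isd")) {
    for (p in c("mu", "phi", "isd")) {
      nm <- paste0(o, s2, "_on_", p, s1)
      cols[[paste0(nm, "_std")]] <- g(nm) * sd1[[p]] / sd2[[o]]
    }
  }
  for (p in c("mu", "phi", "isd")) {
    nm <- paste0("ce", s1, "_on_", p)
    cols[[paste0(nm, "_std")]] <- g(nm) * sd1[[p]] / sd_ce1
    nm <- paste0("ce", s2, "_on_", p)
    cols[[paste0(nm, "_std")]] <- g(nm) * sd2[[p]] / sd_ce2
    nm <- paste0("po", s2, "_on_", p)
    cols[[paste0(nm, "_std")]] <- g(nm) * sd2[[p]] / sd_po
  }
  cols[[paste0("ce", s2, "_on_ce", s1, "_std")]] <-
    g(paste0("ce", s2, "_on_ce", s1)) * sd_ce1 / sd_ce2
  cols[[paste0("po", s2, "_on_ce", s2, "_std")]] <-
    g(paste0("po", s2, "_on_ce", s2)) * sd_ce2 / sd_po
  if (with_covariate) {
    sd_lns <- scales$sd_lns
    cols[[paste0("ce", s1, "_on_lns_std")]] <-
      g(paste0("ce", s1, "_on_lns")) * sd_lns / sd_ce1
    cols[[paste0("ce", s2, "_on_lns_std")]] <-
      g(paste0("ce", s2, "_on_lns")) * sd_lns / sd_ce2
    cols[[paste0("po", s2, "_on_lns_std")]] <-
      g(paste0("po", s2, "_on_lns")) * sd_lns / sd_po
  }
  cbind(out, do.call(cbind, cols))
}

#' Standardized coefficient draws
#'
#' Converts level-2 covariance draws to correlations (dividing by the SD
#' product per draw) and regression-weight draws to standardized weights
#' (`raw * SD(predictor) / SD(outcome)` per draw). SDs of latent random
#' effects are the per-draw sample SDs of the person-level draws; SDs of
#' observed variables (iSD, error counts, covariate) are sample SDs of the
#' data. This is the package's own standardization convention; raw draws
#' remain available alongside.
#'
#' @param fit A [dsem_fit()] result.
#' @return List of matrices of standardized draws, one per chain.
#' @export
standardize <- function(fit) {
  stopifnot(inherits(fit, "dsem_fit"))
  variant <- fit$model$spec$variant
  lapply(fit$draws, function(d) {
    switch(variant,
           single_block =
             .standardize_single(d, fit$scales, fit$model$blocks[[1]]$id,
                                 FALSE),
           single_block_with_errors =
             .standardize_single(d, fit$scales, fit$model$blocks[[1]]$id,
                                 TRUE),
           two_block =
             .standardize_two(d, fit$scales, fit$model$spec$blocks, FALSE),
           two_block_with_covariate =
             .standardize_two(d, fit$scales, fit$model$spec$blocks, TRUE))
  })
}

#' Posterior summary table
#'
#' Pools retained draws over chains and reports, per parameter, the
#' posterior mean, central 95% credible interval, a significance flag (the
#' interval excludes 0), and the PSR convergence statistic (NA with a
#' single chain). Standardized parameters (correlations, standardized
#' regression weights) are appended with `standardized = TRUE`.
#'
#' @param object A [dsem_fit()] result.
#' @param prob Credible-interval mass (default 0.95).
#' @param ... Unused.
#' @return Data.frame: `parameter`, `mean`, `ci_lower`, `ci_upper`,
#'   `significant`, `psr`, `standardized`.
#' @export
summary.dsem_fit <- function(object, prob = 0.95, ...) {
  raw <- object$draws
  std <- standardize(object)
  tab_for <- function(chains, standardized) {
    pooled <- do.call(rbind, chains)
    psr <- if (length(chains) >= 2L) compute_psr(chains) else
      stats::setNames(rep(NA_real_, ncol(pooled)), colnames(pooled))
    a <- (1 - prob) / 2
    data.frame(
      parameter = colnames(pooled),
      mean = colMeans(pooled),
      ci_lower = apply(pooled, 2, stats::quantile, probs = a, names = FALSE),
      ci_upper = apply(pooled, 2, stats::quantile, probs = 1 - a,
                       names = FALSE),
      psr = as.numeric(psr[colnames(pooled)]),
      standardized = standardized,
      row.names = NULL)
  }
  out <- rbind(tab_for(raw, FALSE), tab_for(std, TRUE))
  out$significant <- out$ci_lower > 0 | out$ci_upper < 0
  out[c("parameter", "mean", "ci_lower", "ci_upper", "significant", "psr",
        "standardized")]
}

#' Split one block's series into two contiguous segments
#'
#' Partitions the time axis of a block at `cut`: trials `1..cut` become
#' `<block_id>a`, trials `cut+1..T` become `<block_id>b`. Original trial
#' indices are preserved in `orig_trial`; within-segment `trial` indices
#' restart at 1, so AR lag pairs never cross the cut. Used to compare
#' early- versus late-block dynamics by fitting the two halves as separate
#' blocks.
#'
#' @param prep A [preprocess_dataset()] result.
#' @param block_id Block to split.
#' @param cut Last trial index of the first segment (default: half).
#' @param min_len Minimum admissible segment length (default 2).
#' @return A new `gng_clean` object in which `block_id` is replaced by the
#'   two segment blocks (iSD and trim tables recomputed per segment).
#' @export
split_block <- function(prep, block_id, cut = NULL, min_len = 2L) {
  clean <- prep$clean
  sub <- clean[clean$block_id == block_id, ]
  if (!nrow(sub)) stop("block not present: ", block_id)
  T_ <- max(sub$trial)
  if (is.null(cut)) cut <- T_ %/% 2L
  if (cut < 1L || cut >= T_) stop("cut must lie strictly inside 1..", T_)
  if (cut < min_len || T_ - cut < min_len) {
    stop("degenerate segment: both halves need >= ", min_len, " trials")
  }
  first <- sub$trial <= cut
  a <- sub[first, ]; b <- sub[!first, ]
  a$block_id <- paste0(block_id, "a")
  b$block_id <- paste0(block_id, "b")
  b$trial <- b$trial - cut
  rest <- clean[clean$block_id != block_id, ]
  new_clean <- rbind(rest, a, b)
  new_clean <- new_clean[order(new_clean$block_id, new_clean$person,
                               new_clean$trial), ]
  rownames(new_clean) <- NULL
  # recompute iSD per (possibly new) series
  keys <- unique(new_clean[c("person", "block_id")])
  isd <- do.call(rbind, lapply(seq_len(nrow(keys)), function(k) {
    y <- series_vector(new_clean, keys$person[k], keys$block_id[k])
    data.frame(person = keys$person[k], block_id = keys$block_id[k],
               isd = suppressWarnings(compute_isd(y)),
               n_observed = sum(!is.na(y)))
  }))
  rownames(isd) <- NULL
  structure(list(clean = new_clean, isd = isd,
                 trim_report = prep$trim_report),
            class = "gng_clean")
}
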