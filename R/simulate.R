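#' Simulate one AR(1) reaction-time series
#'
#' Generates `RT_t = mu + x_t` with `x_t = phi * x_(t-1) + zeta_t`, where the
#' innovation SD is `sigma_zeta = isd * sqrt(1 - phi^2)` so that the
#' stationary SD of the process equals the person's fluctuation amplitude
#' `isd`. The initial state is drawn from the stationary distribution.
#' By default the process lives on the log-millisecond scale (the scale the
#' model is fitted on); `scale = "ms"` generates directly in raw
#' milliseconds, which is how the illustrative phi-by-iSD regime figures
#' are produced.
#'
#' @param mu Person mean (log-ms, or ms when `scale = "ms"`).
#' @param phi Lag-1 autoregressive coefficient, `|phi| < 1`.
#' @param isd Stationary SD of the process (> 0 unless the series is
#'   constant).
#' @param n_trials Series length.
#' @param seed Optional integer seed.
#' @param scale `"log"` (default) or `"ms"`.
#' @return Numeric vector of length `n_trials`; attribute `"sigma_zeta"`
#'   holds the innovation SD.
#' @examples
#' y <- simulate_rt_series(600, 0.7, 40, 1000, seed = 1, scale = "ms")
#' sd(y); cor(y[-1], y[-1000])
#' @export
simulate_rt_series <- function(mu, phi, isd, n_trials, seed = NULL,
                               scale = c("log", "ms")) {
  scale <- match.arg(scale)
  if (!is.null(seed)) set.seed(seed)
  if (abs(phi) >= 1) {
    stop("|phi| >= 1: nonstationary series must be requested explicitly ",
         "via trend injection, not through the AR coefficient")
  }
  if (isd < 0) stop("isd must be >= 0")
  sigma_zeta <- isd * sqrt(1 - phi^2)
  x1 <- stats::rnorm(1, 0, isd)
  if (n_trials == 1L) {
    x <- x1
  } else {
    innov <- stats::rnorm(n_trials - 1L, 0, sigma_zeta)
    x <- c(x1, stats::filter(innov, phi, method = "recursive", init = x1))
  }
  structure(mu + as.numeric(x), sigma_zeta = sigma_zeta)
}

#' Simulate per-person error counts
#'
#' Commission errors follow the level-2 linear model
#' `CE = beta0 + beta_mu * mu + beta_phi * phi + beta_isd * iSD
#'  (+ beta_lns * LNS) + e`, with Gaussian residual, rounded to the nearest
#' integer (base-R `round`) and clipped to `[0, max_count]`. Prospective
#' omissions use the analogous predictor including the realized commission
#' count. Clipping and rounding bias the realized moments slightly relative
#' to the linear model; this is intentional fidelity to count data bounded
#' by the 13 eligible trials per block.
#'
#' @param person One-row data.frame (or list) with `mu`, `phi`, `isd`, and
#'   optionally `lns`.
#' @param pop A [population_parameters()].
#' @param seed Optional seed.
#' @param prospective Generate a prospective-omission count too?
#' @param max_count Maximum per-block count (13 eligible trials).
#' @return List with integer `ce` and (if `prospective`) integer `po`.
#' @export
simulate_errors <- function(person, pop, seed = NULL, prospective = FALSE,
                            max_count = 13L) {
  stopifnot(inherits(pop, "population_parameters"))
  if (!is.null(seed)) set.seed(seed)
  lns_term <- if (!is.null(person$lns)) pop$beta_lns * person$lns else 0
  lin <- pop$beta0 + pop$beta_mu * person$mu + pop$beta_phi * person$phi +
    pop$beta_isd * person$isd + lns_term +
    stats::rnorm(length(person$mu), 0, pop$sigma_e)
  ce <- pmin(pmax(round(lin), 0), max_count)
  out <- list(ce = as.integer(ce))
  if (prospective) {
    lin_po <- pop$po_beta0 + pop$po_beta_mu * person$mu +
      pop$po_beta_phi * person$phi + pop$po_beta_isd * person$isd +
      pop$po_beta_ce * ce + lns_term +
      stats::rnorm(length(person$mu), 0, pop$po_sigma_e)
    out$po <- as.integer(pmin(pmax(round(lin_po), 0), max_count))
  }
  out
}

.block_info <- function(block_id) {
  task <- if (grepl("^C", block_id)) "classical" else "prospective"
  list(task = task, block = as.integer(sub("^\\D+", "", block_id)))
}

#' Assemble a full simulated study dataset
#'
#' Generates a long-format trial table plus person-level tables for a cohort
#' performing the requested blocks (default: the full study design CGNG1,
#' CGNG2, PGNG1, PGNG2 of 117 trials each). Per block, person triples are
#' drawn from that block's [population_parameters()], an admissible trial
#' sequence is generated, a log-scale AR(1) series is simulated, and error
#' counts are drawn and reconciled with the sequence: commission errors are
#' assigned to randomly chosen NoGo trials (which then carry an RT and
#' `correct = FALSE`), correct NoGo trials have no RT, and prospective
#' omissions mark randomly chosen prospective trials incorrect (the ongoing
#' Go response and its RT remain). Go trials can optionally be marked
#' incorrect at a small `stray_error_rate` to exercise missingness handling.
#'
#' @param pop A single [population_parameters()] (recycled over blocks) or a
#'   named list with one element per block id; default
#'   [default_population()].
#' @param n_persons Cohort size (the study analyzed 87).
#' @param blocks Block identifiers to emit.
#' @param seed Integer seed; the whole dataset is a deterministic function
#'   of it.
#' @param lns_mean,lns_sd Working-memory (LNS) covariate distribution
#'   (study sample: mean 9.41, SD 2.36).
#' @param stray_error_rate Probability that a Go trial is answered
#'   incorrectly (default 0).
#' @param pm_rt_offset Additive log-scale RT offset on prospective trials
#'   (default 0: prospective RTs behave like Go RTs).
#' @return Object of class `gng_dataset`: list with `trials` (long-format
#'   data.frame: person, task, block, block_id, trial, trial_type, digit,
#'   color, font_size, rt_ms, correct), `persons` (person x block
#'   parameters and error counts), `truth` (generating parameters), `seed`.
#' @export
assemble_dataset <- function(pop = default_population(), n_persons = 87,
                             blocks = c("CGNG1", "CGNG2", "PGNG1", "PGNG2"),
                             seed = 1L, lns_mean = 9.41, lns_sd = 2.36,
                             stray_error_rate = 0, pm_rt_offset = 0) {
  if (inherits(pop, "population_parameters")) {
    pop <- stats::setNames(rep(list(pop), length(blocks)), blocks)
  }
  if (!all(blocks %in% names(pop))) {
    stop("pop must provide parameters for every requested block")
  }
  set.seed(seed)
  lns <- stats::rnorm(n_persons, lns_mean, lns_sd)

  trial_rows <- vector("list", length(blocks))
  person_rows <- vector("list", length(blocks))
  for (b in seq_along(blocks)) {
    bid <- blocks[b]
    info <- .block_info(bid)
    bpop <- pop[[bid]]
    design <- block_design(info$task)
    pers <- sample_person_parameters(bpop, n_persons)
    pers$lns <- lns
    err <- simulate_errors(pers, bpop, prospective = info$task == "prospective")
    pers$ce <- err$ce
    pers$po <- if (is.null(err$po)) NA_integer_ else err$po

    blk <- vector("list", n_persons)
    for (i in seq_len(n_persons)) {
      sq <- generate_trial_sequence(design)
      y <- simulate_rt_series(pers$mu[i], pers$phi[i], pers$isd[i],
                              design$n_trials)
      if (pm_rt_offset != 0) {
        y[sq$trial_type == "prospective"] <-
          y[sq$trial_type == "prospective"] + pm_rt_offset
      }
      rt <- exp(as.numeric(y))
      correct <- rep(TRUE, design$n_trials)
      nogo_idx <- which(sq$trial_type == "nogo")
      ce_idx <- if (pers$ce[i] > 0) sample(nogo_idx, pers$ce[i]) else integer()
      correct[ce_idx] <- FALSE                    # failed inhibition: RT kept
      rt[setdiff(nogo_idx, ce_idx)] <- NA_real_   # correct NoGo: no response
      if (info$task == "prospective" && pers$po[i] > 0) {
        pm_idx <- which(sq$trial_type == "prospective")
        correct[sample(pm_idx, pers$po[i])] <- FALSE  # omitted cue action
      }
      if (stray_error_rate > 0) {
        go_idx <- which(sq$trial_type == "go")
        stray <- go_idx[stats::runif(length(go_idx)) < stray_error_rate]
        correct[stray] <- FALSE
      }
      blk[[i]] <- data.frame(
        person = i, task = info$task, block = info$block, block_id = bid,
        trial = seq_len(design$n_trials), trial_type = sq$trial_type,
        digit = sq$digit, color = sq$color, font_size = sq$font_size,
        rt_ms = rt, correct = correct)
    }
    trial_rows[[b]] <- do.call(rbind, blk)
    person_rows[[b]] <- data.frame(
      person = pers$person, task = info$task, block = info$block,
      block_id = bid, mu = pers$mu, phi = pers$phi, isd = pers$isd,
      ce = pers$ce, po = pers$po, lns = pers$lns)
  }
  structure(
    list(trials = do.call(rbind, trial_rows),
         persons = do.call(rbind, person_rows),
         truth = pop[blocks], seed = seed),
    class = "gng_dataset")
}

#' @export
print.gng_dataset <- function(x, ...) {
  cat(sprintf("Simulated Go/NoGo dataset: %d persons, blocks %s, %d trial records (seed %d)\n",
              length(unique(x$persons$person)),
              paste(unique(x$persons$block_id), collapse = "/"),
              nrow(x$trials), x$seed))
  invisible(x)
}

#' Write a simulated dataset to plain-text files
#'
#' Emits `trials.csv` (long format), `persons.csv`, and `truth.json` (the
#' generating population parameters) into `dir`.
#'
#' @param dataset A [assemble_dataset()] result.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "gng_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("trials.csv", "persons.csv", "truth.json"))
  utils::write.csv(dataset$trials, paths[1], row.names = FALSE)
  utils::write.csv(dataset$persons, paths[2], row.names = FALSE)
  truth <- lapply(dataset$truth, function(p) {
    p$cov_matrix <- NULL   # reconstructable from variances + correlations
    unclass(p)
  })
  jsonlite::write_json(list(seed = dataset$seed, population = truth),
                       paths[3], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read a trial table written by [write_dataset()]
#'
#' @param path Path to `trials.csv`.
#' @return The long-format trial data.frame.
#' @export
read_trials <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
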