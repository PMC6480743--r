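#' Declare a DSEM variant to fit
#'
#' A model spec names which blocks enter the model and which level-2
#' regressions are included:
#' * `"single_block"`: within-person AR(1) with random mean and
#'   autoregression, jointly distributed with the observed iSD (the M1-M4
#'   structure);
#' * `"single_block_with_errors"`: adds the regression of the block's
#'   commission-error count on (mu_i, phi_i, iSD_i) (M5-M8);
#' * `"two_block"`: two AR(1) blocks; the later block's triple is regressed
#'   on the earlier block's triple, commission errors are predicted within
#'   each block (the later block's additionally by the earlier block's
#'   count), and prospective omissions in the later (prospective) block are
#'   predicted by its triple and its commission count (M9);
#' * `"two_block_with_covariate"`: M9 plus a person-level covariate (the
#'   LNS working-memory score) predicting all three error counts (M10).
#'
#' @param variant One of the four variants above.
#' @param blocks Character vector of block ids: one for single-block
#'   variants, `c(earlier, later)` for two-block variants.
#' @param covariate Name of the covariate column in the persons table
#'   (default `"lns"`; only used by `two_block_with_covariate`).
#' @return Object of class `dsem_spec`.
#' @export
dsem_spec <- function(variant = c("single_block", "single_block_with_errors",
                                  "two_block", "two_block_with_covariate"),
                      blocks, covariate = "lns") {
  variant <- match.arg(variant)
  two <- grepl("^two_block", variant)
  if (two && length(blocks) != 2L) {
    stop("two-block variants name exactly two blocks (earlier, later)")
  }
  if (!two && length(blocks) != 1L) {
    stop("single-block variants name exactly one block")
  }
  structure(list(variant = variant, blocks = blocks, covariate = covariate),
            class = "dsem_spec")
}

#' The study's standard model ladder (M1-M10)
#'
#' @param name `"m1"` .. `"m10"`.
#' @return A [dsem_spec()]: m1-m4 are single-block models on CGNG1, CGNG2,
#'   PGNG1, PGNG2; m5-m8 add the commission-error regression on the same
#'   blocks; m9 is the two-block model (CGNG2 -> PGNG1); m10 adds the LNS
#'   covariate.
#' @export
standard_model <- function(name) {
  name <- tolower(name)
  blocks4 <- c("CGNG1", "CGNG2", "PGNG1", "PGNG2")
  if (name %in% paste0("m", 1:4)) {
    dsem_spec("single_block", blocks4[as.integer(substring(name, 2))])
  } else if (name %in% paste0("m", 5:8)) {
    dsem_spec("single_block_with_errors",
              blocks4[as.integer(substring(name, 2)) - 4L])
  } else if (name == "m9") {
    dsem_spec("two_block", c("CGNG2", "PGNG1"))
  } else if (name == "m10") {
    dsem_spec("two_block_with_covariate", c("CGNG2", "PGNG1"))
  } else {
    stop("unknown standard model: ", name)
  }
}

#' Count commission errors and prospective omissions from a trial table
#'
#' Commission errors are incorrect NoGo trials; prospective omissions are
#' incorrect prospective trials. Counting from trials keeps the fitting
#' pipeline independent of any generator-side bookkeeping.
#'
#' @param trials Long-format trial data.frame.
#' @return Data.frame `person`, `block_id`, `ce`, `po` (`NA` for blocks
#'   without prospective trials).
#' @export
count_errors <- function(trials) {
  key <- interaction(trials$person, trials$block_id, drop = TRUE)
  parts <- split(trials, key)
  rows <- lapply(parts, function(df) {
    has_pm <- any(df$trial_type == "prospective")
    data.frame(
      person = df$person[1], block_id = df$block_id[1],
      ce = sum(df$trial_type == "nogo" & !df$correct),
      po = if (has_pm) sum(df$trial_type == "prospective" & !df$correct)
           else NA_integer_)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$block_id, out$person), ]
  rownames(out) <- NULL
  out
}

# Assemble the T x N series matrix for one block, in person order.
.block_matrix <- function(clean, block_id, persons) {
  sub <- clean[clean$block_id == block_id, ]
  if (!nrow(sub)) stop("block not present in clean data: ", block_id)
  T_ <- max(sub$trial)
  Y <- matrix(NA_real_, T_, length(persons))
  for (j in seq_along(persons)) {
    s <- sub[sub$person == persons[j], ]
    if (!nrow(s)) stop("person ", persons[j], " missing from block ", block_id)
    Y[s$trial, j] <- s$log_rt
  }
  Y
}

#' Build the internal model object for a DSEM fit
#'
#' Validates the spec against the preprocessed data, removes excluded
#' persons, rejects persons with fewer than 2 observed trials in any named
#' block, and assembles the series matrices, observed iSDs, error counts,
#' and covariate the sampler needs.
#'
#' @param spec A [dsem_spec()].
#' @param prep A [preprocess_dataset()] result (or a list with `clean` and
#'   `isd` of the same shape).
#' @param errors Data.frame from [count_errors()] (or the generator's
#'   persons table with `ce`/`po` columns). Required for variants with
#'   error regressions.
#' @param covariates Optional data.frame `person`, `<covariate>` for
#'   `two_block_with_covariate`.
#' @param exclude Person ids to drop (e.g. `apply_exclusion()$excluded`).
#' @return Object of class `dsem_model`.
#' @export
build_model <- function(spec, prep, errors = NULL, covariates = NULL,
                        exclude = NULL) {
  stopifnot(inherits(spec, "dsem_spec"))
  clean <- prep$clean
  isd_tab <- prep$isd
  absent <- setdiff(spec$blocks, unique(clean$block_id))
  if (length(absent)) {
    stop("block(s) not present in clean data: ",
         paste(absent, collapse = ", "))
  }
  persons <- sort(unique(clean$person[clean$block_id %in% spec$blocks]))
  persons <- setdiff(persons, exclude)
  if (!length(persons)) stop("no persons left after exclusions")

  # reject persons with < 2 observed trials in any named block
  too_few <- integer()
  for (b in spec$blocks) {
    cnt <- isd_tab[isd_tab$block_id == b, ]
    bad <- cnt$person[cnt$n_observed < 2]
    too_few <- union(too_few, intersect(bad, persons))
  }
  if (length(too_few)) {
    stop("persons with < 2 observed trials in a named block: ",
         paste(sort(too_few), collapse = ", "))
  }

  blocks <- lapply(spec$blocks, function(b) {
    isd <- isd_tab[isd_tab$block_id == b, ]
    list(id = b,
         Y = .block_matrix(clean, b, persons),
         isd = isd$isd[match(persons, isd$person)])
  })
  names(blocks) <- spec$blocks

  need_errors <- spec$variant != "single_block"
  ce <- po <- NULL
  if (need_errors) {
    if (is.null(errors)) stop("this variant needs error counts (see count_errors)")
    ce <- lapply(spec$blocks, function(b) {
      e <- errors[errors$block_id == b, ]
      v <- e$ce[match(persons, e$person)]
      if (anyNA(v)) stop("missing commission counts for block ", b)
      as.numeric(v)
    })
    names(ce) <- spec$blocks
    if (grepl("^two_block", spec$variant)) {
      later <- spec$blocks[2]
      e <- errors[errors$block_id == later, ]
      po <- as.numeric(e$po[match(persons, e$person)])
      if (anyNA(po)) stop("missing prospective-omission counts for block ", later)
    }
  }
  covariate <- NULL
  if (spec$variant == "two_block_with_covariate") {
    if (is.null(covariates)) stop("covariate variant needs a covariates table")
    covariate <- covariates[[spec$covariate]][match(persons, covariates$person)]
    if (anyNA(covariate)) stop("missing covariate values")
  }
  structure(list(spec = spec, persons = persons, blocks = blocks,
                 ce = ce, po = po, covariate = covariate),
            class = "dsem_model")
}

#' @export
print.dsem_model <- function(x, ...) {
  cat(sprintf("DSEM model (%s) on block(s) %s: %d persons, %s trials/block\n",
              x$spec$variant, paste(x$spec$blocks, collapse = " -> "),
              length(x$persons),
              paste(vapply(x$blocks, function(b) nrow(b$Y), 1L),
                    collapse = "/")))
  invisible(x)
}

#' Sampler configuration
#'
#' Defaults follow the reported estimation settings: two parallel chains of
#' 50,000 Gibbs iterations with thinning 10, giving a 5,000-draw solution
#' per chain; models with sluggish diagnostics were escalated to 250,000
#' iterations with thinning 50. The first `burn_in` fraction of each chain
#' is discarded before thinning.
#'
#' @param n_chains Number of chains (>= 2 for PSR diagnostics).
#' @param n_iterations Gibbs iterations per chain.
#' @param thin Keep every `thin`-th post-burn-in draw.
#' @param burn_in Fraction of iterations discarded (default 0.5).
#' @param seed Integer; chain c uses `seed + c - 1`.
#' @return Object of class `sampler_config`; `retained` gives draws kept
#'   per chain.
#' @export
sampler_config <- function(n_chains = 2L, n_iterations = 50000L, thin = 10L,
                           burn_in = 0.5, seed = 1L) {
  n_iterations <- as.integer(n_iterations)
  thin <- as.integer(thin)
  retained <- floor(n_iterations * (1 - burn_in) / thin)
  if (retained < 10) stop("configuration retains fewer than 10 draws")
  structure(list(n_chains = as.integer(n_chains),
                 n_iterations = n_iterations, thin = thin,
                 burn_in = burn_in, seed = as.integer(seed),
                 retained = retained),
            class = "sampler_config")
}
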