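#' Block design for a Go/NoGo task version
#'
#' Describes the trial composition of one 117-trial block of the classical
#' (CGNG) or prospective (PGNG) Go/NoGo task. In both versions every digit
#' 1--9 appears 13 times per block and the NoGo stimulus is the digit 3.
#' In the prospective version 13 of the non-3 trials are shown in blue and
#' carry the prospective-memory cue; blue never co-occurs with the digit 3.
#'
#' @param task_version `"classical"` or `"prospective"`.
#' @param n_trials Total trials per block (default 117).
#' @param n_nogo Number of NoGo trials (default 13).
#' @param n_prospective Number of prospective-cue trials; forced to 0 for the
#'   classical version, default 13 for the prospective version.
#' @return An object of class `block_design`: a list with fields
#'   `task_version`, `n_trials`, `n_go`, `n_nogo`, `n_prospective`,
#'   `digit_set`, `nogo_digit`, `prospective_cue`.
#' @examples
#' block_design("classical")     # 104 Go / 13 NoGo
#' block_design("prospective")   # 91 Go / 13 NoGo / 13 Prospective
#' @export
block_design <- function(task_version = c("classical", "prospective"),
                         n_trials = 117L, n_nogo = 13L,
                         n_prospective = NULL) {
  task_version <- match.arg(task_version)
  n_trials <- as.integer(n_trials)
  n_nogo <- as.integer(n_nogo)
  if (is.null(n_prospective)) {
    n_prospective <- if (task_version == "prospective") 13L else 0L
  }
  n_prospective <- as.integer(n_prospective)
  if (task_version == "classical" && n_prospective != 0L) {
    stop("classical blocks have no prospective trials")
  }
  n_go <- n_trials - n_nogo - n_prospective
  if (n_go < 0L) stop("n_nogo + n_prospective exceeds n_trials")
  structure(
    list(task_version = task_version,
         n_trials = n_trials,
         n_go = n_go,
         n_nogo = n_nogo,
         n_prospective = n_prospective,
         digit_set = 1:9,
         nogo_digit = 3L,
         prospective_cue = "blue"),
    class = "block_design")
}

# Stimulus colours used by the task; blue is reserved for the prospective cue
# in the prospective version.
.gng_colors <- c("blue", "pink", "yellow", "light green", "dark green",
                 "gray", "brown", "orange")
.gng_font_sizes <- c(63L, 81L, 99L, 117L, 135L)

#' Generate one pseudo-randomized trial sequence
#'
#' Draws a uniformly random ordering of the block's trial types and rejects
#' orderings that place two NoGo trials or two prospective trials next to
#' each other, resampling until an admissible ordering is found (at most
#' `max_attempts` tries). Digits, colours, and font sizes are then assigned:
#' each digit 1--9 appears exactly 13 times in a standard 117-trial block,
#' NoGo trials always show the digit 3, prospective trials are blue non-3
#' digits, and in the prospective version no other trial is blue.
#'
#' @param design A [block_design()].
#' @param seed Optional integer seed; `NULL` uses the current RNG state.
#' @param max_attempts Rejection-sampling cap before failing (default 10000).
#' @return An object of class `trial_sequence`: list with `design`,
#'   `trial_type` (character vector, `"go"`/`"nogo"`/`"prospective"`),
#'   `digit`, `color`, `font_size`, and `attempts` (rejection count + 1).
#' @examples
#' ts <- generate_trial_sequence(block_design("prospective"), seed = 1)
#' table(ts$trial_type)
#' @export
generate_trial_sequence <- function(design, seed = NULL,
                                    max_attempts = 10000L) {
  stopifnot(inherits(design, "block_design"))
  if (!is.null(seed)) set.seed(seed)
  n <- design$n_trials
  # Feasibility: k special trials of one kind can be separated iff k <= ceil(n/2).
  if (design$n_nogo > ceiling(n / 2) || design$n_prospective > ceiling(n / 2)) {
    stop("infeasible design: too many special trials to avoid adjacency")
  }
  types <- c(rep("go", design$n_go), rep("nogo", design$n_nogo),
             rep("prospective", design$n_prospective))
  ok <- FALSE
  for (attempt in seq_len(max_attempts)) {
    perm <- sample(types)
    same_adjacent <- perm[-1] == perm[-n] & perm[-1] != "go"
    if (!any(same_adjacent)) { ok <- TRUE; break }
  }
  if (!ok) stop("no admissible ordering found in ", max_attempts, " attempts")

  # Digit assignment: 13 copies of each digit per standard block; NoGo trials
  # take all copies of the NoGo digit, prospective trials draw from the rest.
  digit <- integer(n)
  is_nogo <- perm == "nogo"
  is_pm <- perm == "prospective"
  is_go <- !is_nogo & !is_pm
  digit[is_nogo] <- design$nogo_digit
  other_digits <- setdiff(design$digit_set, design$nogo_digit)
  per_digit <- design$n_trials %/% length(design$digit_set)
  pool <- rep(other_digits, per_digit)
  n_other <- design$n_go + design$n_prospective
  if (length(pool) < n_other) {    # non-standard block size: top up at random
    pool <- c(pool, sample(other_digits, n_other - length(pool), replace = TRUE))
  }
  pool <- sample(pool)[seq_len(n_other)]
  digit[is_pm] <- pool[seq_len(design$n_prospective)]
  digit[is_go] <- pool[design$n_prospective + seq_len(design$n_go)]

  color <- character(n)
  if (design$task_version == "prospective") {
    color[is_pm] <- design$prospective_cue
    non_cue <- setdiff(.gng_colors, design$prospective_cue)
    color[!is_pm] <- sample(non_cue, sum(!is_pm), replace = TRUE)
  } else {
    color <- sample(.gng_colors, n, replace = TRUE)
  }
  font_size <- sample(.gng_font_sizes, n, replace = TRUE)

  structure(
    list(design = design, trial_type = perm, digit = digit, color = color,
         font_size = font_size, attempts = attempt),
    class = "trial_sequence")
}

#' @export
print.block_design <- function(x, ...) {
  cat(sprintf("Go/NoGo block design (%s): %d trials = %d Go + %d NoGo + %d Prospective\n",
              x$task_version, x$n_trials, x$n_go, x$n_nogo, x$n_prospective))
  invisible(x)
}

#' @export
print.trial_sequence <- function(x, ...) {
  print(x$design)
  cat("types:", paste(substr(x$trial_type[1:20], 1, 1), collapse = ""),
      "... (g = go, n = nogo, p = prospective)\n")
  invisible(x)
}
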