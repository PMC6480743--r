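# Shared test fixtures, all generated in code.

# small cohort with the study-calibrated generating values, one block
small_dataset <- function(n_persons = 12, blocks = "CGNG1", seed = 7,
                          pop = NULL) {
  if (is.null(pop)) pop <- default_population(blocks)
  assemble_dataset(pop, n_persons = n_persons, blocks = blocks, seed = seed)
}

# Monte-Carlo standard error of a chain mean via batch means
mcse <- function(x, n_batches = 20) {
  n <- length(x)
  bs <- floor(n / n_batches)
  bm <- vapply(seq_len(n_batches), function(b) {
    mean(x[((b - 1) * bs + 1):(b * bs)])
  }, 1)
  stats::sd(bm) / sqrt(n_batches)
}

# exact two-sided signed-rank p-value by enumerating all sign patterns
# (no zeros, no ties assumed)
exact_signed_rank_p <- function(d) {
  n <- length(d)
  r <- rank(abs(d))
  obs <- sum(r[d > 0])
  EW <- n * (n + 1) / 4
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Wall <- as.numeric(signs %*% r)
  mean(abs(Wall - EW) >= abs(obs - EW))
}
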