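test_that("first-trial removal keeps the time axis recoverable", {
  df <- data.frame(person = 1, block_id = "CGNG1", trial = 1:117,
                   rt_ms = seq(500, 616), correct = TRUE)
  out <- drop_first_trial(df)
  expect_equal(nrow(out), 116)
  expect_equal(out$trial, 1:116)
  expect_equal(out$orig_trial, 2:117)            # original index recoverable
  expect_equal(out$rt_ms, df$rt_ms[match(out$orig_trial, df$trial)])
  tiny <- drop_first_trial(df[1, ])
  expect_equal(nrow(tiny), 0)
  expect_true(isTRUE(attr(tiny, "empty_series")))
  expect_error(drop_first_trial(df[0, ]), "empty")
})

test_that("3-SD trimming matches the direct computation", {
  x <- c(rep(500, 50), 5000)
  out <- trim_outliers(x)
  m <- mean(x); s <- stats::sd(x)
  expect_true(5000 > m + 3 * s)                   # oracle: rule fires
  expect_true(is.na(out[51]))
  expect_equal(sum(is.na(out)), 1)
  expect_equal(attr(out, "n_trimmed"), 1L)

  const <- trim_outliers(rep(480, 30))            # zero SD: rule skips
  expect_equal(attr(const, "n_trimmed"), 0L)
  inliers <- c(490, 500, 510, 505, 495)
  expect_equal(as.numeric(trim_outliers(inliers)), inliers)  # no-op case
  expect_warning(trim_outliers(c(500, NA)), "fewer than 2")
})

test_that("log transform is exact and rejects nonpositive RTs", {
  expect_equal(round(log_transform(518.01), 2), 6.25)
  expect_equal(log_transform(1), 0)
  x <- c(NA, 300, 750)
  expect_equal(exp(log_transform(x)), x, tolerance = 1e-12)
  expect_error(log_transform(c(400, -3, 500)), "position\\(s\\) 2")
})

test_that("iSD is the sample SD over observed values", {
  expect_equal(compute_isd(c(1, 2, 3)), 1)
  expect_warning(expect_true(is.na(compute_isd(c(5, NA)))), "undefined")
  # brute-force two-pass oracle on random fixtures with missing values
  set.seed(4)
  for (i in 1:20) {
    x <- stats::rnorm(60, 6.3, 0.2)
    x[sample(60, 8)] <- NA
    obs <- x[!is.na(x)]
    oracle <- sqrt(sum((obs - mean(obs))^2) / (length(obs) - 1))
    expect_equal(compute_isd(x), oracle)
  }
})

test_that("the pipeline preserves the time axis and never invents values", {
  ds <- small_dataset(n_persons = 6, blocks = c("CGNG1", "PGNG1"), seed = 21)
  prep <- preprocess_dataset(ds$trials)
  # every series is 116 trials long on the preserved axis
  lens <- tapply(prep$clean$trial, interaction(prep$clean$person,
                                               prep$clean$block_id),
                 function(t) length(t))
  expect_true(all(lens == 116))
  expect_true(all(prep$clean$orig_trial == prep$clean$trial + 1))
  # missingness monotonicity: observed values never exceed observed inputs
  for (b in c("CGNG1", "PGNG1")) {
    for (p in 1:6) {
      inp <- ds$trials[ds$trials$person == p & ds$trials$block_id == b, ]
      n_in <- sum(!is.na(inp$rt_ms) & inp$correct & inp$trial > 1)
      y <- series_vector(prep$clean, p, b)
      expect_lte(sum(!is.na(y)), n_in)
    }
  }
  # incorrect trials are missing in the clean series
  bad <- ds$trials[!ds$trials$correct & ds$trials$trial > 1, ]
  for (k in seq_len(min(nrow(bad), 20))) {
    y <- series_vector(prep$clean, bad$person[k], bad$block_id[k])
    expect_true(is.na(y[bad$trial[k] - 1]))
  }
  # iSD table matches compute_isd on the extracted series
  i1 <- prep$isd[prep$isd$person == 3 & prep$isd$block_id == "PGNG1", ]
  expect_equal(i1$isd, compute_isd(series_vector(prep$clean, 3, "PGNG1")))
})
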