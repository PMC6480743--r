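test_that("ADF statistics match an independent reference implementation", {
  # frozen oracle: statsmodels.tsa.stattools.adfuller on the identical
  # series (seed 42, AR(0.5) + 6.3), fixed lag, all three specifications
  set.seed(42)
  e <- stats::rnorm(120)
  y <- as.numeric(stats::filter(e, 0.5, method = "recursive")) + 6.3
  frozen <- list(
    n = c(`0` = -1.1176633790, `2` = -0.6930039943),
    c = c(`0` = -6.2303280972, `2` = -4.9162163616),
    ct = c(`0` = -6.2010770347, `2` = -4.8947896442))
  for (reg in names(frozen)) {
    for (lag in c(0L, 2L)) {
      r <- adf_test(y, reg, lags = lag)
      expect_equal(r$statistic, unname(frozen[[reg]][as.character(lag)]),
                   tolerance = 1e-9)
    }
  }
})

test_that("classification recovers the construction (simulation)", {
  n_seeds <- 40
  cls_mean <- cls_zero <- cls_rw <- character(n_seeds)
  set.seed(11)
  for (i in seq_len(n_seeds)) {
    cls_mean[i] <- adf_classify(stats::rnorm(116, 6.3, 0.2))$classification
    cls_zero[i] <- adf_classify(stats::rnorm(116, 0, 0.2))$classification
    cls_rw[i] <- adf_classify(cumsum(stats::rnorm(116)))$classification
  }
  expect_gte(mean(cls_mean == "stationary_around_mean"), 0.90)
  expect_gte(mean(cls_zero == "stationary_around_zero"), 0.85)
  expect_gte(mean(cls_rw == "nonstationary"), 0.70)
})

test_that("a strong linear trend is detected and detrended", {
  set.seed(5)
  y <- 6 + 0.01 * (1:116) + stats::rnorm(116, 0, 0.15)
  v <- adf_classify(y)
  expect_equal(v$classification, "stationary_around_trend")
  expect_true(v$detrend)
  yd <- detrend_series(y)
  slope <- stats::coef(stats::lm(yd ~ seq_along(yd)))[2]
  expect_lt(abs(slope), 1e-8)
})

test_that("verdicts are deterministic and respect missing-value gaps", {
  set.seed(9)
  y <- stats::rnorm(116, 6.3, 0.2)
  y[sample(116, 15)] <- NA
  a <- adf_classify(y)
  b <- adf_classify(y)
  expect_identical(a$classification, b$classification)
  expect_identical(a$tests$c$statistic, b$tests$c$statistic)
  # too-short series are flagged, not classified
  short <- adf_classify(stats::rnorm(10))
  expect_equal(short$classification, "unclassifiable")
})

test_that("the exclusion rule removes exactly the zero-stationary persons", {
  set.seed(3)
  mk <- function(person, block_id, y) {
    data.frame(person = person, block_id = block_id,
               trial = seq_along(y), orig_trial = seq_along(y) + 1,
               log_rt = y)
  }
  rows <- list()
  for (p in 1:15) rows[[p]] <- mk(p, "PGNG1", stats::rnorm(116, 6.3, 0.2))
  for (p in 16:20) rows[[p]] <- mk(p, "PGNG1", stats::rnorm(116, 0, 0.2))
  clean <- do.call(rbind, rows)
  verdicts <- classify_all_series(clean)
  excl <- apply_exclusion(verdicts)
  expect_setequal(excl$excluded, 16:20)
  expect_setequal(excl$kept, 1:15)
  # idempotent: re-applying to the kept subset excludes nobody
  again <- apply_exclusion(verdicts[verdicts$person %in% excl$kept, ])
  expect_identical(again$excluded, integer(0))
  expect_setequal(again$kept, excl$kept)
  # all mean-stationary: nobody excluded
  ok <- verdicts[verdicts$person %in% 1:15, ]
  expect_length(apply_exclusion(ok)$excluded, 0)
})

test_that("trend power grows with series length (property)", {
  set.seed(21)
  reps <- 25
  hit <- function(T_) {
    mean(replicate(reps, {
      y <- 6 + 0.006 * seq_len(T_) + stats::rnorm(T_, 0, 0.2)
      adf_classify(y)$classification == "stationary_around_trend"
    }))
  }
  expect_gte(hit(200), hit(60))
})
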