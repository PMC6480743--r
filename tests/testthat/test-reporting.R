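test_that("error-rate tables pool blocks as documented", {
  persons <- data.frame(
    person = rep(1:4, 4),
    block_id = rep(c("CGNG1", "CGNG2", "PGNG1", "PGNG2"), each = 4),
    ce = c(1, 2, 0, 1,   1, 1, 1, 1,   4, 3, 4, 3,   2, 3, 2, 3),
    po = c(rep(NA, 8), 2, 1, 2, 1, 1, 0, 1, 0))
  et <- error_rate_table(persons)
  expect_equal(et$by_block$ce_mean,
               c(mean(c(1, 2, 0, 1)), 1, 3.5, 2.5))
  pooled <- et$pooled
  cg <- pooled[pooled$task == "CGNG", ]
  pg <- pooled[pooled$task == "PGNG", ]
  expect_equal(cg$ce_rate, (1 + 1) / 2 / 13)
  expect_equal(pg$ce_rate, (3.5 + 2.5) / 2 / 13)
  expect_equal(pg$po_rate, (1.5 + 0.5) / 2 / 13)
  expect_equal(pg$pm_accuracy, 1 - pg$po_rate)   # accuracy identity
  expect_true(is.na(cg$po_rate))
  # all-zero errors give zero rates
  z <- persons; z$ce <- 0; z$po[!is.na(z$po)] <- 0
  expect_true(all(error_rate_table(z)$pooled$ce_rate == 0))
})

test_that("signed-rank test matches the exact enumeration oracle at n = 6", {
  y <- c(1, 2, 3, 4, 5, 6)
  x <- c(3, 1, 7, 1, 10, 12)       # d = (2, -1, 4, -3, 5, 6): no ties/zeros
  d <- x - y
  res <- wilcoxon_signed_rank(x, y)
  expect_equal(res$statistic, sum(rank(abs(d))[d > 0]))
  p_exact <- exact_signed_rank_p(d)
  expect_lt(abs(res$p_raw - p_exact), 0.08)       # normal approx at n = 6
  expect_equal(sign(res$z), sign(sum(rank(abs(d))[d > 0]) -
                                   6 * 7 / 4))
})

test_that("zero differences follow the Pratt convention", {
  # d = (0, 1, -2, 3): zeros ranked with the rest, dropped from the sum
  res <- wilcoxon_signed_rank(c(1, 3, 1, 6), c(1, 2, 3, 3))
  expect_equal(res$statistic, 2 + 4)              # ranks of +1 and +3
  expect_false(res$undefined)
  ident <- wilcoxon_signed_rank(c(2, 2, 2), c(2, 2, 2))
  expect_true(ident$undefined)
  expect_equal(ident$z, 0)
  expect_equal(ident$p_corrected, 1)
})

test_that("Bonferroni correction multiplies and caps", {
  set.seed(2)
  x <- stats::rnorm(30); y <- x + stats::rnorm(30, 0.05)
  r1 <- wilcoxon_signed_rank(x, y, n_tests = 1)
  r4 <- wilcoxon_signed_rank(x, y, n_tests = 4)
  expect_equal(r4$p_corrected, min(4 * r1$p_raw, 1))
  # any raw p >= 1/n_tests caps at exactly 1
  if (r1$p_raw >= 0.25) expect_equal(r4$p_corrected, 1)
  big <- wilcoxon_signed_rank(1:20, c(2, 1:19), n_tests = 50)
  expect_lte(big$p_corrected, 1)
  expect_gt(big$p_corrected, 0)
})

test_that("back-transformation inverts the log transform", {
  expect_equal(backtransform_ms(0), 1)
  x <- c(250.5, 518.01, 900)
  expect_equal(backtransform_ms(log_transform(x), digits = Inf), x,
               tolerance = 1e-12)
})

test_that("rendered tables star CI-excluding-zero cells and mark na", {
  es <- error_rate_table(data.frame(
    person = rep(1:2, 2), block_id = rep(c("CGNG1", "PGNG1"), each = 2),
    ce = c(1, 1, 3, 4), po = c(NA, NA, 1, 2)))
  fits <- list(M1 = data.frame(
    parameter = c("gamma_mu", "var_mu", "gamma_phi", "var_phi", "gamma_isd",
                  "var_isd", "r_mu_phi", "r_mu_isd", "r_phi_isd",
                  "beta_0", "beta_mu_std", "beta_phi_std", "beta_isd_std",
                  "r2_ce"),
    mean = c(6.25, 0.02, 0.30, 0.01, 0.15, 0.001, 0.22, 0.11, 0.65,
             11.15, -0.27, -0.39, 0.79, 0.45),
    ci_lower = c(6.22, 0.01, 0.26, 0.005, 0.14, 0.0005, -0.10, -0.12, 0.40,
                 1.74, -0.48, -0.93, 0.50, 0.30),
    ci_upper = c(6.28, 0.02, 0.33, 0.02, 0.16, 0.002, 0.47, 0.31, 0.83,
                 19.51, -0.05, -0.001, 1.33, 0.60),
    significant = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, TRUE,
                    TRUE, TRUE, TRUE, TRUE, TRUE),
    psr = 1, standardized = FALSE))
  tabs <- render_tables(error_summary = es, fit_summaries = fits)
  expect_equal(tabs$table1[2, "CGNG1"], "na")     # no PM errors in CGNG
  expect_match(tabs$table1[1, "PGNG1"], "3.50")
  t2 <- tabs$table2
  expect_match(t2$M1[t2$parameter == "gamma_mu"], "\\*")
  expect_false(grepl("\\*", t2$M1[t2$parameter == "r_mu_phi"]))
  # the layout survives a CSV round trip
  f <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(t2, f, row.names = FALSE)
  back <- utils::read.csv(f, stringsAsFactors = FALSE)
  expect_equal(back$M1, t2$M1)
  expect_equal(back$parameter, t2$parameter)
})
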