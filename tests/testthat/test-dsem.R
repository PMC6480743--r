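test_that("model specs and the standard ladder validate their inputs", {
  expect_equal(standard_model("m1")$blocks, "CGNG1")
  expect_equal(standard_model("m6")$variant, "single_block_with_errors")
  expect_equal(standard_model("m6")$blocks, "CGNG2")
  expect_equal(standard_model("m9")$blocks, c("CGNG2", "PGNG1"))
  expect_equal(standard_model("m10")$variant, "two_block_with_covariate")
  expect_error(standard_model("m11"), "unknown")
  expect_error(dsem_spec("two_block", "CGNG1"), "exactly two")
  expect_error(dsem_spec("single_block", c("a", "b")), "exactly one")
})

test_that("build_model enforces data requirements", {
  ds <- small_dataset(n_persons = 4, blocks = "CGNG1", seed = 31)
  prep <- preprocess_dataset(ds$trials)
  expect_error(build_model(standard_model("m3"), prep), "not present")
  expect_error(build_model(standard_model("m5"), prep), "error counts")
  # a person with almost no observed trials is rejected with their id
  prep2 <- prep
  drop <- prep2$clean$person == 2 & prep2$clean$trial > 2
  prep2$clean$log_rt[drop] <- NA
  prep2$isd$n_observed[prep2$isd$person == 2] <- 1L
  expect_error(build_model(standard_model("m1"), prep2), "< 2 observed.*2")
  # exclusions shrink the cohort
  m <- build_model(standard_model("m1"), prep, exclude = c(1, 3))
  expect_equal(m$persons, c(2L, 4L))
})

test_that("Gibbs posterior matches conditional least squares on one series", {
  y <- simulate_rt_series(6.3, 0.45, 0.2, 2000, seed = 12)
  fit <- ar1_fit(y, sampler_config(n_chains = 1, n_iterations = 4500,
                                   thin = 1, burn_in = 1 / 3, seed = 2))
  cls <- ar1_cls(y)
  d <- fit$draws
  expect_lt(abs(mean(d[, "mu"]) - cls$mu), 3 * mcse(d[, "mu"]) + 1e-4)
  expect_lt(abs(mean(d[, "phi"]) - cls$phi), 3 * mcse(d[, "phi"]) + 2e-4)
  expect_lt(abs(mean(d[, "sigma2_zeta"]) - cls$sigma2),
            3 * mcse(d[, "sigma2_zeta"]) + 2e-5)
})

test_that("PSR is 1 for identical chains and flags separated chains", {
  set.seed(8)
  d <- matrix(stats::rnorm(600), 200, 3,
              dimnames = list(NULL, c("a", "b", "c")))
  psr <- compute_psr(list(d, d))
  expect_equal(as.numeric(psr), rep(1, 3), tolerance = 1e-12)
  expect_length(attr(psr, "flagged"), 0)
  # chains drawn from two different stationary distributions
  d2 <- d; d2[, "b"] <- d2[, "b"] + 10
  psr2 <- compute_psr(list(d, d2))
  expect_gt(psr2[["b"]], 1.1)
  expect_true("b" %in% attr(psr2, "flagged"))
  expect_error(compute_psr(list(d)), "2 chains")
})

test_that("posterior summaries match a hand-computed quantile oracle", {
  ds <- small_dataset(n_persons = 6, blocks = "CGNG1", seed = 81)
  prep <- preprocess_dataset(ds$trials)
  mdl <- build_model(standard_model("m1"), prep)
  fit <- dsem_fit(mdl, sampler_config(n_chains = 2, n_iterations = 300,
                                      thin = 1, burn_in = 0.5, seed = 4))
  s <- summary(fit)
  pooled <- do.call(rbind, fit$draws)
  # sorted-array interpolation oracle (type-7), written out by hand
  hand_q <- function(x, p) {
    x <- sort(x)
    h <- (length(x) - 1) * p + 1
    lo <- floor(h)
    x[lo] + (h - lo) * (x[min(lo + 1, length(x))] - x[lo])
  }
  for (p in c("gamma_mu", "gamma_phi", "sigma2_zeta")) {
    row <- s[s$parameter == p, ]
    expect_equal(row$mean, mean(pooled[, p]))
    expect_equal(row$ci_lower, hand_q(pooled[, p], 0.025))
    expect_equal(row$ci_upper, hand_q(pooled[, p], 0.975))
    expect_identical(row$significant, row$ci_lower > 0 | row$ci_upper < 0)
  }
})

test_that("a small single-block fit is sane and seed-stable", {
  ds <- small_dataset(n_persons = 15, blocks = "CGNG1", seed = 41)
  prep <- preprocess_dataset(ds$trials)
  mdl <- build_model(standard_model("m5"), prep,
                     errors = count_errors(ds$trials))
  cfg <- sampler_config(n_chains = 2, n_iterations = 1500, thin = 1,
                        burn_in = 0.5, seed = 9)
  fit <- dsem_fit(mdl, cfg)
  pooled <- do.call(rbind, fit$draws)
  expect_true(all(is.finite(pooled)))
  expect_true(all(pooled[, c("var_mu", "var_phi", "var_isd",
                             "sigma2_zeta", "sigma2_e")] > 0))
  s <- summary(fit)
  expect_true(all(s$ci_lower <= s$mean + 1e-12 &
                    s$mean <= s$ci_upper + 1e-12))
  # correlations bounded in [-1, 1] draw by draw
  std <- do.call(rbind, standardize(fit))
  rs <- std[, c("r_mu_phi", "r_mu_isd", "r_phi_isd")]
  expect_true(all(rs >= -1 & rs <= 1))
  # byte-identical refit under the same config
  fit2 <- dsem_fit(mdl, cfg)
  expect_identical(fit$draws, fit2$draws)
})

test_that("standardized estimates are invariant to rescaling the RTs", {
  ds <- small_dataset(n_persons = 10, blocks = "CGNG1", seed = 51)
  tr2 <- ds$trials
  tr2$rt_ms <- tr2$rt_ms * 100        # rescale every RT by a constant
  cfg <- sampler_config(n_chains = 1, n_iterations = 800, thin = 1,
                        burn_in = 0.5, seed = 3)
  fits <- lapply(list(ds$trials, tr2), function(tr) {
    prep <- preprocess_dataset(tr)
    mdl <- build_model(standard_model("m5"), prep,
                       errors = count_errors(tr))
    dsem_fit(mdl, cfg)
  })
  s1 <- do.call(rbind, standardize(fits[[1]]))
  s2 <- do.call(rbind, standardize(fits[[2]]))
  for (p in c("beta_mu_std", "beta_phi_std", "beta_isd_std", "r_phi_isd")) {
    expect_equal(mean(s1[, p]), mean(s2[, p]), tolerance = 1e-4)
  }
  # and phi draws themselves are scale-free
  expect_equal(mean(fits[[1]]$draws[[1]][, "gamma_phi"]),
               mean(fits[[2]]$draws[[1]][, "gamma_phi"]), tolerance = 1e-4)
})

test_that("MCAR missingness widens credible intervals without biasing phi", {
  pop <- population_parameters(gamma_phi = 0.3, var_phi = 0.005,
                               cor_mu_phi = 0, cor_mu_isd = 0,
                               cor_phi_isd = 0)
  ds <- small_dataset(n_persons = 20, blocks = "CGNG1", seed = 61, pop = pop)
  prep_full <- preprocess_dataset(ds$trials)
  tr_miss <- ds$trials
  set.seed(62)
  kill <- sample(nrow(tr_miss), round(0.35 * nrow(tr_miss)))
  tr_miss$rt_ms[kill] <- NA
  prep_miss <- preprocess_dataset(tr_miss)
  cfg <- sampler_config(n_chains = 1, n_iterations = 2000, thin = 1,
                        burn_in = 0.5, seed = 5)
  width <- function(prep) {
    mdl <- build_model(standard_model("m1"), prep)
    s <- summary(dsem_fit(mdl, cfg))
    row <- s[s$parameter == "gamma_phi", ]
    c(width = row$ci_upper - row$ci_lower, mean = row$mean)
  }
  w_full <- width(prep_full)
  w_miss <- width(prep_miss)
  expect_gt(w_miss[["width"]], 0.95 * w_full[["width"]])
  expect_lt(abs(w_miss[["mean"]] - 0.3), 0.1)
  expect_lt(abs(w_full[["mean"]] - 0.3), 0.1)
})

test_that("block splitting preserves the time axis and rejects bad cuts", {
  ds <- small_dataset(n_persons = 4, blocks = "PGNG1", seed = 71)
  prep <- preprocess_dataset(ds$trials)
  sp <- split_block(prep, "PGNG1", cut = 58)
  expect_setequal(unique(sp$clean$block_id), c("PGNG1a", "PGNG1b"))
  ya <- series_vector(sp$clean, 1, "PGNG1a")
  yb <- series_vector(sp$clean, 1, "PGNG1b")
  expect_length(ya, 58)
  expect_length(yb, 58)
  y <- series_vector(prep$clean, 1, "PGNG1")
  expect_equal(c(ya, yb), y)
  a <- sp$clean[sp$clean$block_id == "PGNG1a" & sp$clean$person == 1, ]
  b <- sp$clean[sp$clean$block_id == "PGNG1b" & sp$clean$person == 1, ]
  expect_equal(a$orig_trial, 2:59)       # original axis retained
  expect_equal(b$orig_trial, 60:117)
  expect_equal(b$trial, 1:58)            # lag pairs never cross the cut
  expect_error(split_block(prep, "PGNG1", cut = 1), "degenerate")
  expect_error(split_block(prep, "PGNG1", cut = 116), "strictly inside")
  # the two halves feed a two-block fit
  err <- count_errors(ds$trials)
  err_a <- err; err_a$block_id <- "PGNG1a"
  err_b <- err; err_b$block_id <- "PGNG1b"
  mdl <- build_model(dsem_spec("two_block", c("PGNG1a", "PGNG1b")), sp,
                     errors = rbind(err_a, err_b))
  expect_s3_class(mdl, "dsem_model")
})
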