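test_that("AR(1) series match their stationary moments (property)", {
  # stationary SD equals isd and lag-1 autocorrelation equals phi, within
  # 2% on a long series, for positive, null, and negative phi
  for (phi in c(0.7, 0, -0.7)) {
    y <- simulate_rt_series(600, phi, 40, 1e5, seed = 10 + phi * 10,
                            scale = "ms")
    expect_equal(stats::sd(y), 40, tolerance = 0.02)
    ac1 <- stats::cor(y[-1], y[-length(y)])
    expect_lt(abs(ac1 - phi), 0.02)
    expect_equal(mean(y), 600, tolerance = 0.02)
  }
})

test_that("degenerate and invalid series requests behave", {
  y <- simulate_rt_series(6.3, 0.5, 0, 100, seed = 1)
  expect_true(all(y == 6.3))                       # no innovations
  expect_error(simulate_rt_series(6.3, 1, 0.2, 50), "nonstationary")
  expect_error(simulate_rt_series(6.3, -1.2, 0.2, 50), "nonstationary")
  expect_error(simulate_rt_series(6.3, 0.5, -1, 50), "isd")
  expect_equal(attr(simulate_rt_series(6.3, 0.6, 0.2, 10, seed = 1),
                    "sigma_zeta"), 0.2 * sqrt(1 - 0.36))
})

test_that("error counts follow the level-2 regression with round/clip", {
  # deterministic check: all weights zero, no residual noise
  pop <- population_parameters(beta0 = 1.105, beta_mu = 0, beta_phi = 0,
                               beta_isd = 0, sigma_e = 0)
  person <- list(mu = rep(6.25, 50), phi = rep(0.3, 50), isd = rep(0.15, 50))
  e <- simulate_errors(person, pop, seed = 1)
  expect_true(all(e$ce == round(1.105)))
  # monotone link: higher isd -> more errors when beta_isd > 0
  pop2 <- population_parameters(beta0 = 2, beta_mu = 0, beta_phi = 0,
                                beta_isd = 20, sigma_e = 0)
  lo <- simulate_errors(list(mu = 6.2, phi = 0.3, isd = 0.10), pop2)
  hi <- simulate_errors(list(mu = 6.2, phi = 0.3, isd = 0.30), pop2)
  expect_gt(hi$ce, lo$ce)
  # clipping to the 13 eligible trials
  pop3 <- population_parameters(beta0 = 99, sigma_e = 0)
  expect_equal(simulate_errors(list(mu = 0, phi = 0, isd = 0), pop3)$ce, 13L)
  pop4 <- population_parameters(beta0 = -99, beta_mu = 0, beta_phi = 0,
                                beta_isd = 0, sigma_e = 0)
  expect_equal(simulate_errors(list(mu = 6, phi = 0, isd = 0.1), pop4)$ce, 0L)
})

test_that("assembled datasets have the study shape and design-driven missingness", {
  ds <- small_dataset(n_persons = 3, blocks = c("CGNG1", "CGNG2", "PGNG1",
                                                "PGNG2"), seed = 5)
  expect_equal(nrow(ds$trials), 3 * 4 * 117)
  one <- small_dataset(n_persons = 1, blocks = "CGNG1", seed = 5)
  expect_equal(nrow(one$trials), 117)

  tr <- ds$trials
  # RT missing exactly on correct NoGo trials
  expect_true(all(is.na(tr$rt_ms[tr$trial_type == "nogo" & tr$correct])))
  expect_true(all(!is.na(tr$rt_ms[tr$trial_type == "nogo" & !tr$correct])))
  expect_true(all(!is.na(tr$rt_ms[tr$trial_type != "nogo"])))
  # recounted errors equal the generator's person table
  cnt <- count_errors(tr)
  m <- merge(cnt, ds$persons, by = c("person", "block_id"))
  expect_equal(m$ce.x, m$ce.y)
  pm <- !is.na(m$po.y)
  expect_equal(m$po.x[pm], m$po.y[pm])
  expect_true(all(m$ce.x <= 13 & m$ce.x >= 0))
})

test_that("datasets are seed-deterministic and survive a CSV round trip", {
  a <- small_dataset(n_persons = 2, blocks = c("CGNG1", "PGNG1"), seed = 77)
  b <- small_dataset(n_persons = 2, blocks = c("CGNG1", "PGNG1"), seed = 77)
  expect_identical(a$trials, b$trials)
  expect_identical(a$persons, b$persons)
  dir <- withr::local_tempdir()
  write_dataset(a, dir)
  back <- read_trials(file.path(dir, "trials.csv"))
  expect_equal(back$rt_ms, a$trials$rt_ms, tolerance = 1e-12)
  expect_identical(back$trial_type, a$trials$trial_type)
  expect_identical(back$correct, a$trials$correct)
})
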