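test_that("rate model recovers a doubled rate and reports diagnostics", {
  d <- simulate_rate_data(n_rats = 5, n_trials = 30, fold = 2, seed = 1)
  fit <- suppressWarnings(fit_rate_model(d, seed = 1))
  s <- fit$summary
  expect_true(all(is.finite(s$rhat[s$parameter != ""])))  # Rhat for every row
  pc <- s[s$parameter == "pct_change_post", ]
  expect_gt(pc$mean, 60); expect_lt(pc$mean, 140)
  expect_gt(pc$q2.5, 0)  # 0 outside the 95% CI
  expect_true(all(s$q25 >= s$q2.5 & s$q75 <= s$q97.5))
})

test_that("rate model validates inputs and degrades for a single rat", {
  d <- simulate_rate_data(n_rats = 1, n_trials = 30, fold = 2, seed = 2)
  expect_warning(fit_rate_model(d, seed = 1, warmup = 300, iter = 300),
                 "single rat")
  bad <- simulate_rate_data(seed = 3)
  bad$exposure_s[1] <- 0
  expect_error(fit_rate_model(bad), "exposure")
  one <- simulate_rate_data(seed = 3)
  expect_error(fit_rate_model(one[one$phase == "pre", ]), "2 phases")
})

test_that("proportion model: extreme data, zero-total cells, coverage of 0.5", {
  # one category with k = n for all rats -> posterior mass above 0.5
  d <- data.frame(rat = paste0("r", 1:4), k = c(20, 25, 18, 22),
                  n = c(20, 25, 18, 22))
  fit <- suppressWarnings(fit_proportion_model(d, seed = 1))
  expect_gt(mean(fit$draws[, "prop"] > 0.5), 0.9)

  d0 <- rbind(d, data.frame(rat = "r5", k = 0, n = 0))
  w <- testthat::capture_warnings(fit_proportion_model(d0, seed = 1))
  expect_true(any(grepl("zero totals", w)))

  # symmetric data -> 0.5 inside the 95% CI
  ds <- data.frame(rat = paste0("r", 1:5), k = c(24, 26, 25, 27, 23), n = 50)
  fs <- suppressWarnings(fit_proportion_model(ds, seed = 2))
  pr <- fs$summary[fs$summary$parameter == "prop", ]
  expect_true(pr$q2.5 <= 0.5 && pr$q97.5 >= 0.5)
})

test_that("simulated 80% reverse bias excludes 0.5 from the 95% CI", {
  set.seed(5)
  d <- data.frame(rat = paste0("r", 1:5),
                  k = stats::rbinom(5, 60, 0.8), n = 60)
  fit <- suppressWarnings(fit_proportion_model(d, seed = 3))
  pr <- fit$summary[fit$summary$parameter == "prop", ]
  expect_gt(pr$q2.5, 0.5)
})

test_that("overlap decision helper mirrors the separation criterion", {
  d1 <- simulate_rate_data(n_rats = 5, n_trials = 30, fold = 4, seed = 7)
  fit <- suppressWarnings(fit_rate_model(d1, seed = 7))
  pre_draws <- exp(fit$draws[, "beta_pre"])
  post_draws <- exp(fit$draws[, "beta_post"])
  expect_lt(posterior_overlap(pre_draws, post_draws), 0.05)
})
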