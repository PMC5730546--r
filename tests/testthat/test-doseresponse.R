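exact_data <- function(ec50 = 1, h = 2, n = 1000,
                       cc = 10^seq(-1.5, 1.5, length.out = 7)) {
  dose_response_data(cc, rep(n, length(cc)),
                     n * hill_probability(cc, ec50, h))
}

test_that("the Hill MLE is exact on noise-free data", {
  f <- fit_hill(exact_data())
  expect_true(f$converged)
  expect_equal(f$ec50, 1, tolerance = 1e-3)
  expect_equal(f$hill_slope, 2, tolerance = 5e-3)
  ## the fitted curve passes through 0.5 at the EC50 by construction
  expect_equal(hill_probability(f$ec50, f$ec50, f$hill_slope), 0.5)
  ## least-squares mode agrees on exact data
  fl <- fit_hill(exact_data(), method = "ls")
  expect_equal(fl$ec50, 1, tolerance = 1e-3)
})

test_that("degenerate dose-response inputs are refused", {
  cc <- 10^seq(-1, 1, length.out = 7)
  expect_error(fit_hill(dose_response_data(cc, rep(10, 7), rep(0, 7))),
               "partial response")
  expect_error(fit_hill(dose_response_data(cc, rep(10, 7), rep(10, 7))),
               "partial response")
  expect_error(fit_hill(dose_response_data(c(0, 1, 2), rep(10, 3),
                                           c(0, 3, 7))),
               "4 distinct")
  expect_error(dose_response_data(1, 10, 11), "exceed")
})

test_that("EC50 estimates are invariant to concentration rescaling", {
  d1 <- exact_data(ec50 = 0.15)
  d2 <- dose_response_data(d1$concentration * 1000, d1$n_exposed,
                           d1$n_immobile)
  f1 <- fit_hill(d1)
  f2 <- fit_hill(d2)
  expect_equal(f2$ec50 / f1$ec50, 1000, tolerance = 1e-4)
  expect_equal(f2$hill_slope, f1$hill_slope, tolerance = 1e-4)
})

test_that("ecx obeys the closed-form Hill relations", {
  f <- list(ec50 = 1, hill_slope = 1)
  expect_equal(ecx(f, 50), 1)
  expect_equal(ecx(f, 10), 1 / 9, tolerance = 1e-12)
  f2 <- list(ec50 = 1, hill_slope = 2)
  expect_equal(ecx(f2, 10), sqrt(1 / 9), tolerance = 1e-12)
  ## strictly increasing in x
  xs <- seq(5, 95, by = 5)
  expect_true(all(diff(ecx(f2, xs)) > 0))
  expect_error(ecx(f2, 0), "between 0 and 100")
  expect_error(ecx(f2, 100), "between 0 and 100")
})

test_that("Abbott's correction rescales by control mortality", {
  d <- dose_response_data(c(0, 1), c(40, 40), c(2, 21)) # p0 = 0.05
  dc <- abbott_correct(d)
  expect_equal(dc$n_immobile[2] / dc$n_exposed[2], 0.5, tolerance = 1e-12)
  ## p0 = 0 -> identity
  d0 <- dose_response_data(c(0, 1), c(40, 40), c(0, 20))
  expect_equal(abbott_correct(d0)$n_immobile, d0$n_immobile)
  ## p < p0 clips at zero (10% control mortality also trips the QC warning)
  expect_warning(dl <- dose_response_data(c(0, 1), c(40, 40), c(4, 2)), "5%")
  expect_equal(suppressWarnings(abbott_correct(dl))$n_immobile[2], 0)
  ## QC flag above 5% control mortality
  expect_warning(dose_response_data(c(0, 1), c(40, 40), c(4, 20)), "5%")
  suppressWarnings(
    expect_error(abbott_correct(dose_response_data(c(0, 1), c(2, 40),
                                                   c(2, 20))),
                 "100%"))
})

test_that("bootstrap intervals are seed-stable, consistent, and cover", {
  cc <- 10^seq(-1, 1, length.out = 7)
  mkdata <- function(n, seed) {
    eff <- toxicant_effect(1, 2)
    counts <- vapply(seq_along(cc), function(j) {
      sum(sample_immobilization(eff, cc[j], n, seed = seed + j))
    }, 1)
    ## three replicate rows per concentration
    dose_response_data(rep(cc, each = 3), rep(n / 3, 3 * length(cc)),
                       as.numeric(vapply(counts, function(k) {
                         r1 <- min(n / 3, k)
                         r2 <- min(n / 3, k - r1)
                         c(r1, r2, k - r1 - r2)
                       }, numeric(3))))
  }
  d <- mkdata(15, 100)
  b1 <- bootstrap_ci(d, B = 60, seed = 5)
  b2 <- bootstrap_ci(d, B = 60, seed = 5)
  expect_identical(b1$ci_ec50, b2$ci_ec50)
  expect_true(b1$ci_ec50[1] < b1$ec50 && b1$ec50 < b1$ci_ec50[2])
  ## intervals shrink as the animal count grows (averaged over datasets to
  ## smooth Monte-Carlo noise in the width itself)
  width <- function(n) {
    mean(vapply(1:5, function(r) {
      diff(bootstrap_ci(mkdata(n, 200 + 17 * r), B = 60, seed = r)$ci_ec50)
    }, 1))
  }
  expect_lt(width(600), width(15))
  ## coverage over outer Monte-Carlo replications (scaled-down check)
  hits <- vapply(1:40, function(r) {
    b <- bootstrap_ci(mkdata(15, 300 + 10 * r), B = 60, seed = r)
    b$ci_ec50[1] <= 1 && 1 <= b$ci_ec50[2]
  }, TRUE)
  expect_gte(mean(hits), 0.85)
})

test_that("paired assay formats correlate as expected", {
  r <- compare_methods(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(r$r_squared, 1)
  expect_equal(r$slope, 1)
  expect_lt(compare_methods(c(1, 2, 3, 4), c(4, 3, 2, 1))$r, 0)
  expect_error(compare_methods(c(1, 2), c(1, 2)), "3 complete pairs")
  ## two assay formats sampling one latent Hill curve with binomial noise
  cc <- 10^seq(-1, 1, length.out = 7)
  eff <- toxicant_effect(1, 2)
  pa <- vapply(seq_along(cc), function(j) {
    mean(sample_immobilization(eff, cc[j], 30, seed = 900 + j))
  }, 1)
  pb <- vapply(seq_along(cc), function(j) {
    mean(sample_immobilization(eff, cc[j], 30, seed = 950 + j))
  }, 1)
  expect_gt(compare_methods(pa, pb)$r_squared, 0.9)
})

test_that("behavioural statistics are calibrated and powered", {
  ## type-I error of the t-test under the null
  set.seed(1234)
  null_p <- vapply(1:1000, function(i) {
    t.test(rnorm(3, 10, 2), rnorm(3, 10, 2), var.equal = TRUE)$p.value
  }, 1)
  rate <- mean(null_p < 0.05)
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)

  ## identical group values -> ANOVA p of 1
  ep <- data.frame(concentration = rep(c(0, 0.5, 1), each = 3),
                   time_h = 1, total_distance_mm = rep(c(1, 2, 3), 3))
  st <- behavioural_stats(ep)
  expect_equal(st$anova$p_value, 1, tolerance = 1e-9)
  expect_error(behavioural_stats(ep[c(1, 4, 7), ]), "2 replicate")

  ## a generative -60% effect is detected in >= 80% of seeds with n = 3
  power_hits <- vapply(1:120, function(s) {
    r <- behavior_recovery_experiment(0.4, n_seeds = 3, mode = "truth",
                                      seed = 5000 + s)
    t.test(r$treated_mm, r$control_mm, var.equal = TRUE)$p.value < 0.05
  }, TRUE)
  expect_gte(mean(power_hits), 0.8)
})
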