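test_that("parameter validation rejects bad values and names the field", {
  expect_error(locomotion_params(hop_rate_hz = -1), "hop_rate_hz")
  expect_error(locomotion_params(hop_rate_hz = NA), "hop_rate_hz")
  expect_error(locomotion_params(sink_speed_mm_s = -0.1), "sink_speed_mm_s")
  expect_error(locomotion_params(upward_bias = 1.5), "upward_bias")
  expect_error(locomotion_params(hop_rate_hz = 2, hop_duration_s = 0.6),
               "hop_duration_s")
  expect_error(chamber_spec(length_mm = 0), "length_mm")
  expect_error(chamber_spec(mm_per_px = -1), "mm_per_px")
  expect_error(sample_trajectory(locomotion_params(), chamber_spec(),
                                 duration_s = 10, fps = 30, seed = NULL),
               "seed")
})

test_that("degenerate rates give a constant trajectory with zero path", {
  p <- locomotion_params(hop_rate_hz = 0, sink_speed_mm_s = 0)
  tr <- sample_trajectory(p, default_chamber(), duration_s = 10, fps = 30,
                          seed = 42)
  expect_equal(nrow(tr$positions), 300)
  expect_equal(truth_path_length(tr), 0)
  expect_equal(length(unique(tr$positions$x_mm)), 1L)
  expect_equal(length(unique(tr$positions$y_mm)), 1L)
})

test_that("pure sedimentation descends at the sink speed along gravity", {
  p <- locomotion_params(hop_rate_hz = 0, sink_speed_mm_s = 0.5)
  tr <- sample_trajectory(p, default_chamber(), duration_s = 10, fps = 30,
                          seed = 7, start_mm = c(4, 6.5))
  pos <- tr$positions
  ## last frame is at t = (n-1)/fps; descent = sink_speed * elapsed time
  expect_equal(pos$y_mm[nrow(pos)] - pos$y_mm[1],
               0.5 * pos$t_s[nrow(pos)], tolerance = 1e-10)
  expect_equal(length(unique(pos$x_mm)), 1L)
  ## from low start the animal stops at the bottom wall instead
  tr2 <- sample_trajectory(p, default_chamber(), duration_s = 30, fps = 30,
                           seed = 7, start_mm = c(4, 11))
  expect_lte(max(tr2$positions$y_mm), 13 - 0.3 + 1e-12)
  expect_gte(max(tr2$positions$y_mm), 0.9 * 13)
})

test_that("mean total path length matches the closed-form expectation", {
  ## hop_rate * duration * mean hop length, tested over 500 seeds in open
  ## water (no walls) with zero sinking
  p <- locomotion_params(hop_rate_hz = 1, hop_length_mm_mean = 2,
                         hop_length_mm_sd = 0, sink_speed_mm_s = 0,
                         upward_bias = 0.5)
  ch <- open_water()
  paths <- vapply(seq_len(500), function(s) {
    truth_path_length(sample_trajectory(p, ch, duration_s = 30, fps = 30,
                                        seed = s, start_mm = c(100, 100)))
  }, 1)
  expected <- 1 * 30 * 2
  se <- sd(paths) / sqrt(length(paths))
  expect_lt(abs(mean(paths) - expected), 3 * se + 1e-9)
  expect_equal(expected / 30, expected_distance_rate(p) * 1, tolerance = 1e-12)
})

test_that("trajectories stay inside the chamber and respect phases", {
  ch <- default_chamber()
  for (s in 1:10) {
    tr <- sample_trajectory(locomotion_params(), ch, duration_s = 15,
                            fps = 30, seed = s)
    pos <- tr$positions
    expect_true(all(pos$x_mm >= 0 & pos$x_mm <= ch$width_mm))
    expect_true(all(pos$y_mm >= 0 & pos$y_mm <= ch$length_mm))
    expect_true(all(pos$phase %in% c("hopping", "resting")))
  }
})

test_that("immobile animals are sedimented, static, and never revert", {
  ch <- default_chamber()
  for (s in 1:5) {
    tr <- sample_trajectory(locomotion_params(), ch, duration_s = 15,
                            fps = 30, seed = s, immobile = TRUE)
    pos <- tr$positions
    expect_true(all(pos$phase == "immobile"))
    expect_equal(truth_path_length(tr), 0)
    expect_gte(pos$y_mm[nrow(pos)], 0.9 * ch$length_mm)
  }
})

test_that("trajectories are reproducible from the seed", {
  a <- sample_trajectory(locomotion_params(), default_chamber(), 10, 30,
                         seed = 123)
  b <- sample_trajectory(locomotion_params(), default_chamber(), 10, 30,
                         seed = 123)
  c <- sample_trajectory(locomotion_params(), default_chamber(), 10, 30,
                         seed = 124)
  expect_identical(a$positions, b$positions)
  expect_false(identical(a$positions, c$positions))
})

test_that("apply_dose scales only the hop rate, with a null-dose identity", {
  p <- locomotion_params()
  eff <- toxicant_effect(ec50 = 1, hill_slope = 2,
                         activity_curve = function(c, t) 0.4)
  expect_identical(apply_dose(p, eff, 0, 24), p)
  dosed <- apply_dose(p, eff, 1, 1)
  expect_equal(dosed$hop_rate_hz, 0.4)
  expect_equal(dosed[setdiff(names(dosed), "hop_rate_hz")],
               p[setdiff(names(p), "hop_rate_hz")])
  ## onset lag holds the effect back
  eff_lag <- toxicant_effect(1, 2, function(c, t) 0.4, onset_lag_h = 2)
  expect_identical(apply_dose(p, eff_lag, 1, 1), p)
  expect_equal(apply_dose(p, eff_lag, 1, 2)$hop_rate_hz, 0.4)
  ## hyperactivity multiplier
  eff_up <- toxicant_effect(1, 2, function(c, t) 1.25)
  expect_equal(apply_dose(p, eff_up, 0.5, 1)$hop_rate_hz, 1.25)
  ## negative multipliers are rejected
  eff_bad <- toxicant_effect(1, 2, function(c, t) -1)
  expect_error(apply_dose(p, eff_bad, 1, 1), "multiplier")
})

test_that("immobilization draws follow the Hill model", {
  eff <- toxicant_effect(ec50 = 0.15, hill_slope = 2)
  expect_false(any(sample_immobilization(eff, 0, 100, seed = 1)))
  expect_equal(hill_probability(0.15, 0.15, 2), 0.5)
  expect_equal(hill_probability(0.45, 0.15, 2), 0.9, tolerance = 1e-12)
  draws <- sample_immobilization(eff, 0.45, 10000, seed = 5)
  expect_lt(abs(mean(draws) - 0.9), 3 * sqrt(0.9 * 0.1 / 10000))
  expect_identical(sample_immobilization(eff, 0.3, 50, seed = 9),
                   sample_immobilization(eff, 0.3, 50, seed = 9))
})

test_that("empirical immobile fractions track the Hill curve on a grid", {
  eff <- toxicant_effect(ec50 = 1, hill_slope = 2)
  cc <- 10^seq(-1, 1, length.out = 7)
  n <- 2000
  for (j in seq_along(cc)) {
    p <- hill_probability(cc[j], 1, 2)
    frac <- mean(sample_immobilization(eff, cc[j], n, seed = 100 + j))
    expect_lt(abs(frac - p), 3 * sqrt(p * (1 - p) / n) + 1e-9)
  }
})

test_that("rendered empty scenes are background plus noise only", {
  ch <- wide_chamber()
  clip <- render_clip(list(), ch, fps = 10, noise_sd = 0.01, seed = 3)
  resid <- clip$frames - array(clip$template, dim = dim(clip$frames))
  expect_lt(max(abs(resid)), 6 * 0.01)
  img <- imaging_config(mm_per_px = ch$mm_per_px, fps = 10)
  expect_equal(nrow(detect_clip(clip, img)), 0)
})

test_that("a rendered animal's center of mass sits at its true position", {
  ch <- wide_chamber(mm_per_px = 13 / 256)
  p <- locomotion_params(hop_rate_hz = 0, sink_speed_mm_s = 0)
  tr <- sample_trajectory(p, ch, duration_s = 1, fps = 10, seed = 1,
                          start_mm = c(20, 6.5))
  clip <- render_clip(list(tr), ch, fps = 10, noise_sd = 0, seed = 1)
  fr <- clip$frames[, , 1]
  diffim <- clip$template - fr
  mask <- diffim > 0.05
  ## brute-force intensity-weighted center of mass of the blob
  w <- diffim * mask
  ry <- row(fr); cx <- col(fr)
  com_y <- sum(w * ry) / sum(w)
  com_x <- sum(w * cx) / sum(w)
  expect_lt(abs(com_x - (20 / ch$mm_per_px + 0.5)), 0.5)
  expect_lt(abs(com_y - (6.5 / ch$mm_per_px + 0.5)), 0.5)
})

test_that("well-separated animals render as distinct dark components", {
  ch <- wide_chamber()
  p <- locomotion_params(hop_rate_hz = 0, sink_speed_mm_s = 0)
  truths <- lapply(1:5, function(a) {
    sample_trajectory(p, ch, 0.5, 10, seed = a,
                      start_mm = c(4 + 8 * (a - 1), 6.5), animal_id = a)
  })
  clip <- render_clip(truths, ch, fps = 10, noise_sd = 0, seed = 1)
  mask <- (clip$template - clip$frames[, , 1]) > 0.3
  lab <- EBImage::bwlabel(mask)
  expect_equal(max(lab), 5)
})

test_that("rendering rejects inconsistent inputs", {
  ch <- default_chamber()
  tr <- sample_trajectory(locomotion_params(), ch, 1, 10, seed = 1)
  bad <- tr
  bad$positions$x_mm[1] <- -1
  expect_error(render_clip(list(bad), ch, fps = 10), "outside chamber")
  tr2 <- sample_trajectory(locomotion_params(), ch, 2, 10, seed = 1)
  expect_error(render_clip(list(tr, tr2), ch, fps = 10), "time base")
})

test_that("generate_assay mirrors the chip layout and is seed-exact", {
  eff <- toxicant_effect(ec50 = 0.5, hill_slope = 2)
  design <- assay_design(sampling_times_h = 1, duration_s = 1, fps = 10)
  ds <- generate_assay(design, eff, seed = 11)
  expect_equal(nrow(ds$index), 8 * 3) # 8 groups x 3 chambers, one timepoint
  expect_equal(length(unique(ds$index$chamber_id)), 24)
  ds2 <- generate_assay(design, eff, seed = 11)
  expect_identical(ds$index, ds2$index)
  expect_identical(ds$chambers[[5]]$truths[[2]]$positions,
                   ds2$chambers[[5]]$truths[[2]]$positions)
  ds3 <- generate_assay(design, eff, seed = 12)
  expect_false(identical(ds$chambers[[5]]$truths[[2]]$positions,
                         ds3$chambers[[5]]$truths[[2]]$positions))
})

test_that("assay designs without controls or replicates are refused", {
  expect_error(assay_design(concentrations = c(0.1, 1)), "control")
  expect_error(assay_design(replicates = 0), "replicates")
  expect_error(assay_design(concentrations = c(0, 1, 1)), "distinct")
})
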