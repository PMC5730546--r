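imaging30 <- function() imaging_config(mm_per_px = 0.05, fps = 30)

test_that("track metrics compute distance, speed and acceleration", {
  tr <- make_track(c(0, 3), c(0, 4), fps = 1)
  m <- track_metrics(tr, imaging30(), jitter_floor_mm = 0)
  expect_equal(m$total_distance_mm, 5)
  expect_equal(m$mean_speed_mm_s, 5)
  expect_error(track_metrics(make_track(0, 0), imaging30()), "2 samples")
})

test_that("the jitter floor suppresses stationary noise completely", {
  set.seed(8)
  n <- 900
  tr <- make_track(5 + rnorm(n, 0, 0.01), 5 + rnorm(n, 0, 0.01), fps = 30)
  m <- track_metrics(tr, imaging30(), jitter_floor_mm = 0.08)
  expect_equal(m$total_distance_mm, 0)
  ## and passive sinking is likewise below the floor at 30 fps
  sink <- make_track(rep(2, 300), seq(2, by = 0.5 / 30, length.out = 300),
                     fps = 30)
  expect_equal(track_metrics(sink, imaging30())$total_distance_mm, 0)
})

test_that("measured distance matches the generative expectation within 5%", {
  ## full default kinematics including sinking; the floor removes the
  ## sedimentation drift so distance ~ hop_rate * T * E[hop length]
  p <- locomotion_params()
  ch <- default_chamber()
  img <- imaging_config(mm_per_px = ch$mm_per_px, fps = 30)
  dists <- vapply(1:100, function(s) {
    tr <- sample_trajectory(p, ch, 30, 30, seed = 7000 + s)
    track_metrics(truth_tracks(list(tr))[[1]], img)$total_distance_mm
  }, 1)
  expected <- expected_distance_rate(p) * 30
  expect_lt(abs(mean(dists) - expected) / expected, 0.05)
})

test_that("motility classification follows the 10-s window and bottom band", {
  ch <- default_chamber()
  ## simulator-immobilized animal -> non_motile
  imm <- sample_trajectory(locomotion_params(), ch, 15, 30, seed = 3,
                           immobile = TRUE)
  expect_equal(classify_motility(truth_tracks(list(imm))[[1]], ch),
               "non_motile")
  ## actively hopping animal -> motile
  act <- sample_trajectory(locomotion_params(), ch, 15, 30, seed = 4)
  expect_equal(classify_motility(truth_tracks(list(act))[[1]], ch), "motile")
  ## 9-s rests at mid-height: hops break every 10-s window and the animal
  ## is not sedimented -> motile
  t_s <- (0:449) / 30
  y <- rep(6, 450)
  x <- rep(4, 450)
  hop_frames <- which(t_s %% 9.5 < 1 / 30)
  x[hop_frames] <- 4 + 1.5
  tr <- make_track(x, y, fps = 30)
  expect_equal(classify_motility(tr, ch), "motile")
  ## still but floating mid-water -> not scored non-motile (must sediment)
  still_mid <- make_track(rep(4, 450), rep(6, 450), fps = 30)
  expect_equal(classify_motility(still_mid, ch), "motile")
  ## short track -> indeterminate
  short <- make_track(rep(4, 30), rep(12.5, 30), fps = 30)
  expect_equal(classify_motility(short, ch), "indeterminate")
})

test_that("chamber summaries average the population per animal", {
  ch <- default_chamber()
  img <- imaging_config(mm_per_px = ch$mm_per_px, fps = 30)
  tr <- sample_trajectory(locomotion_params(), ch, 15, 30, seed = 9)
  five <- structure(rep(truth_tracks(list(tr)), 5), class = "track_set")
  s <- chamber_summary(five, img, ch, n_animals = 5)
  single <- track_metrics(truth_tracks(list(tr))[[1]], img)
  expect_equal(s$total_distance_mm, single$total_distance_mm)
  expect_equal(s$mean_speed_mm_s, single$mean_speed_mm_s)
  expect_equal(s$n_tracks, 5L)
  ## 4 motile + 1 immobilized -> n_non_motile = 1, frac_active = 0.8
  truths <- c(lapply(1:4, function(a) {
    sample_trajectory(locomotion_params(), ch, 15, 30, seed = 20 + a,
                      animal_id = a)
  }), list(sample_trajectory(locomotion_params(), ch, 15, 30, seed = 30,
                             immobile = TRUE, animal_id = 5)))
  s2 <- chamber_summary(truth_tracks(truths), img, ch, n_animals = 5)
  expect_equal(s2$n_non_motile, 1L)
  expect_equal(s2$frac_active, 0.8)
  ## zero tracks -> invalid record with a warning
  expect_warning(s0 <- chamber_summary(structure(list(), class = "track_set"),
                                       img, ch), "invalid")
  expect_false(s0$valid)
})

test_that("metrics are invariant to track order and scale with calibration", {
  ch <- default_chamber()
  img <- imaging_config(mm_per_px = ch$mm_per_px, fps = 30)
  truths <- lapply(1:5, function(a) {
    sample_trajectory(locomotion_params(), ch, 15, 30, seed = 40 + a,
                      animal_id = a)
  })
  tracks <- truth_tracks(truths)
  s1 <- chamber_summary(tracks, img, ch, n_animals = 5)
  s2 <- chamber_summary(structure(rev(tracks), class = "track_set"), img, ch,
                        n_animals = 5)
  expect_equal(s1$total_distance_mm, s2$total_distance_mm)
  ## doubling all coordinates (and the floor) doubles distance exactly
  doubled <- structure(lapply(tracks, function(tr) {
    tr$x_mm <- 2 * tr$x_mm; tr$y_mm <- 2 * tr$y_mm; tr
  }), class = "track_set")
  d1 <- sum(vapply(tracks, function(tr)
    track_metrics(tr, img, 0.08)$total_distance_mm, 1))
  d2 <- sum(vapply(doubled, function(tr)
    track_metrics(tr, img, 0.16)$total_distance_mm, 1))
  expect_equal(d2, 2 * d1, tolerance = 1e-9)
})

test_that("normalization to controls reproduces known percentage changes", {
  ep <- function(vals, time_h = 1) {
    data.frame(time_h = time_h, total_distance_mm = vals, valid = TRUE)
  }
  ## identity -> 0%
  r <- normalize_to_control(ep(c(10, 10, 10)), ep(c(10, 10, 10)))
  expect_equal(r$pct_change, 0)
  ## treated 4 vs control 10 -> -60%
  r2 <- normalize_to_control(ep(c(4, 4, 4)), ep(c(10, 10, 10)))
  expect_equal(r2$pct_change, -60)
  ## control spread >= 5% raises the QC warning
  expect_warning(normalize_to_control(ep(c(4, 4, 4)), ep(c(9, 10, 11))),
                 "5%")
  ## zero control metric is an error
  expect_error(normalize_to_control(ep(c(4, 4)), ep(c(0, 0))), "control")
})

test_that("response syndromes follow the thresholds and time windows", {
  mk <- function(time_h, pct, p) {
    data.frame(concentration = 1, time_h = time_h, pct_change = pct,
               p_value = p, control_mean = 10, treated_mean = 10,
               control_qc_flag = FALSE, label = NA_character_)
  }
  expect_equal(classify_response(mk(2, 25, 0.01))$label, "hyperactivity")
  expect_equal(classify_response(mk(1, -85, NA))$label, "cessation")
  expect_equal(classify_response(mk(2, -10, 0.3))$label, "none")
  expect_equal(classify_response(mk(24, -50, 0.01))$label, "hypoactivity")
  ## +25% outside the 1-8 h window is not hyperactivity
  expect_equal(classify_response(mk(24, 25, 0.01))$label, "none")
  ## cessation only applies at the first timepoint; later -85% with
  ## significance is hypoactivity
  ser <- rbind(mk(1, -85, NA), mk(8, -85, 0.01))
  expect_equal(classify_response(ser)$label, c("cessation", "hypoactivity"))
})

test_that("activity multipliers are recovered by the endpoint chain", {
  ## generative multiplier m -> measured pct change within +-7 points of
  ## 100 (m - 1), truth-bypass lane
  for (m in c(0.2, 0.4, 1.0, 1.25)) {
    r <- behavior_recovery_experiment(m, n_seeds = 50, mode = "truth",
                                      seed = 17)
    expect_lt(abs(mean(r$pct_change) - 100 * (m - 1)), 7)
  }
})
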