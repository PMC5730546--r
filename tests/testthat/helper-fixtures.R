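## Shared fixtures for the suite. Everything is generated in code; seeds are
## fixed so results are reproducible.

default_chamber <- function() chamber_spec()

## a chamber so large that walls play no role (kinematics tests)
open_water <- function() {
  chamber_spec(length_mm = 200, width_mm = 200, mm_per_px = 1)
}

## wide, coarsely sampled chamber used for multi-animal imaging tests
wide_chamber <- function(mm_per_px = 13 / 128) {
  chamber_spec(length_mm = 13, width_mm = 40, mm_per_px = mm_per_px)
}

## five well-separated swimmers in the wide chamber (frozen seed block whose
## minimum pairwise distance stays above three body lengths for 30 s)
separated_truths <- function(duration_s = 30, fps = 30, seed_block = 6000) {
  ch <- wide_chamber()
  lapply(1:5, function(a) {
    sample_trajectory(locomotion_params(upward_bias = 0.5), ch,
                      duration_s, fps, seed = seed_block + a,
                      start_mm = c(4 + 8 * (a - 1), 6.5), animal_id = a)
  })
}

## build a track object directly from coordinate vectors
make_track <- function(x, y, fps = 30, id = 1L) {
  n <- length(x)
  structure(data.frame(
    track_id = id, frame = seq_len(n) - 1L, t_s = (seq_len(n) - 1) / fps,
    x_mm = x, y_mm = y, interpolated = FALSE
  ), class = c("track", "data.frame"))
}

## brute-force reference assignment by permutation enumeration
brute_force_assignment <- function(cost) {
  n <- nrow(cost)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    }
    out
  }
  best <- NULL
  best_cost <- Inf
  for (p in perms(seq_len(n))) {
    cc <- sum(cost[cbind(seq_len(n), p)])
    if (cc < best_cost - 1e-12) {
      best_cost <- cc
      best <- p
    }
  }
  list(assignment = best, cost = best_cost)
}
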