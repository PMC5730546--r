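#' Hop-and-rest locomotion parameters
#'
#' Parameterizes the characteristic swimming style of *Daphnia* neonates:
#' brief antenna-powered hops alternating with passive rests during which the
#' animal sinks under gravity. Hops are initiated at `hop_rate_hz` while the
#' animal is motile, each displacing the animal by a truncated-normal length
#' in a direction uniform in angle except that the vertical component points
#' upwards (against gravity) with probability `upward_bias`.
#'
#' The expected actively swum distance per unit time is
#' `hop_rate_hz * E[hop length]` (see [expected_distance_rate()]); passive
#' sedimentation drift during rests is excluded from that expectation.
#'
#' @param hop_rate_hz mean hop initiation rate while motile (hops per second).
#' @param hop_length_mm_mean,hop_length_mm_sd mean and SD of the per-hop
#'   displacement (mm); draws are truncated at zero.
#' @param hop_duration_s duration of the active burst of one hop (s). Must
#'   satisfy `hop_rate_hz * hop_duration_s < 1` so that a mean rest period
#'   remains between hops.
#' @param sink_speed_mm_s passive sedimentation speed during rests (mm/s).
#' @param upward_bias probability that a hop's vertical component points
#'   against gravity.
#' @param body_length_mm animal body length (mm); neonates are about 0.6 mm.
#' @return An object of class `locomotion_params`.
#' @export
locomotion_params <- function(hop_rate_hz = 1.0,
                              hop_length_mm_mean = 1.5,
                              hop_length_mm_sd = 0.3,
                              hop_duration_s = 0.2,
                              sink_speed_mm_s = 0.5,
                              upward_bias = 0.7,
                              body_length_mm = 0.6) {
  check_number(hop_rate_hz, "hop_rate_hz", min = 0)
  check_number(hop_length_mm_mean, "hop_length_mm_mean", min = 0)
  check_number(hop_length_mm_sd, "hop_length_mm_sd", min = 0)
  check_number(hop_duration_s, "hop_duration_s", min = 0, strict_min = TRUE)
  check_number(sink_speed_mm_s, "sink_speed_mm_s", min = 0)
  check_number(upward_bias, "upward_bias", min = 0, max = 1)
  check_number(body_length_mm, "body_length_mm", min = 0, strict_min = TRUE)
  if (hop_rate_hz > 0 && hop_rate_hz * hop_duration_s >= 1) {
    stop("'hop_duration_s' too long for 'hop_rate_hz': ",
         "hop_rate_hz * hop_duration_s must be < 1", call. = FALSE)
  }
  structure(list(
    hop_rate_hz = hop_rate_hz,
    hop_length_mm_mean = hop_length_mm_mean,
    hop_length_mm_sd = hop_length_mm_sd,
    hop_duration_s = hop_duration_s,
    sink_speed_mm_s = sink_speed_mm_s,
    upward_bias = upward_bias,
    body_length_mm = body_length_mm
  ), class = "locomotion_params")
}

#' Expected actively swum distance per second
#'
#' Closed-form expectation `hop_rate_hz * E[hop length]`, where the hop
#' length is normal truncated at zero. Sedimentation drift during rests is
#' excluded. Used as the generative oracle in parameter-recovery checks.
#'
#' @param params a [locomotion_params()] object.
#' @return expected active distance rate in mm/s.
#' @export
expected_distance_rate <- function(params) {
  stopifnot(inherits(params, "locomotion_params"))
  params$hop_rate_hz *
    truncnorm_mean(params$hop_length_mm_mean, params$hop_length_mm_sd)
}

## triangular-wave fold: specular reflection of out-of-bounds coordinates
reflect_into <- function(u, lo, hi) {
  w <- hi - lo
  z <- (u - lo) %% (2 * w)
  lo + ifelse(z > w, 2 * w - z, z)
}

#' Simulate one animal's ground-truth trajectory
#'
#' Draws a hop-and-rest trajectory as an alternating-renewal process: rest
#' durations are exponential with mean `1/hop_rate_hz - hop_duration_s` (so
#' that hops are initiated at `hop_rate_hz` on average), each hop displaces
#' the animal by a truncated-normal length spread uniformly over
#' `hop_duration_s`, and during rests the animal sinks at `sink_speed_mm_s`
#' until it reaches the chamber bottom. Hop displacements are reflected
#' specularly at the chamber walls; sinking is clamped at the bottom.
#'
#' Animals flagged `immobile` do not move: they are placed, already
#' sedimented, inside the bottom 10% band of the chamber, emulating the
#' standard immobilization scoring (no reaction within the observation
#' window) in which non-motile animals have sunk to the chamber floor.
#'
#' @param params a [locomotion_params()] object.
#' @param chamber a [chamber_spec()] object.
#' @param duration_s,fps clip length (s) and sampling rate (frames/s);
#'   positions are reported on the rendering frame grid.
#' @param seed explicit integer seed; trajectories are fully reproducible.
#' @param start_mm optional `c(x, y)` start position in mm; default uniform
#'   inside the walls.
#' @param immobile logical; if `TRUE` the animal is rendered sedimented and
#'   motionless for the whole clip.
#' @param animal_id identifier carried into the output.
#' @return An object of class `animal_truth`: a list with `animal_id`,
#'   `immobile`, `body_length_mm`, and `positions`, a data frame with
#'   columns `frame` (0-based), `t_s`, `x_mm`, `y_mm` (y increases downwards)
#'   and `phase` (`hopping`, `resting` or `immobile`).
#' @examples
#' tr <- sample_trajectory(locomotion_params(), chamber_spec(),
#'                         duration_s = 5, fps = 30, seed = 1)
#' head(tr$positions)
#' @export
sample_trajectory <- function(params, chamber, duration_s, fps, seed,
                              start_mm = NULL, immobile = FALSE,
                              animal_id = 1L) {
  stopifnot(inherits(params, "locomotion_params"),
            inherits(chamber, "chamber_spec"))
  check_number(duration_s, "duration_s", min = 0, strict_min = TRUE)
  check_number(fps, "fps", min = 0, strict_min = TRUE)
  check_flag(immobile, "immobile")
  n <- round(fps * duration_s)
  t_s <- (seq_len(n) - 1) / fps
  margin <- params$body_length_mm / 2
  xlim <- c(margin, chamber$width_mm - margin)
  ylim <- c(margin, chamber$length_mm - margin)
  if (diff(xlim) <= 0 || diff(ylim) <= 0) {
    stop("chamber too small for 'body_length_mm'", call. = FALSE)
  }
  if (!is.null(start_mm)) {
    check_number(start_mm, "start_mm", len = 2L)
    if (start_mm[1] < 0 || start_mm[1] > chamber$width_mm ||
        start_mm[2] < 0 || start_mm[2] > chamber$length_mm) {
      stop("'start_mm' outside chamber bounds", call. = FALSE)
    }
  }

  out <- with_seed(seed, {
    if (immobile) {
      ## sedimented before the clip starts: parked in the bottom band
      x0 <- start_mm[1] %||% runif(1, xlim[1], xlim[2])
      y0 <- start_mm[2] %||%
        runif(1, max(bottom_band_mm(chamber), ylim[1]) + 0.02 * chamber$length_mm,
              ylim[2])
      y0 <- min(max(y0, bottom_band_mm(chamber)), ylim[2])
      data.frame(frame = seq_len(n) - 1L, t_s = t_s,
                 x_mm = rep(x0, n), y_mm = rep(y0, n),
                 phase = rep("immobile", n), stringsAsFactors = FALSE)
    } else {
      x0 <- start_mm[1] %||% runif(1, xlim[1], xlim[2])
      y0 <- start_mm[2] %||% runif(1, ylim[1], ylim[2])
      x0 <- min(max(x0, xlim[1]), xlim[2])
      y0 <- min(max(y0, ylim[1]), ylim[2])

      ## build the alternating rest/hop event schedule in continuous time
      rest_mean <- if (params$hop_rate_hz > 0) {
        1 / params$hop_rate_hz - params$hop_duration_s
      } else Inf
      t0 <- numeric(0); t1 <- numeric(0)
      vx <- numeric(0); vy <- numeric(0); hop <- logical(0)
      tc <- 0
      while (tc < duration_s) {
        rest <- if (is.finite(rest_mean)) rexp(1, rate = 1 / rest_mean) else Inf
        t0 <- c(t0, tc); t1 <- c(t1, min(tc + rest, duration_s))
        vx <- c(vx, 0); vy <- c(vy, params$sink_speed_mm_s); hop <- c(hop, FALSE)
        tc <- tc + rest
        if (tc >= duration_s) break
        len <- rnorm(1, params$hop_length_mm_mean, params$hop_length_mm_sd)
        if (params$hop_length_mm_sd > 0) {
          for (k in seq_len(100)) {
            if (len >= 0) break
            len <- rnorm(1, params$hop_length_mm_mean, params$hop_length_mm_sd)
          }
          len <- max(len, 0)
        }
        theta <- runif(1, 0, 2 * pi)
        up <- runif(1) < params$upward_bias
        dirx <- cos(theta)
        diry <- if (up) -abs(sin(theta)) else abs(sin(theta))
        speed <- len / params$hop_duration_s
        t0 <- c(t0, tc); t1 <- c(t1, tc + params$hop_duration_s)
        vx <- c(vx, speed * dirx); vy <- c(vy, speed * diry); hop <- c(hop, TRUE)
        tc <- tc + params$hop_duration_s
      }

      ## walk the schedule, sampling positions on the frame grid
      x <- numeric(n); y <- numeric(n)
      phase <- rep("resting", n)
      px <- x0; py <- y0
      for (s in seq_along(t0)) {
        last <- s == length(t0)
        idx <- which(t_s >= t0[s] & (t_s < t1[s] | (last & t_s <= t1[s])))
        if (hop[s]) {
          if (length(idx)) {
            dt <- t_s[idx] - t0[s]
            x[idx] <- reflect_into(px + vx[s] * dt, xlim[1], xlim[2])
            y[idx] <- reflect_into(py + vy[s] * dt, ylim[1], ylim[2])
            phase[idx] <- "hopping"
          }
          dte <- t1[s] - t0[s]
          px <- reflect_into(px + vx[s] * dte, xlim[1], xlim[2])
          py <- reflect_into(py + vy[s] * dte, ylim[1], ylim[2])
        } else {
          ## rest: sink, clamped at the bottom wall
          if (length(idx)) {
            dt <- t_s[idx] - t0[s]
            x[idx] <- px
            y[idx] <- pmin(py + vy[s] * dt, ylim[2])
          }
          dte <- min(t1[s], duration_s) - t0[s]
          py <- min(py + vy[s] * dte, ylim[2])
        }
      }
      data.frame(frame = seq_len(n) - 1L, t_s = t_s, x_mm = x, y_mm = y,
                 phase = phase, stringsAsFactors = FALSE)
    }
  })

  structure(list(
    animal_id = animal_id,
    immobile = immobile,
    body_length_mm = params$body_length_mm,
    positions = out
  ), class = "animal_truth")
}

#' Total path length of a trajectory on the frame grid
#'
#' Sum of frame-to-frame Euclidean displacements of a ground-truth
#' trajectory, optionally suppressing steps below a jitter floor (see
#' [track_metrics()] for the rationale).
#'
#' @param truth an `animal_truth` object.
#' @param jitter_floor_mm displacements below this are zeroed; default 0
#'   (raw path length).
#' @return path length in mm.
#' @export
truth_path_length <- function(truth, jitter_floor_mm = 0) {
  stopifnot(inherits(truth, "animal_truth"))
  p <- truth$positions
  if (nrow(p) < 2) return(0)
  step <- sqrt(diff(p$x_mm)^2 + diff(p$y_mm)^2)
  step[step < jitter_floor_mm] <- 0
  sum(step)
}
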