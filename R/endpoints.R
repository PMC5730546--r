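#' Per-animal locomotor metrics from one track
#'
#' Total distance is the sum of frame-to-frame Euclidean displacements with
#' steps below `jitter_floor_mm` zeroed. The floor removes two non-locomotor
#' contributions: sub-pixel centroid jitter from detection noise, and the
#' slow passive sedimentation drift during rests, which is gravity, not
#' swimming. The default (0.08 mm per frame step) sits above the
#' sedimentation step at the frame rates the pipeline supports (0.5 mm/s is
#' under 0.05 mm/frame at 10 fps and 0.017 at 30 fps) and far below a hop
#' step (0.25 mm/frame at 30 fps and above), so distance measures active
#' locomotion. Mean speed is total distance over track duration; mean
#' absolute acceleration comes from finite differences of the per-frame
#' speed. Interpolated samples are included.
#'
#' @param track a `track` data frame (>= 2 samples).
#' @param imaging an [imaging_config()] (provides `fps`).
#' @param jitter_floor_mm displacement floor per frame step (mm).
#' @return list with `total_distance_mm`, `mean_speed_mm_s`,
#'   `mean_abs_acceleration_mm_s2`, `duration_s`, `n_samples`.
#' @examples
#' tr <- structure(data.frame(track_id = 1, frame = 0:1, t_s = c(0, 1),
#'                            x_mm = c(0, 3), y_mm = c(0, 4),
#'                            interpolated = FALSE), class = c("track", "data.frame"))
#' track_metrics(tr, imaging_config(mm_per_px = 0.05, fps = 1))$total_distance_mm # 5
#' @export
track_metrics <- function(track, imaging, jitter_floor_mm = 0.08) {
  stopifnot(inherits(imaging, "imaging_config"))
  check_number(jitter_floor_mm, "jitter_floor_mm", min = 0)
  if (nrow(track) < 2) {
    stop("track must have at least 2 samples", call. = FALSE)
  }
  step <- sqrt(diff(track$x_mm)^2 + diff(track$y_mm)^2)
  step[step < jitter_floor_mm] <- 0
  dt <- diff(track$t_s)
  if (any(dt <= 0)) stop("track time must be strictly increasing", call. = FALSE)
  total <- sum(step)
  duration <- track$t_s[nrow(track)] - track$t_s[1]
  speed <- step / dt
  accel <- if (length(speed) > 1) diff(speed) / dt[-1] else numeric(0)
  list(
    total_distance_mm = total,
    mean_speed_mm_s = total / duration,
    mean_abs_acceleration_mm_s2 = if (length(accel)) mean(abs(accel)) else 0,
    duration_s = duration,
    n_samples = nrow(track)
  )
}

#' Classify a track as motile or non-motile
#'
#' The imaging analogue of the standard immobilization criterion (no
#' reaction within 10 s): a track is `non_motile` when its displacement
#' stays below `eps_mm` over every sliding window of `window_s` *and* its
#' mean position lies in the bottom 10% band of the chamber (a dead or
#' immobilized animal sediments). Tracks shorter than `window_s` are
#' reported `indeterminate`.
#'
#' @param track a `track` data frame.
#' @param chamber a [chamber_spec()].
#' @param window_s observation window (s), default 10.
#' @param eps_mm displacement tolerance within a window; default half a body
#'   length of a neonate (0.3 mm).
#' @return `"motile"`, `"non_motile"` or `"indeterminate"`.
#' @export
classify_motility <- function(track, chamber, window_s = 10, eps_mm = 0.3) {
  stopifnot(inherits(chamber, "chamber_spec"))
  check_number(window_s, "window_s", min = 0, strict_min = TRUE)
  check_number(eps_mm, "eps_mm", min = 0, strict_min = TRUE)
  span <- track$t_s[nrow(track)] - track$t_s[1]
  if (!is.finite(span) || span < window_s) return("indeterminate")
  n <- nrow(track)
  still <- TRUE
  for (i in seq_len(n)) {
    if (track$t_s[n] - track$t_s[i] < window_s && i > 1) break
    in_win <- which(track$t_s >= track$t_s[i] &
                      track$t_s <= track$t_s[i] + window_s)
    disp <- sqrt((track$x_mm[in_win] - track$x_mm[i])^2 +
                   (track$y_mm[in_win] - track$y_mm[i])^2)
    if (any(disp >= eps_mm)) {
      still <- FALSE
      break
    }
  }
  sedimented <- mean(track$y_mm) >= bottom_band_mm(chamber)
  if (still && sedimented) "non_motile" else "motile"
}

#' Summarize one chamber at one timepoint
#'
#' Averages per-animal metrics over the population kept in the chamber.
#' `total_distance_mm` is the population mean per animal: the summed track
#' distance divided by the number of animals (`n_animals` when known --
#' robust to track fragmentation -- otherwise the number of tracks).
#' `frac_active` is the fraction of tracks whose clip distance exceeds two
#' body lengths; `n_non_motile` counts tracks classified non-motile by
#' [classify_motility()].
#'
#' @param tracks a `track_set` for the chamber.
#' @param imaging an [imaging_config()].
#' @param chamber a [chamber_spec()].
#' @param time_h assay timepoint (hours).
#' @param chamber_id identifier carried into the record.
#' @param n_animals number of animals loaded, when known.
#' @param jitter_floor_mm see [track_metrics()].
#' @param body_length_mm body length for the activity threshold.
#' @return one-row data frame (`endpoint_record`): `chamber_id`, `time_h`,
#'   `n_tracks`, `total_distance_mm`, `mean_speed_mm_s`,
#'   `mean_abs_acceleration_mm_s2`, `frac_active`, `n_non_motile`, `valid`.
#'   With zero tracks the record is flagged invalid (with a warning) and
#'   must be excluded downstream.
#' @export
chamber_summary <- function(tracks, imaging, chamber, time_h = 0,
                            chamber_id = "chamber", n_animals = NULL,
                            jitter_floor_mm = 0.08, body_length_mm = 0.6) {
  if (!length(tracks)) {
    warning(sprintf("chamber %s at %g h: no reportable tracks; record flagged invalid",
                    chamber_id, time_h), call. = FALSE)
    return(data.frame(chamber_id = chamber_id, time_h = time_h, n_tracks = 0L,
                      total_distance_mm = NA_real_, mean_speed_mm_s = NA_real_,
                      mean_abs_acceleration_mm_s2 = NA_real_,
                      frac_active = NA_real_, n_non_motile = NA_integer_,
                      valid = FALSE))
  }
  mets <- lapply(tracks, track_metrics, imaging = imaging,
                 jitter_floor_mm = jitter_floor_mm)
  dists <- vapply(mets, `[[`, 1, "total_distance_mm")
  denom <- n_animals %||% length(tracks)
  moti <- vapply(tracks, classify_motility, "", chamber = chamber)
  n_non <- sum(moti == "non_motile")
  if (!is.null(n_animals)) n_non <- min(n_non, n_animals)
  data.frame(
    chamber_id = chamber_id,
    time_h = time_h,
    n_tracks = length(tracks),
    total_distance_mm = sum(dists) / denom,
    mean_speed_mm_s = mean(vapply(mets, `[[`, 1, "mean_speed_mm_s")),
    mean_abs_acceleration_mm_s2 =
      mean(vapply(mets, `[[`, 1, "mean_abs_acceleration_mm_s2")),
    frac_active = mean(dists > 2 * body_length_mm),
    n_non_motile = n_non,
    valid = TRUE
  )
}

#' Normalize treated endpoints to concurrent controls
#'
#' For every shared timepoint, computes the percentage change of a chosen
#' metric from replicate chamber means, `100 * (treated - control) /
#' control`, and a two-sample Student t-test of the replicate chamber values
#' against the concurrent controls. Control replicates differing by 5% or
#' more (range relative to mean) raise a QC warning, mirroring the assay's
#' control self-consistency requirement.
#'
#' @param treated,control data frames of endpoint records (rows =
#'   replicate chambers x timepoints) sharing `time_h`; invalid records are
#'   dropped.
#' @param metric endpoint column to normalize (default total distance).
#' @param concentration concentration label carried into the output.
#' @return data frame of class `normalized_response`: `concentration`,
#'   `time_h`, `pct_change`, `p_value`, `control_mean`, `treated_mean`,
#'   `control_qc_flag`, `label` (filled by [classify_response()]).
#' @export
normalize_to_control <- function(treated, control,
                                 metric = "total_distance_mm",
                                 concentration = NA_real_) {
  for (nm in c("time_h", metric)) {
    if (!nm %in% names(treated) || !nm %in% names(control)) {
      stop(sprintf("'%s' column missing from endpoint records", nm),
           call. = FALSE)
    }
  }
  if ("valid" %in% names(treated)) treated <- treated[treated$valid, ]
  if ("valid" %in% names(control)) control <- control[control$valid, ]
  times <- sort(intersect(unique(treated$time_h), unique(control$time_h)))
  if (!length(times)) {
    stop("treated and control share no timepoints", call. = FALSE)
  }
  rows <- lapply(times, function(tt) {
    tv <- treated[[metric]][treated$time_h == tt]
    cv <- control[[metric]][control$time_h == tt]
    mc <- mean(cv)
    if (!is.finite(mc) || mc <= 0) {
      stop(sprintf("control metric is zero or undefined at %g h: ", tt),
           call. = FALSE)
    }
    qc <- length(cv) > 1 && diff(range(cv)) / mc >= 0.05
    if (qc) {
      warning(sprintf(
        "control replicates at %g h differ by >= 5%% (range %.1f%% of mean)",
        tt, 100 * diff(range(cv)) / mc), call. = FALSE)
    }
    p <- if (length(tv) >= 2 && length(cv) >= 2) {
      ## essentially-constant replicates (e.g. identical chambers in
      ## synthetic identity checks) carry no evidence either way
      tryCatch(t.test(tv, cv, var.equal = TRUE)$p.value,
               error = function(e) NA_real_)
    } else NA_real_
    data.frame(concentration = concentration, time_h = tt,
               pct_change = 100 * (mean(tv) - mc) / mc, p_value = p,
               control_mean = mc, treated_mean = mean(tv),
               control_qc_flag = qc, label = NA_character_)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("normalized_response", "data.frame")
  out
}

#' Classify response syndromes over time
#'
#' Labels each timepoint of a normalized response series:
#' \itemize{
#'   \item `cessation`: change <= -80% at the first post-exposure timepoint
#'     (immediate near-total loss of activity; no significance requirement);
#'   \item `hyperactivity`: change >= +20% with p < 0.05 within the 1-8 h
#'     exposure window;
#'   \item `hypoactivity`: change <= -20% with p < 0.05 (threshold chosen
#'     symmetric to the hyperactivity definition);
#'   \item `none` otherwise. Cessation takes precedence over hypoactivity.
#' }
#'
#' @param series a `normalized_response` data frame ordered or orderable by
#'   `time_h`, with `pct_change` and `p_value`.
#' @return the series with the `label` column filled.
#' @export
classify_response <- function(series) {
  stopifnot(all(c("time_h", "pct_change", "p_value") %in% names(series)))
  series <- series[order(series$time_h), , drop = FALSE]
  first_t <- series$time_h[1]
  lab <- rep("none", nrow(series))
  sig <- !is.na(series$p_value) & series$p_value < 0.05
  lab[sig & series$pct_change <= -20] <- "hypoactivity"
  lab[series$time_h == first_t & series$pct_change <= -80] <- "cessation"
  lab[sig & series$pct_change >= 20 &
        series$time_h >= 1 & series$time_h <= 8] <- "hyperactivity"
  series$label <- lab
  series
}
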