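#' Tracking configuration
#'
#' Controls linking of detections into trajectories. `gate_mm` is the
#' largest plausible displacement per frame interval; a track that goes
#' undetected accumulates gap allowance `gate_mm * (1 + gap length)`. Tracks
#' undetected for more than `max_gap_frames` are closed; gaps up to that
#' length are bridged by linear interpolation. Tracks shorter than
#' `min_track_frames` are discarded as spurious.
#'
#' The default gate (4.5 mm) is three times the default mean hop length: a
#' hop is the largest displacement one frame interval can plausibly contain.
#' No motion model is used (constant-position prediction): hop-and-rest
#' motion is bursty and poorly served by constant-velocity extrapolation.
#'
#' @param gate_mm maximum displacement per frame interval (mm, > 0).
#' @param max_gap_frames frames a track may go undetected before it is
#'   closed (>= 0).
#' @param min_track_frames minimum reported track length (samples).
#' @return An object of class `tracking_config`.
#' @export
tracking_config <- function(gate_mm = 4.5, max_gap_frames = 3L,
                            min_track_frames = 15L) {
  check_number(gate_mm, "gate_mm", min = 0, strict_min = TRUE)
  check_number(max_gap_frames, "max_gap_frames", min = 0)
  check_number(min_track_frames, "min_track_frames", min = 1)
  structure(list(
    gate_mm = gate_mm,
    max_gap_frames = as.integer(max_gap_frames),
    min_track_frames = as.integer(min_track_frames)
  ), class = "tracking_config")
}

BIG_COST <- 1e9

#' Link detections into per-animal tracks
#'
#' Frame by frame, live tracks and detections are matched one-to-one by the
#' Hungarian algorithm minimizing summed squared distance; assignments
#' beyond the (gap-scaled) gate are forbidden. Unmatched detections open new
#' tracks; tracks unmatched for more than `max_gap_frames` are closed; gaps
#' within the allowance are bridged by linear interpolation with the
#' `interpolated` flag set. Equal-cost ties resolve to the lowest track id
#' and then the lowest detection x, so the assignment is independent of
#' detection order within a frame.
#'
#' @param detections data frame from [detect_clip()] (columns `frame_index`,
#'   `x_px`, `y_px`; or precalibrated `x_mm`, `y_mm`).
#' @param config a [tracking_config()].
#' @param imaging an [imaging_config()]; provides `mm_per_px` (required when
#'   detections are in pixels) and `fps` for time stamps.
#' @return A list of class `track_set`; each element is a data frame of
#'   class `track` with columns `track_id`, `frame`, `t_s`, `x_mm`, `y_mm`,
#'   `interpolated`. Empty input gives an empty track set.
#' @export
link_tracks <- function(detections, config = tracking_config(), imaging) {
  stopifnot(inherits(config, "tracking_config"))
  if (nrow(detections) == 0) {
    return(structure(list(), class = "track_set"))
  }
  if (all(c("x_mm", "y_mm") %in% names(detections))) {
    det <- data.frame(frame = detections$frame_index %||% detections$frame,
                      x = detections$x_mm, y = detections$y_mm)
  } else {
    if (missing(imaging) || !inherits(imaging, "imaging_config")) {
      stop("pixel detections require an imaging_config for calibration",
           call. = FALSE)
    }
    ## invert the pixel-centre convention used by the renderer
    det <- data.frame(frame = detections$frame_index,
                      x = (detections$x_px - 0.5) * imaging$mm_per_px,
                      y = (detections$y_px - 0.5) * imaging$mm_per_px)
  }
  fps <- if (!missing(imaging) && inherits(imaging, "imaging_config")) {
    imaging$fps
  } else 1
  if (any(!is.finite(det$frame))) {
    stop("detections must carry frame indices", call. = FALSE)
  }
  det <- det[order(det$frame, det$x, det$y), , drop = FALSE]

  tracks <- list()       # closed + live track records
  live <- integer(0)     # indices into 'tracks' of live tracks
  next_id <- 1L
  gate2 <- function(missed) (config$gate_mm * (1 + missed))^2

  for (f in seq(min(det$frame), max(det$frame))) {
    df <- det[det$frame == f, , drop = FALSE]
    nd <- nrow(df)
    nt <- length(live)
    match_t <- integer(0)
    match_d <- integer(0)
    if (nt > 0 && nd > 0) {
      lastx <- vapply(tracks[live], function(tr) tr$x[length(tr$x)], 1)
      lasty <- vapply(tracks[live], function(tr) tr$y[length(tr$y)], 1)
      missed <- vapply(tracks[live], function(tr) tr$missed, 1L)
      cost <- outer(lastx, df$x, "-")^2 + outer(lasty, df$y, "-")^2
      allow <- gate2(missed)
      cost[cost > allow] <- BIG_COST
      k <- max(nt, nd)
      sq <- matrix(0, k, k)
      sq[seq_len(nt), seq_len(nd)] <- cost
      if (k > nd) sq[, (nd + 1L):k] <- BIG_COST * 2
      if (k > nt) sq[(nt + 1L):k, ] <- BIG_COST * 2
      asg <- solve_assignment(sq)
      for (i in seq_len(nt)) {
        j <- asg[i]
        if (j >= 1 && j <= nd && sq[i, j] < BIG_COST) {
          match_t <- c(match_t, i)
          match_d <- c(match_d, j)
        }
      }
    }

    matched_tracks <- logical(nt)
    matched_dets <- logical(nd)
    if (length(match_t)) {
      for (k2 in seq_along(match_t)) {
        ti <- live[match_t[k2]]
        j <- match_d[k2]
        tr <- tracks[[ti]]
        gap <- f - tr$frame[length(tr$frame)] - 1L
        if (gap > 0) { # bridge the dropout by linear interpolation
          gi <- seq_len(gap)
          w <- gi / (gap + 1)
          tr$frame <- c(tr$frame, tr$frame[length(tr$frame)] + gi)
          tr$x <- c(tr$x, tr$x[length(tr$x)] * (1 - w) + df$x[j] * w)
          tr$y <- c(tr$y, tr$y[length(tr$y)] * (1 - w) + df$y[j] * w)
          tr$interp <- c(tr$interp, rep(TRUE, gap))
        }
        tr$frame <- c(tr$frame, as.integer(f))
        tr$x <- c(tr$x, df$x[j])
        tr$y <- c(tr$y, df$y[j])
        tr$interp <- c(tr$interp, FALSE)
        tr$missed <- 0L
        tracks[[ti]] <- tr
        matched_tracks[match_t[k2]] <- TRUE
        matched_dets[j] <- TRUE
      }
    }
    if (nt > 0) {
      for (i in which(!matched_tracks)) {
        ti <- live[i]
        tracks[[ti]]$missed <- tracks[[ti]]$missed + 1L
      }
    }
    if (nd > 0) {
      for (j in which(!matched_dets)) {
        tracks[[length(tracks) + 1L]] <- list(
          id = next_id, frame = as.integer(f), x = df$x[j], y = df$y[j],
          interp = FALSE, missed = 0L)
        next_id <- next_id + 1L
      }
    }
    live <- which(vapply(tracks, function(tr) tr$missed <= config$max_gap_frames,
                         TRUE))
  }

  keep <- vapply(tracks, function(tr) length(tr$frame) >= config$min_track_frames,
                 TRUE)
  out <- lapply(tracks[keep], function(tr) {
    structure(data.frame(
      track_id = tr$id, frame = tr$frame, t_s = tr$frame / fps,
      x_mm = tr$x, y_mm = tr$y, interpolated = tr$interp
    ), class = c("track", "data.frame"))
  })
  ## renumber in order of first appearance for stable ids after filtering
  ord <- order(vapply(out, function(tr) tr$frame[1], 1),
               vapply(out, function(tr) tr$track_id[1], 1))
  out <- out[ord]
  structure(out, class = "track_set")
}

#' Convert ground-truth trajectories to tracks (truth bypass)
#'
#' Turns simulator ground truth directly into a `track_set`, bypassing
#' detection and linking. This isolates endpoint and statistics correctness
#' from tracker noise.
#'
#' @param truths list of `animal_truth` objects.
#' @return a `track_set`.
#' @export
truth_tracks <- function(truths) {
  out <- lapply(seq_along(truths), function(i) {
    p <- truths[[i]]$positions
    structure(data.frame(
      track_id = i, frame = p$frame, t_s = p$t_s,
      x_mm = p$x_mm, y_mm = p$y_mm,
      interpolated = FALSE
    ), class = c("track", "data.frame"))
  })
  structure(out, class = "track_set")
}

#' Flatten a track set to one data frame
#'
#' The trajectory CSV exchange format between tracking and endpoints:
#' `track_id`, `frame`, `t_s`, `x_mm`, `y_mm`, `interpolated`.
#'
#' @param tracks a `track_set`.
#' @return a single data frame (zero rows for an empty set).
#' @export
tracks_to_df <- function(tracks) {
  if (!length(tracks)) {
    return(data.frame(track_id = integer(0), frame = integer(0),
                      t_s = numeric(0), x_mm = numeric(0), y_mm = numeric(0),
                      interpolated = logical(0)))
  }
  out <- do.call(rbind, tracks)
  rownames(out) <- NULL
  out
}

#' @rdname tracks_to_df
#' @param df data frame in the trajectory CSV format.
#' @export
df_to_tracks <- function(df) {
  out <- lapply(split(df, df$track_id), function(d) {
    d <- d[order(d$frame), , drop = FALSE]
    rownames(d) <- NULL
    structure(d, class = c("track", "data.frame"))
  })
  names(out) <- NULL
  structure(out, class = "track_set")
}

#' Write / read trajectory CSV files
#' @param tracks a `track_set`.
#' @param path file path.
#' @return `read_tracks_csv` returns a `track_set`.
#' @export
write_tracks_csv <- function(tracks, path) {
  write.csv(tracks_to_df(tracks), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracks_csv
#' @export
read_tracks_csv <- function(path) {
  df_to_tracks(read.csv(path))
}

#' Score reconstructed tracks against simulator ground truth
#'
#' For synthetic runs only. Each track sample is attributed to the nearest
#' ground-truth animal within one body length; identity swaps are counted as
#' changes of attribution along a track. Also reports the fraction of truth
#' samples recovered within one body length and the absolute error of the
#' chamber total (jitter-floored) distance. Used to reproduce the density
#' effect: identity errors grow with animals per chamber.
#'
#' @param tracks a `track_set`.
#' @param truths list of `animal_truth` objects on one time base.
#' @param body_length_mm match radius (one body length).
#' @param jitter_floor_mm floor used for the distance comparison (see
#'   [track_metrics()]).
#' @return list with `n_swaps`, `matched_fraction`, `distance_error_mm`,
#'   `distance_error_frac`, `n_tracks`.
#' @export
evaluate_tracking <- function(tracks, truths, body_length_mm = 0.6,
                              jitter_floor_mm = 0.08) {
  stopifnot(length(truths) > 0)
  nfr <- vapply(truths, function(tr) nrow(tr$positions), 1L)
  if (length(unique(nfr)) != 1L) {
    stop("truths must share one time base", call. = FALSE)
  }
  frames <- truths[[1]]$positions$frame
  tx <- vapply(truths, function(tr) tr$positions$x_mm, numeric(nfr[1]))
  ty <- vapply(truths, function(tr) tr$positions$y_mm, numeric(nfr[1]))
  frame_row <- function(f) {
    r <- match(f, frames)
    if (any(is.na(r))) stop("track frames outside the truth time base",
                            call. = FALSE)
    r
  }

  n_swaps <- 0L
  for (tr in tracks) {
    r <- frame_row(tr$frame)
    d2 <- (tx[r, , drop = FALSE] - tr$x_mm)^2 +
      (ty[r, , drop = FALSE] - tr$y_mm)^2
    nearest <- max.col(-d2, ties.method = "first")
    dist <- sqrt(d2[cbind(seq_along(nearest), nearest)])
    ids <- ifelse(dist <= body_length_mm, nearest, NA_integer_)
    ids <- ids[!is.na(ids)]
    if (length(ids) > 1) n_swaps <- n_swaps + sum(diff(ids) != 0)
  }

  ## truth-sample recovery
  tdf <- tracks_to_df(tracks)
  matched <- 0L
  total <- length(frames) * length(truths)
  if (nrow(tdf)) {
    by_frame <- split(tdf, tdf$frame)
    for (fch in names(by_frame)) {
      f <- as.integer(fch)
      r <- match(f, frames)
      if (is.na(r)) stop("track frames outside the truth time base",
                         call. = FALSE)
      sub <- by_frame[[fch]]
      for (a in seq_along(truths)) {
        d2 <- (sub$x_mm - tx[r, a])^2 + (sub$y_mm - ty[r, a])^2
        if (any(d2 <= body_length_mm^2)) matched <- matched + 1L
      }
    }
  }

  truth_dist <- sum(vapply(truths, truth_path_length, 1,
                           jitter_floor_mm = jitter_floor_mm))
  track_dist <- sum(vapply(tracks, function(tr) {
    step <- sqrt(diff(tr$x_mm)^2 + diff(tr$y_mm)^2)
    step[step < jitter_floor_mm] <- 0
    sum(step)
  }, 1))
  list(
    n_swaps = n_swaps,
    matched_fraction = matched / total,
    distance_error_mm = abs(track_dist - truth_dist),
    distance_error_frac = if (truth_dist > 0) {
      abs(track_dist - truth_dist) / truth_dist
    } else as.numeric(track_dist > 0),
    n_tracks = length(tracks)
  )
}
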