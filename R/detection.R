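#' Imaging and detection configuration
#'
#' Settings for converting frames into candidate animal positions. Animals
#' are darker than the back-illuminated background (fixed polarity);
#' foreground pixels are those whose intensity falls more than
#' `threshold_offset` below the background estimate. Connected components
#' are accepted when their area lies within
#' `[min_area_factor, max_area_factor]` times the expected animal area
#' computed from `body_length_mm` and `mm_per_px`.
#'
#' @param mm_per_px spatial calibration (mm per pixel).
#' @param fps acquisition frame rate (frames/s).
#' @param body_length_mm nominal animal length used for the expected blob
#'   area (ellipse with 0.6 aspect ratio).
#' @param threshold_offset intensity margin below background; `NULL` (the
#'   default) means estimate it per clip as 5 times the robust (MAD) noise
#'   SD of background-subtracted pixels.
#' @param min_area_factor,max_area_factor accepted blob area range as
#'   multiples of the expected animal area. The defaults (0.25, 4) tolerate
#'   partial occlusion and touching pairs while rejecting specks.
#' @return An object of class `imaging_config`.
#' @export
imaging_config <- function(mm_per_px, fps, body_length_mm = 0.6,
                           threshold_offset = NULL,
                           min_area_factor = 0.25, max_area_factor = 4) {
  check_number(mm_per_px, "mm_per_px", min = 0, strict_min = TRUE)
  check_number(fps, "fps", min = 0, strict_min = TRUE)
  check_number(body_length_mm, "body_length_mm", min = 0, strict_min = TRUE)
  if (!is.null(threshold_offset)) {
    check_number(threshold_offset, "threshold_offset", min = 0, strict_min = TRUE)
  }
  check_number(min_area_factor, "min_area_factor", min = 0, strict_min = TRUE)
  check_number(max_area_factor, "max_area_factor", min = 0, strict_min = TRUE)
  if (min_area_factor >= max_area_factor) {
    stop("'min_area_factor' must be < 'max_area_factor'", call. = FALSE)
  }
  a <- 0.5 * body_length_mm / mm_per_px
  structure(list(
    mm_per_px = mm_per_px,
    fps = fps,
    body_length_mm = body_length_mm,
    threshold_offset = threshold_offset,
    min_area_factor = min_area_factor,
    max_area_factor = max_area_factor,
    expected_area_px = pi * a * (0.6 * a)
  ), class = "imaging_config")
}

as_frame_stack <- function(frames) {
  if (inherits(frames, "synthetic_clip")) return(frames$frames)
  if (is.list(frames)) {
    stopifnot(length(frames) > 0)
    return(array(unlist(frames), dim = c(dim(frames[[1]]), length(frames))))
  }
  if (is.array(frames) && length(dim(frames)) == 3) return(frames)
  if (is.matrix(frames)) return(array(frames, dim = c(dim(frames), 1L)))
  stop("'frames' must be a synthetic_clip, a 3-d array, or a list of matrices",
       call. = FALSE)
}

#' Estimate the static background of a clip
#'
#' Per-pixel temporal median over the frame stack. Moving animals occupy any
#' given pixel in a minority of frames, so the median recovers the empty
#' chamber image. For long clips an evenly spaced subset of frames
#' (`max_frames`, default 51) is used; the median is insensitive to this
#' subsampling.
#'
#' @param frames a `synthetic_clip`, a `ny x nx x nframes` array, or a list
#'   of matrices; at least 5 frames.
#' @param max_frames maximum number of frames entering the median.
#' @return background image matrix (`ny x nx`).
#' @export
estimate_background <- function(frames, max_frames = 51L) {
  stack <- as_frame_stack(frames)
  nf <- dim(stack)[3]
  if (nf < 5) stop("at least 5 frames are required", call. = FALSE)
  use <- if (nf > max_frames) {
    unique(round(seq(1, nf, length.out = max_frames)))
  } else seq_len(nf)
  m <- matrix(stack[, , use], nrow = prod(dim(stack)[1:2]), ncol = length(use))
  matrix(row_medians(m), dim(stack)[1], dim(stack)[2])
}

#' Robust noise estimate of background-subtracted frames
#'
#' Median absolute deviation (scaled to SD) of `background - frame`
#' residuals over a pixel sample; drives the default detection threshold.
#'
#' @param frames frames as in [estimate_background()].
#' @param background background image from [estimate_background()].
#' @param max_pixels sample size cap.
#' @return noise SD estimate (intensity units).
#' @export
estimate_noise_sd <- function(frames, background, max_pixels = 2e5) {
  stack <- as_frame_stack(frames)
  nf <- dim(stack)[3]
  ## a handful of frames carries plenty of pixels for a MAD estimate
  use <- unique(round(seq(1, nf, length.out = min(nf, 5))))
  resid <- as.numeric(background) - as.numeric(stack[, , use])
  if (length(resid) > max_pixels) {
    idx <- round(seq(1, length(resid), length.out = max_pixels))
    resid <- resid[idx]
  }
  mad(resid, center = 0)
}

#' Detect animals in one frame
#'
#' The thresholding stage of the pipeline: pixels whose intensity falls more
#' than `threshold_offset` below the background are foreground; 8-connected
#' components with area inside the configured gate become detections with
#' intensity-weighted (sub-pixel) centroids. Records are sorted by centroid
#' x then y so the output is deterministic.
#'
#' @param frame image matrix (rows = image y, columns = image x).
#' @param background background matrix of the same shape.
#' @param config an [imaging_config()]; its `threshold_offset` must be set
#'   (use [detect_clip()] for the automatic per-clip threshold).
#' @return data frame with columns `frame_index`, `t_s` (both `NA` here;
#'   filled by [detect_clip()]), `x_px`, `y_px`, `area_px`,
#'   `mean_intensity`.
#' @export
detect_frame <- function(frame, background, config) {
  stopifnot(inherits(config, "imaging_config"))
  if (!is.matrix(frame) || !is.matrix(background) ||
      !all(dim(frame) == dim(background))) {
    stop("'frame' and 'background' must be matrices of the same shape",
         call. = FALSE)
  }
  thr <- config$threshold_offset
  if (is.null(thr)) {
    stop("'threshold_offset' is not set; supply it in imaging_config() or ",
         "use detect_clip()", call. = FALSE)
  }
  diffim <- background - frame
  mask <- diffim > thr
  if (!any(mask)) return(empty_detections())

  lab <- EBImage::bwlabel(mask)
  lab_v <- as.integer(lab)
  areas <- tabulate(lab_v)
  lim <- config$expected_area_px * c(config$min_area_factor,
                                     config$max_area_factor)
  keep <- which(areas >= lim[1] & areas <= lim[2])
  if (!length(keep)) return(empty_detections())

  idx <- which(lab_v %in% keep)
  labk <- lab_v[idx]
  ny <- nrow(frame)
  ry <- ((idx - 1L) %% ny) + 1L        # image row  = y
  cx <- ((idx - 1L) %/% ny) + 1L       # image col  = x
  w <- diffim[idx]
  sw <- rowsum(w, labk)
  sx <- rowsum(w * cx, labk)
  sy <- rowsum(w * ry, labk)
  sint <- rowsum(frame[idx], labk)
  labs <- as.integer(rownames(sw))
  out <- data.frame(
    frame_index = NA_integer_,
    t_s = NA_real_,
    x_px = as.numeric(sx / sw),
    y_px = as.numeric(sy / sw),
    area_px = areas[labs],
    mean_intensity = as.numeric(sint) / areas[labs]
  )
  out[order(out$x_px, out$y_px), , drop = FALSE]
}

empty_detections <- function() {
  data.frame(frame_index = integer(0), t_s = numeric(0), x_px = numeric(0),
             y_px = numeric(0), area_px = numeric(0),
             mean_intensity = numeric(0))
}

#' Detect animals across a whole clip
#'
#' Estimates the background and the noise level, resolves the detection
#' threshold (explicit `threshold_offset`, or 5 x the robust noise SD), and
#' runs [detect_frame()] on every frame.
#'
#' @param clip a `synthetic_clip` or a `ny x nx x nframes` array.
#' @param config an [imaging_config()].
#' @param background optional precomputed background.
#' @return data frame of detections with `frame_index` (0-based) and `t_s`
#'   filled in; attribute `"threshold_offset"` records the threshold used.
#' @export
detect_clip <- function(clip, config, background = NULL) {
  stopifnot(inherits(config, "imaging_config"))
  stack <- as_frame_stack(clip)
  if (is.null(background)) background <- estimate_background(stack)
  thr <- config$threshold_offset
  if (is.null(thr)) {
    thr <- 5 * estimate_noise_sd(stack, background)
    thr <- max(thr, 1e-4) # guard for noise-free synthetic clips
  }
  cfg <- config
  cfg$threshold_offset <- thr
  nf <- dim(stack)[3]
  recs <- vector("list", nf)
  for (f in seq_len(nf)) {
    d <- detect_frame(stack[, , f], background, cfg)
    if (nrow(d)) {
      d$frame_index <- f - 1L
      d$t_s <- (f - 1L) / config$fps
    }
    recs[[f]] <- d
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  attr(out, "threshold_offset") <- thr
  out
}

#' Write / read detection tables
#'
#' CSV exchange format for detections: `frame`, `t_s`, `x_px`, `y_px`,
#' `area_px`.
#'
#' @param detections data frame from [detect_clip()].
#' @param path file path.
#' @return `read_detections_csv` returns the detection data frame.
#' @export
write_detections_csv <- function(detections, path) {
  out <- data.frame(frame = detections$frame_index, t_s = detections$t_s,
                    x_px = detections$x_px, y_px = detections$y_px,
                    area_px = detections$area_px)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_detections_csv
#' @export
read_detections_csv <- function(path) {
  d <- read.csv(path)
  data.frame(frame_index = as.integer(d$frame), t_s = d$t_s, x_px = d$x_px,
             y_px = d$y_px, area_px = d$area_px,
             mean_intensity = NA_real_)
}
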