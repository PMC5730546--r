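#' Render a synthetic chamber video clip
#'
#' Draws each animal as a dark ellipse (major axis = body length) on a
#' uniform light background with a dark chamber border, the imaging geometry
#' of a back-illuminated chamber. Ellipse edges fall off with a Gaussian
#' profile of width `blur_px` (optical blur), and i.i.d. Gaussian read noise
#' of SD `noise_sd` is added per pixel; intensities are clipped to `[0, 1]`.
#' Ellipses are oriented along the instantaneous direction of motion.
#'
#' @param truths list of `animal_truth` objects sharing one time base.
#' @param chamber a [chamber_spec()] object; sets the image size via
#'   `mm_per_px`.
#' @param fps frames per second of the clip (must match the truth time base).
#' @param noise_sd Gaussian pixel noise SD (intensity units, >= 0).
#' @param blur_px edge blur scale in pixels (>= 0.25 effective).
#' @param seed explicit integer seed for the noise.
#' @param background,animal_intensity,border_intensity background, animal
#'   core and border intensities in `[0, 1]`.
#' @param border_px width of the dark chamber border (pixels).
#' @param aspect minor/major axis ratio of the body ellipse.
#' @return An object of class `synthetic_clip`: list with `frames` (array
#'   `ny x nx x nframes`, rows = image y, columns = image x), `fps`,
#'   `duration_s`, `truth`, `chamber` and the rendering settings.
#' @export
render_clip <- function(truths, chamber, fps = 30, noise_sd = 0.02,
                        blur_px = 1, seed = 1, background = 0.9,
                        animal_intensity = 0.15, border_intensity = 0.25,
                        border_px = 2L, aspect = 0.6) {
  stopifnot(inherits(chamber, "chamber_spec"))
  check_number(noise_sd, "noise_sd", min = 0)
  check_number(blur_px, "blur_px", min = 0)
  check_number(fps, "fps", min = 0, strict_min = TRUE)
  if (length(truths) > 0) {
    if (!all(vapply(truths, inherits, TRUE, "animal_truth"))) {
      stop("'truths' must be a list of animal_truth objects", call. = FALSE)
    }
    nf <- vapply(truths, function(tr) nrow(tr$positions), 1L)
    if (length(unique(nf)) != 1L) {
      stop("all truths must share the same time base", call. = FALSE)
    }
    for (tr in truths) {
      p <- tr$positions
      if (any(p$x_mm < 0 | p$x_mm > chamber$width_mm |
              p$y_mm < 0 | p$y_mm > chamber$length_mm)) {
        stop("animal positions outside chamber bounds", call. = FALSE)
      }
      if (max(abs(p$t_s - (p$frame / fps))) > 1e-9) {
        stop("truth time base does not match 'fps'", call. = FALSE)
      }
    }
    n_frames <- nf[1]
  } else {
    n_frames <- as.integer(round(fps)) # 1 s of empty scene
  }

  ny <- chamber$ny; nx <- chamber$nx
  mpp <- chamber$mm_per_px
  template <- matrix(background, ny, nx)
  if (border_px > 0) {
    b <- seq_len(min(border_px, ny, nx))
    template[b, ] <- border_intensity
    template[ny - b + 1L, ] <- border_intensity
    template[, b] <- border_intensity
    template[, nx - b + 1L] <- border_intensity
  }

  a_px <- 0.5 * (if (length(truths)) truths[[1]]$body_length_mm else 0.6) / mpp
  b_px <- aspect * a_px
  edge <- max(blur_px, 0.25)
  pad <- ceiling(a_px + 3 * edge + 1)

  frames <- array(0, dim = c(ny, nx, n_frames))
  for (f in seq_len(n_frames)) {
    img <- template
    for (tr in truths) {
      p <- tr$positions
      ## pixel-centre convention: pixel (r, c) is centred at
      ## ((r - 0.5) * mpp, (c - 0.5) * mpp) in (y, x) mm
      cy <- p$y_mm[f] / mpp + 0.5
      cx <- p$x_mm[f] / mpp + 0.5
      ## orientation along instantaneous motion (zero-motion -> horizontal)
      f2 <- min(f + 1L, nrow(p)); f1 <- max(f - 1L, 1L)
      dy <- p$y_mm[f2] - p$y_mm[f1]; dx <- p$x_mm[f2] - p$x_mm[f1]
      ang <- if (abs(dx) + abs(dy) > 1e-12) atan2(dy, dx) else 0
      rows <- max(1L, floor(cy - pad)):min(ny, ceiling(cy + pad))
      cols <- max(1L, floor(cx - pad)):min(nx, ceiling(cx + pad))
      ry <- rows - cy
      rx <- rep(cols - cx, each = length(rows))
      ry <- rep(ry, times = length(cols))
      u <- rx * cos(ang) + ry * sin(ang)
      v <- -rx * sin(ang) + ry * cos(ang)
      d <- sqrt((u / a_px)^2 + (v / b_px)^2)
      ## Gaussian-profile edge: weight 1 inside, 0 well outside
      w <- pnorm((1 - d) * b_px / edge)
      patch <- img[rows, cols]
      img[rows, cols] <- patch - w * (patch - animal_intensity)
    }
    frames[, , f] <- img
  }

  if (noise_sd > 0) {
    frames <- with_seed(seed, frames + rnorm(length(frames), 0, noise_sd))
  }
  frames[frames < 0] <- 0
  frames[frames > 1] <- 1

  structure(list(
    frames = frames,
    fps = fps,
    duration_s = n_frames / fps,
    truth = truths,
    chamber = chamber,
    noise_sd = noise_sd,
    blur_px = blur_px,
    background = background,
    template = template
  ), class = "synthetic_clip")
}

#' @export
print.synthetic_clip <- function(x, ...) {
  cat(sprintf("synthetic_clip: %d frames (%g s at %g fps), %d x %d px, %d animals\n",
              dim(x$frames)[3], x$duration_s, x$fps,
              dim(x$frames)[1], dim(x$frames)[2], length(x$truth)))
  invisible(x)
}
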