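#' Geometry and calibration of one test chamber
#'
#' Describes a single cuboid chamber of the millifluidic array as seen by a
#' camera looking along the depth axis. Chambers are mounted vertically, so
#' one image axis points down; image pixels map to millimetres through
#' `mm_per_px`. The out-of-plane depth is carried for volume calculations but
#' is not rendered (analysis is restricted to the x-y plane).
#'
#' @param length_mm vertical extent of the chamber (mm); gravity acts along
#'   this axis.
#' @param width_mm horizontal extent (mm).
#' @param depth_mm out-of-plane depth (mm), used only for chamber volume.
#' @param mm_per_px spatial calibration; default scales the 13 mm vertical
#'   extent to 512 pixel rows.
#' @param gravity_axis which image axis points down; only `"+y"` (image rows
#'   increase downwards) is supported.
#' @return An object of class `chamber_spec` with fields `length_mm`,
#'   `width_mm`, `depth_mm`, `mm_per_px`, `gravity_axis`, rendered image size
#'   `ny` x `nx` (rows x columns) and `volume_ul`.
#' @examples
#' ch <- chamber_spec()
#' ch$volume_ul  # 13 x 8 x 2 mm = 208 uL
#' @export
chamber_spec <- function(length_mm = 13, width_mm = 8, depth_mm = 2,
                         mm_per_px = length_mm / 512, gravity_axis = "+y") {
  check_number(length_mm, "length_mm", min = 0, strict_min = TRUE)
  check_number(width_mm, "width_mm", min = 0, strict_min = TRUE)
  check_number(depth_mm, "depth_mm", min = 0, strict_min = TRUE)
  check_number(mm_per_px, "mm_per_px", min = 0, strict_min = TRUE)
  if (!identical(gravity_axis, "+y")) {
    stop("'gravity_axis' must be \"+y\" (image rows increase downwards)",
         call. = FALSE)
  }
  structure(list(
    length_mm = length_mm,
    width_mm = width_mm,
    depth_mm = depth_mm,
    mm_per_px = mm_per_px,
    gravity_axis = gravity_axis,
    ny = as.integer(ceiling(length_mm / mm_per_px)),
    nx = as.integer(ceiling(width_mm / mm_per_px)),
    volume_ul = length_mm * width_mm * depth_mm
  ), class = "chamber_spec")
}

#' @export
print.chamber_spec <- function(x, ...) {
  cat(sprintf(
    "chamber_spec: %g x %g x %g mm (L x W x D), %.4g mm/px -> %d x %d px, %g uL\n",
    x$length_mm, x$width_mm, x$depth_mm, x$mm_per_px, x$ny, x$nx, x$volume_ul))
  invisible(x)
}

## lowest 10% of the chamber height, where sedimented animals accumulate
bottom_band_mm <- function(chamber) 0.9 * chamber$length_mm
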