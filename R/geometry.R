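#' Detector pixel pitch from resolution
#' @param dpi detector resolution in dots per inch (> 0)
#' @return pixel pitch in mm (25.4 / dpi)
#' @export
pixel_pitch <- function(dpi) {
  if (!is.finite(dpi) || dpi <= 0) stopf("dpi must be > 0")
  25.4 / dpi
}

#' Virtual flat-panel imaging geometry
#'
#' The "virtual calibration box": everything needed to map 3D millimetres to
#' detector coordinates. World frame convention: the X-ray source sits at the
#' origin, the detector plane is z = +`sdd`, u points right (+x) and v up
#' (+y) from the principal point. Pixel `[1, 1]` is the top-left detector
#' pixel; v decreases with the row index.
#'
#' @param sdd source-to-detector distance (mm, > 0)
#' @param dpi detector resolution (dots per inch, > 0)
#' @param detector_size integer `(rows, cols)` in pixels
#' @param principal_point `(u0, v0)` pixel coordinates of the source's foot
#'   on the detector; defaults to the detector centre
#' @return an object of class `imaging_geometry`
#' @export
imaging_geometry <- function(sdd = 1150, dpi = 96, detector_size = c(768, 768),
                             principal_point = NULL) {
  if (!is.finite(sdd) || sdd <= 0) stopf("sdd must be > 0")
  pitch <- pixel_pitch(dpi)
  detector_size <- as.integer(detector_size)
  if (length(detector_size) != 2 || any(detector_size < 1))
    stopf("detector_size must be (rows, cols), both >= 1")
  if (is.null(principal_point))
    principal_point <- c((detector_size[2] + 1) / 2, (detector_size[1] + 1) / 2)
  structure(list(sdd = sdd, dpi = dpi, pixel_pitch = pitch,
                 detector_size = detector_size,
                 principal_point = principal_point),
            class = "imaging_geometry")
}

#' @export
print.imaging_geometry <- function(x, ...) {
  cat(sprintf("imaging_geometry: SDD %.1f mm, %.4g DPI (pitch %.6f mm), detector %d x %d px\n",
              x$sdd, x$dpi, x$pixel_pitch, x$detector_size[1], x$detector_size[2]))
  invisible(x)
}

#' Perspective projection onto the detector
#'
#' Central projection from the source at the origin onto the detector plane
#' z = sdd: `u = x * sdd / z`, `v = y * sdd / z` (detector mm relative to the
#' principal point). Points on the central ray map to (0, 0).
#'
#' @param geometry an [imaging_geometry()]
#' @param points3d n x 3 matrix of world points (mm), all with 0 < z < sdd
#' @return n x 2 matrix of (u, v) detector coordinates (mm)
#' @export
project_points <- function(geometry, points3d) {
  points3d <- rbind(points3d)
  z <- points3d[, 3]
  if (any(z <= 0)) stopf("cannot project: point behind the source (z <= 0)")
  if (any(z >= geometry$sdd)) stopf("cannot project: point behind the detector (z >= sdd)")
  s <- geometry$sdd / z
  cbind(u = points3d[, 1] * s, v = points3d[, 2] * s)
}

# detector mm <-> pixel index mapping (pixel [1,1] top-left, v up)
detector_mm_to_px <- function(geometry, uv) {
  uv <- rbind(uv)
  p <- geometry$pixel_pitch
  col <- uv[, 1] / p + geometry$principal_point[1]
  row <- geometry$principal_point[2] - uv[, 2] / p
  cbind(row = row, col = col)
}

detector_px_to_mm <- function(geometry, rowcol) {
  rowcol <- rbind(rowcol)
  p <- geometry$pixel_pitch
  u <- (rowcol[, 2] - geometry$principal_point[1]) * p
  v <- (geometry$principal_point[2] - rowcol[, 1]) * p
  cbind(u = u, v = v)
}

# (u, v) of the centre of pixel [1, 1]
detector_topleft_mm <- function(geometry) {
  detector_px_to_mm(geometry, cbind(1, 1))
}
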