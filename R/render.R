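# Silhouette and synthetic-radiograph rendering. Silhouettes are produced by
# rasterizing the projected triangles with supersampling (robust to the
# femoral component's self-occlusion), not by analytic silhouette-edge
# extraction.

#' Contour in detector-plane millimetres
#'
#' An ordered point sequence on the detector. Both image-derived and
#' model-projected contours use this container. Consecutive duplicate points
#' are removed; a closed contour needs at least 3 points and does not repeat
#' its first point.
#'
#' @param points n x 2 matrix of (u, v) detector coordinates (mm)
#' @param closed logical: is the contour a closed loop?
#' @export
contour2d <- function(points, closed = TRUE) {
  points <- rbind(points)
  if (ncol(points) != 2) stopf("contour points must be n x 2")
  if (nrow(points) > 1) {
    d <- rowSums(abs(diff(points)))
    keep <- c(TRUE, d > 0)
    points <- points[keep, , drop = FALSE]
    if (closed && nrow(points) > 1 &&
        all(points[1, ] == points[nrow(points), ]))
      points <- points[-nrow(points), , drop = FALSE]
  }
  if (closed && nrow(points) < 3) stopf("a closed contour needs >= 3 points")
  structure(points, closed = closed, class = c("contour2d", "matrix"))
}

#' @export
print.contour2d <- function(x, ...) {
  cat(sprintf("contour2d: %d points, %s, u [%.2f, %.2f] v [%.2f, %.2f] mm\n",
              nrow(x), if (isTRUE(attr(x, "closed"))) "closed" else "open",
              min(x[, 1]), max(x[, 1]), min(x[, 2]), max(x[, 2])))
  invisible(x)
}

# signed polygon area (shoelace), mm^2
contour_area <- function(points) {
  x <- points[, 1]; y <- points[, 2]
  n <- nrow(points)
  j <- c(2:n, 1)
  sum(x * y[j] - x[j] * y) / 2
}

contour_perimeter <- function(points, closed = TRUE) {
  p <- rbind(points, if (closed) points[1, , drop = FALSE])
  sum(sqrt(rowSums(diff(p)^2)))
}

#' Render the silhouette of a posed mesh
#'
#' A detector pixel is set iff the ray from the source through (a supersampled
#' neighbourhood of) the pixel centre intersects the posed mesh; with
#' `supersample > 1` the pixel is set when at least half its subsamples are
#' covered.
#'
#' @param mesh a [triangle_mesh()]
#' @param pose a [rigid_transform()] placing the mesh in the world frame
#' @param geometry an [imaging_geometry()]
#' @param supersample integer >= 1, subsamples per pixel edge
#' @param coverage if `TRUE` return fractional coverage in `[0, 1]` instead of
#'   the thresholded binary mask
#' @return matrix of `geometry$detector_size`; binary 0/1 (or coverage)
#' @export
render_silhouette <- function(mesh, pose, geometry, supersample = 2,
                              coverage = FALSE) {
  V <- transform_points(mesh$vertices, pose)
  z <- V[, 3]
  if (any(z <= 0) || any(z >= geometry$sdd))
    stopf("posed mesh must lie strictly between source and detector")
  P <- project_points(geometry, V)
  tl <- detector_topleft_mm(geometry)
  nr <- geometry$detector_size[1]
  nc <- geometry$detector_size[2]
  pitch <- geometry$pixel_pitch
  # field-of-view check
  px <- detector_mm_to_px(geometry, P)
  if (all(px[, 1] < 0.5) || all(px[, 1] > nr + 0.5) ||
      all(px[, 2] < 0.5) || all(px[, 2] > nc + 0.5)) {
    warnf("mesh projects outside the field of view; returning empty mask")
    return(matrix(0, nr, nc))
  }
  cov <- cpp_render_coverage(P, mesh$faces, tl[1], tl[2], pitch,
                             nr, nc, as.integer(supersample))
  if (coverage) cov else (cov >= 0.5) + 0
}

#' Outer contour of a binary silhouette mask
#'
#' Sub-pixel boundary at the 0.5 iso-level (marching squares with linear
#' interpolation between pixel centres), in detector mm. With several
#' disjoint foreground blobs the largest (by enclosed area) is returned as
#' the outer contour and the others are attached as `attr(, "others")`.
#'
#' @param mask binary matrix from [render_silhouette()] (or any 0/1 matrix of
#'   the detector size); fractional coverage matrices work too
#' @param geometry an [imaging_geometry()]
#' @return a closed [contour2d()]
#' @export
silhouette_to_contour <- function(mask, geometry) {
  if (sum(mask > 0.5) < 1) stopf("empty mask: no foreground pixel")
  tl <- detector_topleft_mm(geometry)
  loops <- cpp_marching_squares(mask, 0.5, tl[1], tl[2], geometry$pixel_pitch)
  loops <- Filter(function(l) isTRUE(attr(l, "closed")) && nrow(l) >= 3, loops)
  if (length(loops) == 0) stopf("no closed iso-contour found")
  areas <- vapply(loops, function(l) abs(contour_area(l)), numeric(1))
  ord <- order(areas, decreasing = TRUE)
  main <- contour2d(loops[[ord[1]]], closed = TRUE)
  if (length(ord) > 1)
    attr(main, "others") <- lapply(loops[ord[-1]], contour2d, closed = TRUE)
  main
}

#' Radiograph container
#' @param pixels grayscale intensity matrix in `[0, 1]`
#' @param geometry the [imaging_geometry()] the image was formed under
#' @param meta list of scene metadata (scene id, flexion angle, noise ...)
#' @export
radiograph <- function(pixels, geometry, meta = list()) {
  pixels <- as.matrix(pixels)
  if (!all(dim(pixels) == geometry$detector_size))
    stopf("pixel grid (%d x %d) must equal detector_size (%d x %d)",
          nrow(pixels), ncol(pixels),
          geometry$detector_size[1], geometry$detector_size[2])
  if (!all(is.finite(pixels))) stopf("pixel intensities must be finite")
  structure(list(pixels = pixels, geometry = geometry, meta = meta),
            class = "radiograph")
}

#' @export
print.radiograph <- function(x, ...) {
  cat(sprintf("radiograph: %d x %d px, intensities [%.3f, %.3f]\n",
              nrow(x$pixels), ncol(x$pixels), min(x$pixels), max(x$pixels)))
  if (!is.null(x$meta$scene_id)) cat("  scene:", x$meta$scene_id, "\n")
  invisible(x)
}

#' Render a synthetic radiograph of a posed scene
#'
#' Implant components are dark on a bright background (radiograph polarity).
#' Soft-tissue / PMMA-tube attenuation is emulated by a smooth low-frequency
#' multiplicative background field (not physical Beer-Lambert). The image is
#' Gaussian-blurred, then additive Gaussian noise is applied; both steps are
#' deterministic for a fixed `seed`.
#'
#' @param scene list of components, each `list(mesh =, pose =)`; an optional
#'   `radiopaque = FALSE` entry excludes a component (e.g. the polyethylene
#'   inlay, which is radiolucent)
#' @param geometry an [imaging_geometry()]
#' @param blur_sigma_px Gaussian blur sigma in pixels (0 disables)
#' @param noise_sd additive Gaussian noise SD on the `[0, 1]` intensity scale
#' @param background peak background intensity
#' @param attenuation intensity fraction removed where a component covers
#' @param supersample subsamples per pixel edge for the coverage masks
#' @param seed integer seed for noise and the background field
#' @param meta metadata list stored with the image
#' @return a [radiograph()]
#' @export
render_synthetic_radiograph <- function(scene, geometry, blur_sigma_px = 1,
                                        noise_sd = 0.02, background = 0.9,
                                        attenuation = 0.75, supersample = 2,
                                        seed = 1, meta = list()) {
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  nr <- geometry$detector_size[1]
  nc <- geometry$detector_size[2]
  cov <- matrix(0, nr, nc)
  for (comp in scene) {
    if (isFALSE(comp$radiopaque)) next
    ci <- render_silhouette(comp$mesh, comp$pose, geometry,
                            supersample = supersample, coverage = TRUE)
    cov <- pmax(cov, ci)
  }
  img <- with_seed(seed, {
    # low-frequency multiplicative background (soft-tissue / PMMA analogue)
    uc <- runif(1, 0.3, 0.7) * nc
    vc <- runif(1, 0.3, 0.7) * nr
    sc <- runif(1, 0.5, 0.9) * max(nr, nc)
    amp <- runif(1, 0.05, 0.12)
    rows <- matrix(seq_len(nr), nr, nc)
    cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    field <- 1 - amp * exp(-((rows - vc)^2 + (cols - uc)^2) / (2 * sc^2))
    img <- background * field * (1 - attenuation * cov)
    if (blur_sigma_px > 0) img <- gaussian_blur(img, blur_sigma_px)
    if (noise_sd > 0) img <- img + matrix(rnorm(nr * nc, 0, noise_sd), nr, nc)
    img
  })
  img <- pmin(pmax(img, 0), 1) # argument order keeps the matrix dims
  meta$blur_sigma_px <- blur_sigma_px
  meta$noise_sd <- noise_sd
  meta$seed <- seed
  radiograph(img, geometry, meta)
}

# Gaussian blur via EBImage (separable kernel internally)
gaussian_blur <- function(img, sigma) {
  out <- EBImage::imageData(EBImage::gblur(img, sigma = sigma,
                                           boundary = "replicate"))
  dim(out) <- dim(img)
  out
}

#' Write a radiograph as grayscale PNG plus a JSON sidecar
#'
#' The sidecar carries the virtual calibration (SDD, DPI, principal point)
#' and the scene metadata, mirroring how calibration data accompanies a
#' clinical image.
#'
#' @param rad a [radiograph()]
#' @param path output PNG path; the sidecar is written as `<path>.json`
#' @export
write_radiograph <- function(rad, path) {
  png::writePNG(rad$pixels, path, dpi = rad$geometry$dpi)
  side <- list(sdd_mm = rad$geometry$sdd,
               dpi = rad$geometry$dpi,
               detector_size_px = rad$geometry$detector_size,
               principal_point_px = rad$geometry$principal_point,
               scene = rad$meta)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a radiograph written by [write_radiograph()]
#' @param path PNG path with a `<path>.json` sidecar next to it
#' @export
read_radiograph <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  geom <- imaging_geometry(sdd = side$sdd_mm, dpi = side$dpi,
                           detector_size = side$detector_size_px,
                           principal_point = side$principal_point_px)
  px <- png::readPNG(path)
  if (length(dim(px)) == 3) px <- px[, , 1]
  radiograph(px, geom, meta = as.list(side$scene))
}
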