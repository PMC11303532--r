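# Minimum joint space width (mJSW), peripheral-rim correction, linear wear,
# and the simulated CMM ball-probe reference. The polyethylene inlay is
# radiolucent: mJSW is measured from the registered femoral component to the
# tibial baseplate reference plane, and the height of the peripheral rim the
# inlay rests on is subtracted.

#' Tibial reference frame
#'
#' Defines the baseplate reference plane and the medio-lateral axis used to
#' split condyles. Typically derived from the registered pose of the tibial
#' component via [tibial_frame_from_pose()]. The medial side is the negative
#' medio-lateral half (x' < 0), the lateral side positive — a labelling
#' convention, stated so worn-pool laterality is unambiguous.
#'
#' @param origin 3D point on the baseplate top plane at the baseplate midline
#' @param ml_axis unit vector of the medio-lateral axis
#' @param normal unit normal of the baseplate plane (pointing to the femur)
#' @export
tibial_frame <- function(origin = c(0, 0, 0), ml_axis = c(1, 0, 0),
                         normal = c(0, 1, 0)) {
  ml_axis <- ml_axis / sqrt(sum(ml_axis^2))
  normal <- normal / sqrt(sum(normal^2))
  ap_axis <- c(ml_axis[2] * normal[3] - ml_axis[3] * normal[2],
               ml_axis[3] * normal[1] - ml_axis[1] * normal[3],
               ml_axis[1] * normal[2] - ml_axis[2] * normal[1])
  structure(list(origin = origin, ml_axis = ml_axis, normal = normal,
                 ap_axis = ap_axis),
            class = "tibial_frame")
}

#' Tibial frame from a registered tray pose
#'
#' The tray model frame has its top plane at y = 0, the medio-lateral axis
#' along x and the origin at the baseplate midline; the registered pose maps
#' it into the world frame.
#' @param pose [rigid_transform()] of the tibial component
#' @export
tibial_frame_from_pose <- function(pose) {
  R <- rotation_matrix(pose)
  tibial_frame(origin = pose$translation, ml_axis = R[, 1], normal = R[, 2])
}

# world points -> (ml, height-above-plane, ap) coordinates of a tibial frame
frame_coordinates <- function(points, frame) {
  p <- sweep(rbind(points), 2, frame$origin)
  out <- cbind(as.vector(p %*% frame$ml_axis),
               as.vector(p %*% frame$normal),
               as.vector(p %*% frame$ap_axis))
  colnames(out) <- c("ml", "height", "ap")
  out
}

#' Split a mesh into medial and lateral condyle submeshes
#'
#' Faces are partitioned by the sign of their centroid's medio-lateral
#' coordinate in the tibial frame (medial x' < 0, lateral x' > 0).
#'
#' @param mesh a [triangle_mesh()] in world coordinates
#' @param tibial_frame a [tibial_frame()]
#' @return list with `medial` and `lateral` [triangle_mesh()] parts
#' @export
split_condyles <- function(mesh, tibial_frame) {
  V <- mesh$vertices
  Fc <- (V[mesh$faces[, 1], , drop = FALSE] +
         V[mesh$faces[, 2], , drop = FALSE] +
         V[mesh$faces[, 3], , drop = FALSE]) / 3
  ml <- frame_coordinates(Fc, tibial_frame)[, "ml"]
  med <- mesh$faces[ml < 0, , drop = FALSE]
  lat <- mesh$faces[ml >= 0, , drop = FALSE]
  if (nrow(med) == 0 || nrow(lat) == 0)
    stopf("all faces on one side of the split plane: tibial frame misconfigured?")
  list(medial = triangle_mesh(V, med), lateral = triangle_mesh(V, lat))
}

#' Minimum joint space width per condyle
#'
#' Minimum distance from the posed femoral surface to the tibial baseplate
#' reference plane, per condyle, minus the peripheral rim height the inlay
#' rests on. Distance to a plane is minimized at a mesh vertex, so the
#' closest-point query reduces to a vertex minimum. A femur below the
#' reference plane yields a negative raw distance and a penetration flag.
#'
#' @param femur_mesh femoral [triangle_mesh()] (model frame)
#' @param femur_pose registered [rigid_transform()] of the femur
#' @param tibial_frame [tibial_frame()] from the tibial-component registration
#' @param rim_height height of the peripheral rim (mm, >= 0)
#' @param scene_id,flexion_angle optional metadata carried into the result
#' @return object of class `condyle_measurement`: `mjsw_medial`,
#'   `mjsw_lateral` (mm, rim-corrected), `rim_height`, per-condyle 3D contact
#'   points, and a `penetration` flag
#' @export
measure_mjsw <- function(femur_mesh, femur_pose, tibial_frame, rim_height = 0,
                         scene_id = NA_character_, flexion_angle = NA_real_) {
  if (rim_height < 0) stopf("rim_height must be >= 0")
  W <- transform_points(femur_mesh$vertices, femur_pose)
  fc <- frame_coordinates(W, tibial_frame)
  med <- fc[, "ml"] < 0
  if (!any(med) || all(med))
    stopf("femur entirely on one side of the split plane: tibial frame misconfigured?")
  i_med <- which(med)[which.min(fc[med, "height"])]
  i_lat <- which(!med)[which.min(fc[!med, "height"])]
  raw <- c(medial = unname(fc[i_med, "height"]),
           lateral = unname(fc[i_lat, "height"]))
  structure(list(mjsw_medial = unname(raw["medial"]) - rim_height,
                 mjsw_lateral = unname(raw["lateral"]) - rim_height,
                 raw_distance = raw,
                 rim_height = rim_height,
                 contact_medial = W[i_med, ],
                 contact_lateral = W[i_lat, ],
                 penetration = any(raw < 0),
                 scene_id = scene_id,
                 flexion_angle = flexion_angle),
            class = "condyle_measurement")
}

#' @export
print.condyle_measurement <- function(x, ...) {
  cat(sprintf("condyle_measurement: mJSW medial %.3f mm, lateral %.3f mm (rim %.2f mm subtracted)%s\n",
              x$mjsw_medial, x$mjsw_lateral, x$rim_height,
              if (x$penetration) " [PENETRATION]" else ""))
  invisible(x)
}

#' Linear wear from two mJSW measurements
#'
#' `mjsw_new - mjsw_worn`, exactly. Negative output is allowed and flags
#' measurement noise exceeding the wear.
#' @param mjsw_new,mjsw_worn mJSW (mm) of the same condyle in comparable poses
#' @export
linear_wear <- function(mjsw_new, mjsw_worn) mjsw_new - mjsw_worn

#' Simulated CMM ball-probe minimum thickness
#'
#' Emulates a tactile coordinate-measurement machine: a ball probe of the
#' given diameter is lowered onto the articular surface over a measurement
#' patch centred at the condyle's lowest articular point, and the minimum
#' (probe contact height minus inlay bottom plane) over the patch is
#' returned. Probe contact at horizontal position q is
#' `max over surface samples p with d = |p - q| <= r of (h(p) + sqrt(r^2 - d^2)) - r`.
#' By convexity of the ball the reading is always >= the true minimum
#' material thickness, with equality where the surface curvature radius is
#' >= the probe radius — the contact-area caveat of tactile reference
#' measurements. Thickness is vertical (along the bottom-plane normal).
#'
#' @param inlay_mesh inlay [triangle_mesh()] in its model frame (flat bottom
#'   on y = 0, medio-lateral axis x)
#' @param condyle `"medial"` (x < 0) or `"lateral"` (x > 0)
#' @param probe_diameter ball diameter (mm, > 0; default 3)
#' @param patch patch extent `(ml, ap)` in mm (default 2 x 10)
#' @param patch_center optional `(x, z)` centre; defaults to the condyle's
#'   lowest articular point
#' @param grid_step sampling step for surface heights and probe positions (mm)
#' @return minimum thickness (mm)
#' @export
cmm_probe_thickness <- function(inlay_mesh, condyle = c("medial", "lateral"),
                                probe_diameter = 3, patch = c(2, 10),
                                patch_center = NULL, grid_step = 0.2) {
  condyle <- match.arg(condyle)
  if (probe_diameter <= 0) stopf("probe_diameter must be > 0")
  r <- probe_diameter / 2
  V <- inlay_mesh$vertices
  bottom <- min(V[, 2])
  sgn <- if (condyle == "medial") -1 else 1
  if (is.null(patch_center)) {
    # locate the condyle's lowest articular point: coarse height scan of the
    # top surface over the condyle half, then take the minimum
    xs <- seq(min(V[, 1]), max(V[, 1]), by = max(grid_step * 4, 0.5))
    xs <- xs[sign(xs) == sgn]
    zs <- seq(min(V[, 3]), max(V[, 3]), by = max(grid_step * 4, 0.5))
    g <- as.matrix(expand.grid(x = xs, z = zs))
    h <- raycast_top_heights(inlay_mesh, g)
    if (all(is.na(h))) stopf("no articular surface found on the %s side", condyle)
    # restrict to dished region (below the nominal top plateau)
    top_plateau <- max(h, na.rm = TRUE)
    dish <- which(!is.na(h) & h < top_plateau - 1e-6)
    if (length(dish) == 0) dish <- which(!is.na(h))
    # among (near-)minimal heights, prefer the sample closest to the centre
    # of the condyle half, so a flat surface probes its middle, not a corner
    hmin <- min(h[dish])
    cand <- dish[h[dish] <= hmin + 1e-9]
    ctr <- colMeans(g[dish, , drop = FALSE])
    k <- cand[which.min((g[cand, 1] - ctr[1])^2 + (g[cand, 2] - ctr[2])^2)]
    patch_center <- g[k, ]
  }
  half <- patch / 2
  # surface samples extend a probe radius beyond the patch, on a grid aligned
  # with the probe positions so every probe centre coincides with a sample
  # (otherwise a flat surface would read low by r - sqrt(r^2 - d^2))
  ext <- function(halfext) ceiling((halfext + r) / grid_step) * grid_step
  xs <- patch_center[1] + seq(-ext(half[1]), ext(half[1]), by = grid_step)
  zs <- patch_center[2] + seq(-ext(half[2]), ext(half[2]), by = grid_step)
  g <- as.matrix(expand.grid(x = xs, z = zs))
  h <- raycast_top_heights(inlay_mesh, g)
  if (mean(is.na(h)) > 0.5)
    stopf("measurement patch lies off the articular surface")
  px <- seq(patch_center[1] - half[1], patch_center[1] + half[1], by = grid_step)
  pz <- seq(patch_center[2] - half[2], patch_center[2] + half[2], by = grid_step)
  best <- Inf
  ok <- !is.na(h)
  gx <- g[ok, 1]; gz <- g[ok, 2]; gh <- h[ok]
  for (qx in px) {
    dx2 <- (gx - qx)^2
    for (qz in pz) {
      d2 <- dx2 + (gz - qz)^2
      within <- d2 <= r^2
      if (!any(within)) next
      contact <- max(gh[within] + sqrt(r^2 - d2[within])) - r
      thickness <- contact - bottom
      if (thickness < best) best <- thickness
    }
  }
  if (!is.finite(best)) stopf("probe never contacted the surface over the patch")
  best
}

# top-surface heights by casting vertical rays downward from above the mesh
raycast_top_heights <- function(mesh, xz) {
  ytop <- max(mesh$vertices[, 2]) + 5
  O <- cbind(xz[, 1], ytop, xz[, 2])
  t <- cpp_raycast(O, c(0, -1, 0), mesh$vertices, mesh$faces)
  ytop - t
}
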