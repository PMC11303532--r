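# Synthetic phantom study: parametric inlay / femoral / tibial-tray meshes,
# imposed wear, contact-seated scenes at the study's flexion angles, and
# rendered radiographs with ground truth. The proprietary implant geometry is
# replaced by a documented parametric analogue (congruent sphere-on-dish);
# the measurement method depends only on matched surface models, not on the
# brand geometry.

# tensor grid: coarse base step, refined step inside given intervals
refine_grid <- function(lo, hi, base_step, fine_step, fine_intervals = NULL) {
  xs <- seq(lo, hi, by = base_step)
  if (!is.null(fine_intervals)) {
    for (iv in fine_intervals) {
      a <- max(lo, iv[1]); b <- min(hi, iv[2])
      if (b > a) xs <- c(xs, seq(a, b, by = fine_step))
    }
  }
  sort(unique(round(c(xs, hi), 9)))
}

# watertight solid from a top heightfield H[i, j] over tensor grid (xs, zs)
# with a flat bottom at y = y_bottom
heightfield_solid <- function(xs, zs, H, y_bottom, articular = NULL) {
  nx <- length(xs); nz <- length(zs)
  top_id <- function(i, j) (j - 1) * nx + i
  bot_id <- function(i, j) nx * nz + (j - 1) * nx + i
  Vtop <- cbind(rep(xs, nz), as.vector(H), rep(zs, each = nx))
  Vbot <- cbind(rep(xs, nz), y_bottom, rep(zs, each = nx))
  V <- rbind(Vtop, Vbot)
  faces <- vector("list", 6)
  i <- rep(seq_len(nx - 1), nz - 1)
  j <- rep(seq_len(nz - 1), each = nx - 1)
  A <- top_id(i, j); B <- top_id(i + 1, j); C <- top_id(i + 1, j + 1); D <- top_id(i, j + 1)
  faces[[1]] <- rbind(cbind(A, C, B), cbind(A, D, C))          # top, +y out
  a <- bot_id(i, j); b <- bot_id(i + 1, j); c <- bot_id(i + 1, j + 1); d <- bot_id(i, j + 1)
  faces[[2]] <- rbind(cbind(a, b, c), cbind(a, c, d))          # bottom, -y out
  ii <- seq_len(nx - 1)
  faces[[3]] <- rbind(cbind(top_id(ii, 1), top_id(ii + 1, 1), bot_id(ii + 1, 1)),
                      cbind(top_id(ii, 1), bot_id(ii + 1, 1), bot_id(ii, 1)))   # z = min wall
  faces[[4]] <- rbind(cbind(top_id(ii, nz), bot_id(ii + 1, nz), top_id(ii + 1, nz)),
                      cbind(top_id(ii, nz), bot_id(ii, nz), bot_id(ii + 1, nz))) # z = max wall
  jj <- seq_len(nz - 1)
  faces[[5]] <- rbind(cbind(top_id(1, jj), bot_id(1, jj + 1), top_id(1, jj + 1)),
                      cbind(top_id(1, jj), bot_id(1, jj), bot_id(1, jj + 1)))    # x = min wall
  faces[[6]] <- rbind(cbind(top_id(nx, jj), top_id(nx, jj + 1), bot_id(nx, jj + 1)),
                      cbind(top_id(nx, jj), bot_id(nx, jj + 1), bot_id(nx, jj)))  # x = max wall
  labels <- c(rep("articular", nx * nz), rep("bottom", nx * nz))
  triangle_mesh(V, do.call(rbind, faces), labels = labels)
}

#' Parametric phantom inlay mesh
#'
#' A flat-bottomed polyethylene inlay: a box of the given footprint and
#' nominal thickness whose top surface carries two spherical condylar dishes
#' of the femoral radius, so the femoral component articulates congruently.
#' Model frame: bottom on y = 0, centred in x (medio-lateral) and z
#' (antero-posterior); the medial dish is at negative x.
#'
#' @param thickness nominal inlay thickness (mm)
#' @param footprint `(ml, ap)` extents (mm), default 76 x 50
#' @param femoral_radius radius of the condylar spheres (mm)
#' @param dish_depth depth of each dish below the top plateau (mm,
#'   < thickness)
#' @param condyle_spacing distance between dish centres (mm)
#' @param fine_step grid step inside the dishes (mm)
#' @param base_step grid step elsewhere (mm)
#' @return a watertight [triangle_mesh()]; dish centres and parameters are
#'   attached as `attr(, "params")`
#' @export
make_inlay_mesh <- function(thickness, footprint = c(76, 50),
                            femoral_radius = 20, dish_depth = 2,
                            condyle_spacing = 46, fine_step = 0.8,
                            base_step = 4) {
  if (dish_depth >= thickness) stopf("dish_depth must be < thickness")
  if (dish_depth < 0) stopf("dish_depth must be >= 0")
  R <- femoral_radius
  rho_max <- if (dish_depth > 0) sqrt(R^2 - (R - dish_depth)^2) else 0
  if (2 * rho_max > condyle_spacing) stopf("dishes overlap: infeasible parameters")
  if (condyle_spacing / 2 + rho_max > footprint[1] / 2 ||
      rho_max > footprint[2] / 2)
    stopf("dishes fall outside the footprint: infeasible parameters")
  cx <- condyle_spacing / 2
  pad <- min(rho_max + 1, footprint[2] / 2)
  xs <- refine_grid(-footprint[1] / 2, footprint[1] / 2, base_step, fine_step,
                    list(c(-cx - pad, -cx + pad), c(cx - pad, cx + pad)))
  zs <- refine_grid(-footprint[2] / 2, footprint[2] / 2, base_step, fine_step,
                    list(c(-pad, pad)))
  yc <- thickness - dish_depth + R # dish sphere centre height
  H <- matrix(thickness, length(xs), length(zs))
  if (dish_depth > 0) {
    for (s in c(-1, 1)) {
      dx <- outer(xs - s * cx, rep(1, length(zs)))
      dz <- outer(rep(1, length(xs)), zs)
      rho2 <- dx^2 + dz^2
      inside <- rho2 < R^2
      hs <- H
      hs[inside] <- yc - sqrt(R^2 - rho2[inside])
      H <- pmin(H, hs)
    }
  }
  mesh <- heightfield_solid(xs, zs, H, 0)
  attr(mesh, "params") <- list(thickness = thickness, footprint = footprint,
                               femoral_radius = R, dish_depth = dish_depth,
                               condyle_spacing = condyle_spacing,
                               dish_centers = rbind(medial = c(-cx, 0),
                                                    lateral = c(cx, 0)))
  mesh
}

#' Parametric femoral component mesh
#'
#' Two convex spherical condyle segments of the given radius, centred at
#' +/- `condyle_spacing / 2` on the medio-lateral (x) axis and joined by a
#' box-shaped intercondylar bar. Model frame: the condylar axis is the x
#' axis through the origin; y points superiorly; flexion is rotation about
#' x, which leaves the articulating spheres invariant (the congruent-contact
#' property of the phantom). Each segment spans the sagittal arc
#' `sag_range` (degrees from straight down, positive posterior) and
#' `+/- ml_half_angle` medio-laterally, closed by a fan to the sphere centre.
#'
#' @param radius condylar sphere radius (mm)
#' @param condyle_spacing distance between sphere centres (mm)
#' @param sag_range sagittal arc (degrees), default -70 to 130
#' @param ml_half_angle medio-lateral half-arc (degrees)
#' @param step angular tessellation step (degrees); the grid contains the
#'   study's flexion angles so the seated contact point is an exact vertex
#' @export
make_femur_mesh <- function(radius = 20, condyle_spacing = 46,
                            sag_range = c(-70, 130), ml_half_angle = 40,
                            step = 5) {
  if (radius <= 0 || condyle_spacing <= 0) stopf("radius and spacing must be > 0")
  alphas <- seq(sag_range[1], sag_range[2], by = step) * pi / 180
  betas <- seq(-ml_half_angle, ml_half_angle, by = step) * pi / 180
  na <- length(alphas); nb <- length(betas)
  Vs <- list(); Fs <- list(); voff <- 0
  for (s in c(-1, 1)) {
    Cx <- s * condyle_spacing / 2
    # patch vertices: rows alpha, cols beta
    d <- cbind(rep(sin(betas), each = na),
               -cos(rep(betas, each = na)) * cos(rep(alphas, nb)),
               cos(rep(betas, each = na)) * sin(rep(alphas, nb)))
    Vp <- cbind(Cx + radius * d[, 1], radius * d[, 2], radius * d[, 3])
    id <- function(i, j) voff + (j - 1) * na + i
    i <- rep(seq_len(na - 1), nb - 1)
    j <- rep(seq_len(nb - 1), each = na - 1)
    Fp <- rbind(cbind(id(i, j), id(i + 1, j), id(i + 1, j + 1)),
                cbind(id(i, j), id(i + 1, j + 1), id(i, j + 1)))
    # close the patch with a fan to the sphere centre
    ctr <- voff + na * nb + 1
    ring <- c(id(seq_len(na), 1),                        # beta min edge
              id(na, seq(2, nb)),                        # alpha max edge
              id(seq(na - 1, 1), nb),                    # beta max edge (reverse)
              id(1, seq(nb - 1, 2)))                     # alpha min edge (reverse)
    nr <- length(ring)
    Ff <- cbind(ring, c(ring[-1], ring[1]), ctr)
    Vs[[length(Vs) + 1]] <- rbind(Vp, c(Cx, 0, 0))
    Fs[[length(Fs) + 1]] <- rbind(Fp, Ff)
    voff <- voff + na * nb + 1
  }
  # intercondylar bar
  hw <- condyle_spacing / 2
  bx <- c(-hw, hw); by <- c(-radius * 0.3, radius * 0.4); bz <- c(-radius * 0.4, radius * 0.4)
  bv <- as.matrix(expand.grid(bx, by, bz))
  bf <- rbind(c(1, 3, 4), c(1, 4, 2), c(5, 8, 7), c(5, 6, 8),
              c(1, 2, 6), c(1, 6, 5), c(3, 7, 8), c(3, 8, 4),
              c(1, 5, 7), c(1, 7, 3), c(2, 4, 8), c(2, 8, 6)) + voff
  Vs[[length(Vs) + 1]] <- bv
  Fs[[length(Fs) + 1]] <- bf
  mesh <- triangle_mesh(do.call(rbind, Vs), do.call(rbind, Fs))
  attr(mesh, "params") <- list(radius = radius, condyle_spacing = condyle_spacing,
                               sag_range = sag_range, ml_half_angle = ml_half_angle,
                               step = step)
  mesh
}

#' Parametric tibial tray mesh
#'
#' A plate with a raised peripheral rim on which the flat-bottomed phantom
#' inlay rests. Model frame: top plane of the plate at y = 0 (the baseplate
#' reference plane), centred in x and z; the rim top is at y = `rim_height`.
#'
#' @param footprint `(ml, ap)` plate extents (mm)
#' @param plate_thickness plate thickness below the reference plane (mm)
#' @param rim_height peripheral rim height above the reference plane (mm)
#' @param rim_width rim band width (mm)
#' @param keel_depth length of the fixation keel below the plate (mm)
#' @param keel_size keel `(ml, ap)` cross-section (mm)
#' @param peg_depth length of the two fixation pegs below the plate (mm).
#'   The pegs sit lateral of the keel and anterior of the plate centre, so
#'   their silhouette moves visibly when the plate tilts about the
#'   medio-lateral axis: they disambiguate tilt from vertical shift in a
#'   single-view registration, as the fixation features of a clinical tray do
#' @param peg_offset `(ml, ap)` placement of the pegs at `(+/- ml, ap)` (mm)
#' @param peg_size peg cross-section (mm)
#' @export
make_tibial_tray_mesh <- function(footprint = c(80, 54), plate_thickness = 4,
                                  rim_height = 2, rim_width = 3,
                                  keel_depth = 25, keel_size = c(14, 10),
                                  peg_depth = 14, peg_offset = c(16, 12),
                                  peg_size = 7) {
  hx <- footprint[1] / 2; hz <- footprint[2] / 2
  xs <- sort(unique(c(seq(-hx, hx, by = 4), -hx + rim_width, hx - rim_width, hx)))
  zs <- sort(unique(c(seq(-hz, hz, by = 4), -hz + rim_width, hz - rim_width, hz)))
  H <- matrix(0, length(xs), length(zs))
  rim <- outer(abs(xs) > hx - rim_width - 1e-9, rep(TRUE, length(zs))) |
         outer(rep(TRUE, length(xs)), abs(zs) > hz - rim_width - 1e-9)
  H[rim] <- rim_height
  mesh <- heightfield_solid(xs, zs, H, -plate_thickness)
  add_box <- function(mesh, centre_xz, size_xz, depth) {
    bx <- size_xz[1] / 2; bz <- size_xz[2] / 2
    bv <- as.matrix(expand.grid(centre_xz[1] + c(-bx, bx),
                                c(-plate_thickness - depth,
                                  -plate_thickness + 0.5),
                                centre_xz[2] + c(-bz, bz)))
    bf <- rbind(c(1, 3, 4), c(1, 4, 2), c(5, 8, 7), c(5, 6, 8),
                c(1, 2, 6), c(1, 6, 5), c(3, 7, 8), c(3, 8, 4),
                c(1, 5, 7), c(1, 7, 3), c(2, 4, 8), c(2, 8, 6)) +
      nrow(mesh$vertices)
    triangle_mesh(rbind(mesh$vertices, bv), rbind(mesh$faces, bf),
                  labels = c(mesh$labels, rep("fixation", 8)))
  }
  if (keel_depth > 0)
    mesh <- add_box(mesh, c(0, 0), keel_size, keel_depth)
  if (peg_depth > 0) {
    mesh <- add_box(mesh, c(-peg_offset[1], peg_offset[2]),
                    c(peg_size, peg_size), peg_depth)
    mesh <- add_box(mesh, c(peg_offset[1], peg_offset[2]),
                    c(peg_size, peg_size), peg_depth)
  }
  attr(mesh, "params") <- list(footprint = footprint,
                               plate_thickness = plate_thickness,
                               rim_height = rim_height, rim_width = rim_width,
                               keel_depth = keel_depth, keel_size = keel_size,
                               peg_depth = peg_depth, peg_offset = peg_offset,
                               peg_size = peg_size)
  mesh
}

#' Impose wear on an inlay as geometric material removal
#'
#' Lowers articular vertices inside a wear pool centred on a condyle dish.
#' `uniform_patch` lowers every pool vertex by `depth` (so the probe-model
#' minimum thickness decreases by exactly `depth`); `gaussian_pool` applies
#' a Gaussian depth field with peak `depth` and scale `pool_sigma`. The
#' default pool covers the whole dish — wider than the probe ball — so the
#' reference measurement and the seated contact both see the full depth.
#'
#' @param inlay_mesh a mesh from [make_inlay_mesh()]
#' @param condyle `"medial"` or `"lateral"`
#' @param depth material removal depth (mm, >= 0)
#' @param pool_shape `"uniform_patch"` or `"gaussian_pool"`
#' @param pool_radius pool radius (mm); default covers the dish
#' @param pool_sigma Gaussian pool scale (mm)
#' @return the worn mesh; imposed wear is recorded in `attr(, "wear")`
#' @export
apply_wear <- function(inlay_mesh, condyle = c("medial", "lateral"), depth,
                       pool_shape = c("uniform_patch", "gaussian_pool"),
                       pool_radius = NULL, pool_sigma = 3) {
  condyle <- match.arg(condyle)
  pool_shape <- match.arg(pool_shape)
  if (depth < 0) stopf("depth must be >= 0")
  if (depth == 0) return(inlay_mesh)
  par <- attr(inlay_mesh, "params")
  if (is.null(par)) stopf("inlay_mesh must come from make_inlay_mesh()")
  ctr <- par$dish_centers[condyle, ]
  R <- par$femoral_radius
  rho_max <- sqrt(R^2 - (R - par$dish_depth)^2)
  if (is.null(pool_radius)) pool_radius <- rho_max + 0.5
  V <- inlay_mesh$vertices
  art <- inlay_mesh$labels == "articular"
  rho <- sqrt((V[, 1] - ctr[1])^2 + (V[, 3] - ctr[2])^2)
  if (pool_shape == "uniform_patch") {
    sel <- art & rho <= pool_radius
    removal <- rep(depth, sum(sel))
  } else {
    sel <- art & rho <= 3 * pool_sigma
    removal <- depth * exp(-rho[sel]^2 / (2 * pool_sigma^2))
  }
  if (!any(sel)) stopf("wear pool selects no articular vertices")
  local_thick <- min(V[sel, 2])
  if (depth >= local_thick)
    stopf("wear depth %.3f mm >= local thickness %.3f mm", depth, local_thick)
  V[sel, 2] <- V[sel, 2] - removal
  out <- inlay_mesh
  out$vertices <- V
  wr <- attr(inlay_mesh, "wear") %||% list()
  wr[[condyle]] <- list(depth = depth, shape = pool_shape,
                        pool_radius = pool_radius, pool_sigma = pool_sigma)
  attr(out, "wear") <- wr
  out
}

#' Scenario configuration for the synthetic phantom study
#'
#' The defaults mirror the imaging protocol this package emulates: three
#' inlay thicknesses 10/14/16 mm with a 76 x 50 mm footprint, anteroposterior
#' views at flexion 0/30/60 degrees, SDD 1150 mm, 96 DPI, and three worn
#' inlays alongside three unworn ones (18 radiographs). Imposed per-condyle
#' wear depths span 0.05-0.5 mm. Values the physical study does not print
#' (femoral radius, dish depth, rim height, object-plane distance, noise
#' level) are plausible configuration choices recorded here, not asserted as
#' the study's.
#'
#' @param thicknesses inlay thicknesses (mm)
#' @param footprint inlay footprint (ml, ap) in mm
#' @param femoral_radius condylar sphere radius (mm)
#' @param dish_depth dish depth (mm)
#' @param condyle_spacing dish/condyle centre spacing (mm)
#' @param flexion_angles imaging flexion angles (degrees, in [0, 90])
#' @param wear_depths matrix (inlay x condyle) of imposed wear depths (mm);
#'   rownames follow the inlay order, columns medial/lateral
#' @param sdd source-to-detector distance (mm)
#' @param dpi detector resolution
#' @param detector_size detector (rows, cols) in pixels
#' @param object_z beam-axis distance of the joint centre (mm)
#' @param y_base world height of the baseplate reference plane (mm)
#' @param rim_height peripheral rim height (mm)
#' @param blur_sigma_px radiograph blur (px)
#' @param noise_sd radiograph additive noise SD
#' @param supersample rendering supersampling factor
#' @param seed master seed; every per-scene seed derives from it
#' @export
scenario_config <- function(thicknesses = c(10, 14, 16),
                            footprint = c(76, 50),
                            femoral_radius = 20,
                            dish_depth = 2,
                            condyle_spacing = 46,
                            flexion_angles = c(0, 30, 60),
                            wear_depths = rbind(c(0.15, 0.05),
                                                c(0.30, 0.10),
                                                c(0.50, 0.20)),
                            sdd = 1150, dpi = 96,
                            detector_size = c(768, 768),
                            object_z = sdd / 2,
                            y_base = -15,
                            rim_height = 2,
                            blur_sigma_px = 1,
                            noise_sd = 0.02,
                            supersample = 2,
                            seed = 20240806) {
  if (any(flexion_angles < 0 | flexion_angles > 90))
    stopf("flexion angles must lie in [0, 90] degrees")
  if (any(thicknesses <= dish_depth))
    stopf("thicknesses must exceed the dish depth")
  wear_depths <- rbind(wear_depths)
  if (nrow(wear_depths) != length(thicknesses) || ncol(wear_depths) != 2)
    stopf("wear_depths must be a (n_inlay x 2) matrix (medial, lateral)")
  colnames(wear_depths) <- c("medial", "lateral")
  geometry <- imaging_geometry(sdd = sdd, dpi = dpi, detector_size = detector_size)
  structure(list(thicknesses = thicknesses, footprint = footprint,
                 femoral_radius = femoral_radius, dish_depth = dish_depth,
                 condyle_spacing = condyle_spacing,
                 flexion_angles = flexion_angles, wear_depths = wear_depths,
                 geometry = geometry, object_z = object_z, y_base = y_base,
                 rim_height = rim_height, blur_sigma_px = blur_sigma_px,
                 noise_sd = noise_sd, supersample = supersample, seed = seed),
            class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("scenario_config: %d inlays (%s mm) x {new, worn} x %d angles (%s deg) = %d radiographs\n",
              length(x$thicknesses), paste(x$thicknesses, collapse = "/"),
              length(x$flexion_angles), paste(x$flexion_angles, collapse = "/"),
              2 * length(x$thicknesses) * length(x$flexion_angles)))
  cat(sprintf("  SDD %.0f mm, %.4g DPI, object plane z = %.0f mm, seed %d\n",
              x$geometry$sdd, x$geometry$dpi, x$object_z, x$seed))
  invisible(x)
}

#' Seat the femur on an inlay and build one posed scene
#'
#' The tibia (tray + inlay) is fixed; the femur is rotated by the flexion
#' angle about its condylar axis and translated down by a contact solver
#' until its minimum signed distance to the inlay lies in (0, 0.005] mm with
#' no penetration. Optionally a per-condyle vertical offset emulates condyle
#' lift-off (the silicone-band loading fault discussed for the physical
#' phantom).
#'
#' @param config a [scenario_config()]
#' @param inlay_mesh the (possibly worn) inlay mesh
#' @param femur_mesh the femoral mesh
#' @param tray_mesh the tibial tray mesh
#' @param angle flexion angle (degrees; must be one of the config's angles)
#' @param liftoff optional extra vertical offset of the femur (mm)
#' @return list with component poses, scene list for rendering, and the
#'   ground-truth mJSW per condyle
#' @export
build_scene <- function(config, inlay_mesh, femur_mesh, tray_mesh, angle,
                        liftoff = 0) {
  if (!angle %in% config$flexion_angles)
    stopf("angle %.1f not in the configured flexion angles", angle)
  zc <- config$object_z
  tray_pose <- rigid_transform(0, config$y_base, zc)
  inlay_pose <- rigid_transform(0, config$y_base + config$rim_height, zc)
  inlay_world <- transform_mesh(inlay_mesh, inlay_pose)
  # rotate femur by flexion, then seat it: the femur translates only
  # vertically, so the vertical clearance against the inlay's articular
  # height field is linear in y and the contact height has a closed form
  par <- attr(inlay_mesh, "params")
  Rf <- par$femoral_radius
  target <- 0.003
  # Seat with a vertical drop plus a small varus/valgus tilt about the
  # antero-posterior axis so BOTH condyles reach the contact gap even under
  # differential medial/lateral wear (the physical phantom's silicone bands
  # press both condyles into contact). For a vertical translation the
  # clearance against the articular height field is linear in y, and the
  # tilt converges in a few fixed-point iterations.
  clearances <- function(rx, ry = 0, rz = 0) {
    Vrot <- transform_points(femur_mesh$vertices, rigid_transform(rx = rx, rz = rz))
    low <- Vrot[, 2] < -0.5 * Rf # only the lower condylar band can contact
    Vlow <- Vrot[low, , drop = FALSE]
    h <- raycast_top_heights(inlay_world, cbind(Vlow[, 1], Vlow[, 3] + zc))
    ok <- is.finite(h)
    list(clear = Vlow[ok, 2] - h[ok], x = Vlow[ok, 1])
  }
  rz <- 0
  y_seat <- NA_real_
  for (it in 1:12) {
    cl <- clearances(angle, rz = rz)
    if (length(cl$clear) == 0)
      stopf("seating solver failed: no femur vertex above the inlay surface")
    c_med <- min(cl$clear[cl$x < 0])
    c_lat <- min(cl$clear[cl$x >= 0])
    y_seat <- target - max(c_med, c_lat) # drop until the higher side touches
    dc <- c_lat - c_med # > 0: lateral hangs higher -> tilt lateral side down
    if (abs(dc) < 1e-9) break
    # Rz by -theta lowers the +x (lateral) side
    rz <- rz - atan2(dc, par$condyle_spacing) * 180 / pi
  }
  femur_pose <- rigid_transform(0, y_seat + liftoff, zc, rx = angle, rz = rz)
  # verify the seated contact with the mesh-distance machinery
  seated <- transform_mesh(femur_mesh, femur_pose)
  gap <- mesh_min_distance(seated, inlay_world)$distance
  if (liftoff == 0 && (gap > 0.005 || gap < target - 0.005))
    stopf("seating solver failed to converge: residual gap %.4f mm", gap)
  frame <- tibial_frame_from_pose(tray_pose)
  truth_m <- measure_mjsw(femur_mesh, femur_pose, frame, config$rim_height)
  scene <- list(
    list(name = "femur", mesh = femur_mesh, pose = femur_pose),
    list(name = "tray", mesh = tray_mesh, pose = tray_pose),
    list(name = "inlay", mesh = inlay_mesh, pose = inlay_pose, radiopaque = FALSE)
  )
  list(scene = scene, femur_pose = femur_pose, tray_pose = tray_pose,
       inlay_pose = inlay_pose, tibial_frame = frame,
       true_mjsw = c(medial = truth_m$mjsw_medial, lateral = truth_m$mjsw_lateral),
       seating_gap = target, angle = angle)
}

#' Generate the synthetic phantom dataset
#'
#' Builds the full study: for every inlay thickness, a new and a worn inlay,
#' each imaged at every flexion angle — 18 radiographs under the default
#' configuration — together with per-scene ground truth (true poses, true
#' mJSW, simulated-CMM reference thicknesses, imposed wear) and a study-table
#' skeleton. Fully reproducible: every random draw derives from the master
#' seed.
#'
#' @param config a [scenario_config()]
#' @param out_dir optional output directory; meshes (STL), images (PNG+JSON
#'   sidecar), `truth.csv` and `study_table.csv` are written there
#' @param force overwrite an existing non-empty `out_dir`
#' @param verbose print progress
#' @return a `phantom_dataset` list: `scenes` (each with the radiograph,
#'   meshes, true poses, hints and truth), `truth` data frame (one row per
#'   scene x condyle), `config`
#' @export
generate_dataset <- function(config = scenario_config(), out_dir = NULL,
                             force = FALSE, verbose = FALSE) {
  if (!is.null(out_dir)) {
    if (dir.exists(out_dir) && length(list.files(out_dir)) > 0 && !force)
      stopf("output directory %s exists and is not empty (use force = TRUE)", out_dir)
    dir.create(file.path(out_dir, "meshes"), recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(out_dir, "images"), recursive = TRUE, showWarnings = FALSE)
  }
  femur <- make_femur_mesh(radius = config$femoral_radius,
                           condyle_spacing = config$condyle_spacing)
  tray <- make_tibial_tray_mesh(rim_height = config$rim_height)
  n_inlay <- length(config$thicknesses)
  inlays <- list()
  cmm <- list()
  for (i in seq_len(n_inlay)) {
    id <- paste0("inlay", i)
    new_mesh <- make_inlay_mesh(config$thicknesses[i],
                                footprint = config$footprint,
                                femoral_radius = config$femoral_radius,
                                dish_depth = config$dish_depth,
                                condyle_spacing = config$condyle_spacing)
    worn_mesh <- apply_wear(new_mesh, "medial", config$wear_depths[i, "medial"])
    worn_mesh <- apply_wear(worn_mesh, "lateral", config$wear_depths[i, "lateral"])
    inlays[[id]] <- list(new = new_mesh, worn = worn_mesh)
    for (st in c("new", "worn")) {
      for (cd in c("medial", "lateral")) {
        cmm[[paste(id, st, cd, sep = ".")]] <-
          cmm_probe_thickness(inlays[[id]][[st]], cd)
      }
    }
  }
  scenes <- list()
  truth_rows <- list()
  k <- 0L
  for (i in seq_len(n_inlay)) {
    id <- paste0("inlay", i)
    for (st in c("new", "worn")) {
      for (angle in config$flexion_angles) {
        k <- k + 1L
        scene_id <- sprintf("%s_%s_f%02d", id, st, angle)
        if (verbose) message("building scene ", scene_id)
        sc <- build_scene(config, inlays[[id]][[st]], femur, tray, angle)
        seed_k <- derive_seed(config$seed, k)
        # contour-selection hints: projected component bounding boxes with a
        # small margin (stored in the sidecar, replacing the interactive step)
        hint <- function(mesh, pose, margin = 4) {
          W <- transform_points(mesh$vertices, pose)
          P <- project_points(config$geometry, W)
          c(min(P[, 1]) - margin, max(P[, 1]) + margin,
            min(P[, 2]) - margin, max(P[, 2]) + margin)
        }
        meta <- list(scene_id = scene_id, inlay_id = id, state = st,
                     flexion_angle = angle,
                     hint_femur = hint(femur, sc$femur_pose),
                     hint_tray = hint(tray, sc$tray_pose))
        rad <- render_synthetic_radiograph(sc$scene, config$geometry,
                                           blur_sigma_px = config$blur_sigma_px,
                                           noise_sd = config$noise_sd,
                                           supersample = config$supersample,
                                           seed = seed_k, meta = meta)
        for (cd in c("medial", "lateral")) {
          truth_rows[[length(truth_rows) + 1]] <- data.frame(
            scene_id = scene_id, inlay_id = id, state = st, angle_deg = angle,
            condyle = cd,
            true_mjsw_mm = unname(sc$true_mjsw[cd]),
            cmm_mm = cmm[[paste(id, st, cd, sep = ".")]],
            imposed_wear_mm = if (st == "worn") config$wear_depths[i, cd] else 0)
        }
        scenes[[scene_id]] <- list(
          scene_id = scene_id, inlay_id = id, state = st, angle = angle,
          radiograph = rad, femur_mesh = femur, tray_mesh = tray,
          inlay_mesh = inlays[[id]][[st]],
          femur_pose = sc$femur_pose, tray_pose = sc$tray_pose,
          tibial_frame = sc$tibial_frame, true_mjsw = sc$true_mjsw,
          seed = seed_k, meta = meta)
        if (!is.null(out_dir))
          write_radiograph(rad, file.path(out_dir, "images",
                                          paste0(scene_id, ".png")))
      }
    }
  }
  truth <- do.call(rbind, truth_rows)
  if (!is.null(out_dir)) {
    write_stl(femur, file.path(out_dir, "meshes", "femur.stl"))
    write_stl(tray, file.path(out_dir, "meshes", "tray.stl"))
    for (id in names(inlays)) {
      write_stl(inlays[[id]]$new, file.path(out_dir, "meshes", paste0(id, "_new.stl")))
      write_stl(inlays[[id]]$worn, file.path(out_dir, "meshes", paste0(id, "_worn.stl")))
    }
    write.csv(truth, file.path(out_dir, "truth.csv"), row.names = FALSE)
    skel <- truth[, c("inlay_id", "state", "angle_deg", "condyle", "cmm_mm")]
    skel$mbwm_mm <- NA_real_
    skel$replicate <- 1L
    write.csv(skel, file.path(out_dir, "study_table.csv"), row.names = FALSE)
  }
  structure(list(scenes = scenes, truth = truth, inlays = inlays,
                 femur_mesh = femur, tray_mesh = tray, config = config),
            class = "phantom_dataset")
}

#' @export
print.phantom_dataset <- function(x, ...) {
  cat(sprintf("phantom_dataset: %d scenes, %d truth rows (seed %d)\n",
              length(x$scenes), nrow(x$truth), x$config$seed))
  invisible(x)
}
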