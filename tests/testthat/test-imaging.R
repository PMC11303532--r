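test_that("pixel pitch follows the DPI definition", {
  expect_equal(pixel_pitch(96), 25.4 / 96)
  expect_equal(pixel_pitch(25.4), 1.0)
  expect_error(pixel_pitch(0), "dpi")
  expect_error(imaging_geometry(sdd = -1), "sdd")
})

test_that("perspective projection follows similar triangles", {
  g <- imaging_geometry(sdd = 1150)
  expect_equal(as.numeric(project_points(g, rbind(c(0, 0, 575)))), c(0, 0))
  expect_equal(as.numeric(project_points(g, rbind(c(10, 0, 575)))), c(20, 0))
  expect_equal(as.numeric(project_points(g, rbind(c(0, 5, 1150 * 2 / 3)))), c(0, 7.5))
  expect_error(project_points(g, rbind(c(0, 0, -5))), "behind the source")
  expect_error(project_points(g, rbind(c(0, 0, 1200))), "behind the detector")
  # px <-> mm mapping round-trips
  uv <- cbind(runif(5, -50, 50), runif(5, -50, 50))
  expect_equal(mbwm:::detector_px_to_mm(g, mbwm:::detector_mm_to_px(g, uv)), uv,
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("rendered sphere silhouette matches the closed-form disc", {
  g <- imaging_geometry(sdd = 1150, dpi = 96, detector_size = c(256, 256))
  sph <- sphere_mesh(10, n_lat = 48, n_lon = 72)
  pose <- rigid_transform(0, 0, 575)
  mask <- render_silhouette(sph, pose, g, supersample = 3)
  contour <- silhouette_to_contour(mask, g)
  radii <- sqrt(rowSums(unclass(contour)^2))
  r_true <- 1150 * 10 / sqrt(575^2 - 10^2)
  expect_lt(abs(mean(radii) - r_true), 0.5 * g$pixel_pitch)
  # doubling the object distance halves the silhouette (closed-form check)
  r_z <- function(z) 1150 * 10 / sqrt(z^2 - 100) # disc radius at distance z
  mask2 <- render_silhouette(sph, rigid_transform(0, 0, 900), g, supersample = 3)
  maskh <- render_silhouette(sph, rigid_transform(0, 0, 450), g, supersample = 3)
  r2 <- mean(sqrt(rowSums(unclass(silhouette_to_contour(mask2, g))^2)))
  rh <- mean(sqrt(rowSums(unclass(silhouette_to_contour(maskh, g))^2)))
  expect_equal(rh / r2, r_z(450) / r_z(900), tolerance = 0.01)
  # translating the mesh shifts the mask centroid by d * sdd / z detector mm
  maskt <- render_silhouette(sph, rigid_transform(5, 0, 575), g, supersample = 3)
  c0 <- mbwm:::detector_px_to_mm(g, t(colMeans(which(mask == 1, arr.ind = TRUE))))
  c1 <- mbwm:::detector_px_to_mm(g, t(colMeans(which(maskt == 1, arr.ind = TRUE))))
  expect_equal(c1[1] - c0[1], 5 * 1150 / 575, tolerance = 0.05)
})

test_that("silhouette rasterization agrees with a ray-cast oracle off-boundary", {
  g <- imaging_geometry(sdd = 400, dpi = 26, detector_size = c(48, 48))
  box <- cube_mesh(origin = c(-6, -4, 0), side = 9)
  pose <- rigid_transform(0, 0, 195, 15, 25, 10)
  mask <- render_silhouette(box, pose, g, supersample = 4)
  oracle <- oracle_raycast_mask(box, pose, g)
  disagree <- which(mask != oracle, arr.ind = TRUE)
  if (nrow(disagree) > 0) {
    # every disagreement must touch a boundary pixel of the oracle mask
    on_boundary <- vapply(seq_len(nrow(disagree)), function(k) {
      r <- disagree[k, 1]; cc <- disagree[k, 2]
      rs <- max(1, r - 1):min(nrow(oracle), r + 1)
      cs <- max(1, cc - 1):min(ncol(oracle), cc + 1)
      length(unique(as.vector(oracle[rs, cs]))) > 1
    }, logical(1))
    expect_true(all(on_boundary))
  }
  expect_gt(sum(mask), 0)
})

test_that("silhouette_to_contour returns a sub-pixel 0.5-level boundary", {
  g <- imaging_geometry(sdd = 1000, dpi = 25.4, detector_size = c(101, 101)) # 1 mm pitch
  rc <- expand.grid(r = 1:101, c = 1:101)
  mask <- matrix(0, 101, 101)
  rad <- sqrt((rc$r - 51)^2 + (rc$c - 51)^2)
  mask[rad <= 20] <- 1
  contour <- silhouette_to_contour(mask, g)
  radii <- sqrt(rowSums(unclass(contour)^2))
  expect_true(all(abs(radii - 20) <= 0.5 + 1e-9)) # within half a pixel
  # enclosed area within 1 px^2 of foreground count x pitch^2
  expect_lt(abs(abs(mbwm:::contour_area(contour)) - sum(mask)), 1)
  # perimeter within 1% of the true circle for R >= 20 px, measured on the
  # renderer's fractional-coverage contour (a hard binary mask carries
  # staircase excess by construction)
  gg <- imaging_geometry(sdd = 1150, dpi = 96, detector_size = c(256, 256))
  sphp <- sphere_mesh(10, n_lat = 64, n_lon = 96)
  covp <- render_silhouette(sphp, rigid_transform(0, 0, 575), gg,
                            supersample = 4, coverage = TRUE)
  cp <- silhouette_to_contour(covp, gg)
  r_det <- 1150 * 10 / sqrt(575^2 - 100)
  expect_lt(abs(mbwm:::contour_perimeter(cp) - 2 * pi * r_det) / (2 * pi * r_det),
            0.01)
  # single pixel -> small loop enclosing ~ one pitch^2
  single <- matrix(0, 101, 101); single[40, 60] <- 1
  c1 <- silhouette_to_contour(single, g)
  expect_lt(abs(abs(mbwm:::contour_area(c1)) - 1), 1)
  # two disjoint blobs: largest returned, others reported separately
  two <- mask; two[5:8, 5:8] <- 1
  c2 <- silhouette_to_contour(two, g)
  expect_equal(nrow(c2), nrow(contour), tolerance = 2)
  expect_length(attr(c2, "others"), 1)
  expect_error(silhouette_to_contour(matrix(0, 10, 10), g), "empty")
})

test_that("synthetic radiographs are deterministic and threshold-exact when clean", {
  g <- imaging_geometry(sdd = 1150, dpi = 30, detector_size = c(128, 128))
  sph <- sphere_mesh(12, n_lat = 24, n_lon = 36)
  scene <- list(list(mesh = sph, pose = rigid_transform(0, 0, 575)))
  r0 <- render_synthetic_radiograph(scene, g, blur_sigma_px = 0, noise_sd = 0,
                                    seed = 5)
  mask <- render_silhouette(sph, rigid_transform(0, 0, 575), g)
  # implant dark on bright background: thresholding recovers the silhouette
  bg <- median(r0$pixels[mask == 0])
  inside <- median(r0$pixels[mask == 1])
  expect_lt(inside, bg / 2)
  recovered <- (r0$pixels < (inside + bg) / 2) + 0
  expect_equal(recovered, mask, ignore_attr = TRUE)
  # same seed -> bit-identical; different seed -> different noise
  r1 <- render_synthetic_radiograph(scene, g, seed = 9)
  r2 <- render_synthetic_radiograph(scene, g, seed = 9)
  r3 <- render_synthetic_radiograph(scene, g, seed = 10)
  expect_identical(r1$pixels, r2$pixels)
  expect_false(identical(r1$pixels, r3$pixels))
  # radiolucent components are not rendered
  r4 <- render_synthetic_radiograph(
    list(list(mesh = sph, pose = rigid_transform(0, 0, 575), radiopaque = FALSE)),
    g, blur_sigma_px = 0, noise_sd = 0, seed = 5)
  expect_gt(min(r4$pixels), 0.5)
  expect_error(render_synthetic_radiograph(scene, g, noise_sd = -1), "noise_sd")
})

test_that("radiograph PNG + sidecar round-trips the calibration", {
  g <- imaging_geometry(sdd = 1150, dpi = 96, detector_size = c(64, 64))
  px <- matrix(runif(64 * 64), 64, 64)
  rad <- radiograph(px, g, meta = list(scene_id = "t1", flexion_angle = 30))
  path <- withr::local_tempfile(fileext = ".png")
  write_radiograph(rad, path)
  back <- read_radiograph(path)
  expect_equal(back$geometry$sdd, 1150)
  expect_equal(back$geometry$dpi, 96)
  expect_equal(back$meta$scene_id, "t1")
  expect_equal(back$pixels, px, tolerance = 1 / 255, ignore_attr = TRUE)
  expect_lt(max(abs(back$pixels - px)), 1 / 255)
  expect_error(radiograph(matrix(0, 3, 3), g), "detector_size")
})
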