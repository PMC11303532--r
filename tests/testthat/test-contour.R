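make_disc_image <- function(nr = 160, nc = 160, r_px = 40, noise_sd = 0,
                            blur = 1, seed = 3) {
  g <- imaging_geometry(sdd = 1150, dpi = 96, detector_size = c(nr, nc))
  sph <- sphere_mesh(r_px * (25.4 / 96) / 2, n_lat = 40, n_lon = 64)
  z <- 575
  # pick the sphere radius so the projected disc is ~r_px pixels
  r_mm <- r_px * 25.4 / 96 * z / 1150
  sph <- sphere_mesh(r_mm, n_lat = 40, n_lon = 64)
  scene <- list(list(mesh = sph, pose = rigid_transform(0, 0, z)))
  rad <- render_synthetic_radiograph(scene, g, blur_sigma_px = blur,
                                     noise_sd = noise_sd, seed = seed)
  list(rad = rad, geometry = g,
       r_det = 1150 * r_mm / sqrt(z^2 - r_mm^2) / (25.4 / 96)) # radius in px
}

test_that("canny edge map honours the basic Canny contract", {
  g <- imaging_geometry(detector_size = c(64, 64))
  expect_equal(sum(canny_edge_map(matrix(0.5, 64, 64))), 0)
  # vertical step at column 32: edges within 1 px of the step
  img <- matrix(0.2, 64, 64)
  img[, 33:64] <- 0.8
  e <- canny_edge_map(img)
  cols <- ((which(e) - 1) %/% 64) + 1
  expect_gt(sum(e), 30)
  expect_true(all(abs(cols - 32.5) <= 1.5))
  # invariance under adding a constant (up to floating-point ties in the
  # non-maximum suppression of the perfectly symmetric blurred step)
  e2 <- canny_edge_map(img + 0.1)
  cols2 <- ((which(e2) - 1) %/% 64) + 1
  expect_true(all(abs(cols2 - 32.5) <= 1.5))
  expect_equal(sum(e2), sum(e), tolerance = 0.05)
  expect_error(canny_edge_map(img, low_frac = 0.5, high_frac = 0.3), "low_frac")
})

test_that("canny recovers the projected disc boundary within a pixel", {
  d <- make_disc_image(noise_sd = 0.02, blur = 1)
  e <- canny_edge_map(d$rad$pixels)
  rc <- which(e, arr.ind = TRUE)
  centre <- (d$geometry$detector_size + 1) / 2
  radii <- sqrt((rc[, 1] - centre[1])^2 + (rc[, 2] - centre[2])^2)
  ring <- radii > d$r_det - 6 & radii < d$r_det + 6 # ignore background-field edges
  expect_gt(mean(ring), 0.95)
  expect_lt(abs(mean(radii[ring]) - d$r_det), 1)
})

test_that("edge linking orders chains, drops speckle, converts to mm", {
  d <- make_disc_image(noise_sd = 0, blur = 1)
  e <- canny_edge_map(d$rad$pixels)
  # add a 3-px speckle chain
  e2 <- e
  e2[5, 5:7] <- TRUE
  contours <- link_edges_to_contours(e2, d$geometry, min_length = 10)
  expect_length(contours, 1)
  expect_true(attr(contours[[1]], "closed"))
  # ordered: consecutive points are close (sub-pixel-refined chain)
  steps <- sqrt(rowSums(diff(unclass(contours[[1]]))^2))
  expect_lt(max(steps), 3 * d$geometry$pixel_pitch)
  # radius in mm matches the projected disc radius
  radii <- sqrt(rowSums(unclass(contours[[1]])^2))
  expect_lt(abs(mean(radii) - d$r_det * d$geometry$pixel_pitch),
            0.5 * d$geometry$pixel_pitch)
  # sub-pixel refinement beats the raw pixel quantization on the clean disc
  expect_lt(sd(radii), 0.5 * d$geometry$pixel_pitch)
})

test_that("nested contours are both recovered and labelled by area", {
  # two concentric rings drawn directly on an edge map
  nr <- 120
  g <- imaging_geometry(detector_size = c(nr, nr))
  img <- matrix(0.9, nr, nr)
  rc <- expand.grid(r = 1:nr, c = 1:nr)
  rad <- matrix(sqrt((rc$r - 60.5)^2 + (rc$c - 60.5)^2), nr, nr)
  img[rad < 40] <- 0.5
  img[rad < 20] <- 0.15
  e <- canny_edge_map(img)
  contours <- link_edges_to_contours(e, g, min_length = 10)
  expect_length(contours, 2)
  a <- vapply(contours, function(cc) abs(mbwm:::contour_area(cc)), numeric(1))
  expect_true(a[1] > a[2]) # sorted by enclosed area
})

test_that("hint-driven contour selection is deterministic with documented ties", {
  sq <- function(cx, cy, h) contour2d(cbind(cx + c(-h, h, h, -h), cy + c(-h, -h, h, h)))
  contours <- list(sq(0, 0, 10), sq(50, 0, 10))
  got <- select_component_contour(contours, c(50, 0))
  expect_equal(got, contours[[2]])
  # rectangle hint
  got2 <- select_component_contour(contours, c(-12, 12, -12, 12))
  expect_equal(got2, contours[[1]])
  expect_error(select_component_contour(contours, c(200, 200)), "no contour")
  # identical contours equidistant from the hint: lowest index wins
  twins <- list(sq(0, 0, 10), sq(0, 0, 10))
  expect_identical(select_component_contour(twins, c(0, 0)), twins[[1]])
})

test_that("contour CSV export is tidy", {
  cc <- contour2d(cbind(c(0, 1, 1), c(0, 0, 1)))
  path <- withr::local_tempfile(fileext = ".csv")
  df <- write_contours_csv(list(cc), path)
  expect_equal(names(df), c("contour_id", "point_index", "u_mm", "v_mm"))
  expect_equal(nrow(read.csv(path)), 3)
})
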