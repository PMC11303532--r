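test_that("parametric inlay matches its nominal dimensions and is watertight", {
  inlay <- make_inlay_mesh(14)
  bb <- apply(inlay$vertices, 2, range)
  expect_equal(bb[, 1], c(-38, 38))   # 76 mm medio-lateral
  expect_equal(bb[, 2], c(0, 14))     # thickness
  expect_equal(bb[, 3], c(-25, 25))   # 50 mm antero-posterior
  expect_true(is_watertight(inlay))
  # probe-model minimum thickness: nominal minus dish depth
  expect_equal(cmm_probe_thickness(inlay, "medial"), 12, tolerance = 1e-3)
  expect_equal(cmm_probe_thickness(inlay, "lateral"), 12, tolerance = 1e-3)
  expect_error(make_inlay_mesh(2, dish_depth = 2), "dish_depth")
  expect_error(make_inlay_mesh(14, femoral_radius = 60, dish_depth = 59,
                               condyle_spacing = 46), "infeasible|dish")
})

test_that("the femoral component is congruent with the inlay and mirror-symmetric", {
  femur <- make_femur_mesh()
  # mirror symmetry about the midline
  mirrored <- femur$vertices %*% diag(c(-1, 1, 1))
  key <- function(v) sort(apply(round(v, 6), 1, paste, collapse = ","))
  expect_equal(key(mirrored), key(femur$vertices))
  # congruence: the seated femur sits within the contact gap on both condyles
  cfg <- scenario_config(thicknesses = 14, wear_depths = rbind(c(0, 0)))
  inlay <- make_inlay_mesh(14)
  tray <- make_tibial_tray_mesh()
  sc <- build_scene(cfg, inlay, femur, tray, 0)
  seated <- transform_mesh(femur, sc$femur_pose)
  inlay_w <- transform_mesh(inlay, sc$inlay_pose)
  parts <- split_condyles(seated, sc$tibial_frame)
  d_med <- mesh_min_distance(parts$medial, inlay_w)$distance
  d_lat <- mesh_min_distance(parts$lateral, inlay_w)$distance
  expect_lt(d_med, 0.01)
  expect_lt(d_lat, 0.01)
  # no penetration deeper than the solver tolerance
  sd <- point_to_mesh_deviation(seated$vertices, inlay_w)
  expect_gt(min(sd$signed_distance), -0.005)
})

test_that("seating responds to flexion and to wear as constructed", {
  cfg <- scenario_config(thicknesses = 10, wear_depths = rbind(c(0.3, 0.1)))
  inlay <- make_inlay_mesh(10)
  femur <- make_femur_mesh()
  tray <- make_tibial_tray_mesh()
  s0 <- build_scene(cfg, inlay, femur, tray, 0)
  # at 0 flexion the femur is level and centred over the dishes
  expect_equal(s0$femur_pose$rotation[1], 0)
  expect_equal(unname(s0$true_mjsw["medial"]), unname(s0$true_mjsw["lateral"]),
               tolerance = 1e-9)
  # worn scene: per-condyle mJSW drops by the imposed depth (uniform pool)
  worn <- apply_wear(apply_wear(inlay, "medial", 0.3), "lateral", 0.1)
  sw <- build_scene(cfg, worn, femur, tray, 0)
  expect_equal(unname(s0$true_mjsw - sw$true_mjsw), c(0.3, 0.1),
               tolerance = 5e-4)
  # differential wear is accommodated by a small varus tilt, not lift-off
  expect_gt(abs(sw$femur_pose$rotation[3]), 0.1)
  expect_error(build_scene(cfg, inlay, femur, tray, 45), "angle")
})

test_that("dataset generation is seed-deterministic with consistent ground truth", {
  cfg <- scenario_config(thicknesses = 14, wear_depths = rbind(c(0.15, 0.05)),
                         flexion_angles = 0, seed = 77)
  ds1 <- generate_dataset(cfg)
  expect_length(ds1$scenes, 2) # one inlay, one angle, new + worn
  expect_equal(nrow(ds1$truth), 4)
  ds2 <- generate_dataset(cfg)
  expect_identical(ds1$scenes[[1]]$radiograph$pixels,
                   ds2$scenes[[1]]$radiograph$pixels)
  expect_identical(ds1$truth, ds2$truth)
  # ground truth self-consistency: probe-model thickness drops by the
  # imposed depth, exactly
  tw <- ds1$truth
  for (cd in c("medial", "lateral")) {
    new <- tw[tw$state == "new" & tw$condyle == cd, ]
    worn <- tw[tw$state == "worn" & tw$condyle == cd, ]
    expect_equal(new$cmm_mm - worn$cmm_mm, worn$imposed_wear_mm,
                 tolerance = 1e-6)
    # seated mJSW follows to within the seating/tessellation tolerance
    expect_equal(new$true_mjsw_mm - worn$true_mjsw_mm, worn$imposed_wear_mm,
                 tolerance = 5e-4)
  }
  # a different master seed changes the rendered images
  cfg2 <- cfg
  cfg2$seed <- 78
  ds3 <- generate_dataset(cfg2)
  expect_false(identical(ds1$scenes[[1]]$radiograph$pixels,
                         ds3$scenes[[1]]$radiograph$pixels))
})

test_that("dataset files are written once and protected from collisions", {
  cfg <- scenario_config(thicknesses = 10, wear_depths = rbind(c(0.1, 0.1)),
                         flexion_angles = 0, seed = 5,
                         detector_size = c(256, 256))
  dir <- withr::local_tempdir()
  out <- file.path(dir, "ds")
  ds <- generate_dataset(cfg, out_dir = out)
  expect_true(file.exists(file.path(out, "truth.csv")))
  expect_true(file.exists(file.path(out, "study_table.csv")))
  expect_length(list.files(file.path(out, "images"), pattern = "\\.png$"), 2)
  expect_gt(length(list.files(file.path(out, "meshes"), pattern = "\\.stl$")), 3)
  expect_error(generate_dataset(cfg, out_dir = out), "force")
  expect_silent(generate_dataset(cfg, out_dir = out, force = TRUE))
  # round-trip a written radiograph
  png <- list.files(file.path(out, "images"), pattern = "\\.png$",
                    full.names = TRUE)[1]
  rad <- read_radiograph(png)
  expect_equal(rad$geometry$sdd, 1150)
})
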