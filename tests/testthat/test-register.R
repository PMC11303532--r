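circle_contour <- function(r, n = 720, centre = c(0, 0), phase = 0) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)] + phase
  contour2d(cbind(centre[1] + r * cos(th), centre[2] + r * sin(th)))
}

test_that("contour cost matches closed forms on circles", {
  c1 <- circle_contour(30)
  expect_equal(contour_cost(c1, c1), 0)
  # concentric circles radii r and r + d -> d (magnification 1)
  c2 <- circle_contour(30.5)
  expect_equal(contour_cost(c1, c2), 0.5, tolerance = 1e-3)
  # magnification rescales the cost to object scale
  expect_equal(contour_cost(c1, c2, magnification = 2), 0.25, tolerance = 1e-3)
  # small translation d: mean nearest distance -> (2/pi) d in the dense limit
  d <- 0.05
  c3 <- circle_contour(30, centre = c(d, 0))
  expect_equal(contour_cost(c1, c3), 2 * d / pi, tolerance = 0.03 * d)
  # invariant under order-preserving re-parameterization (cyclic shift,
  # reversal) of either contour
  c1s <- circle_contour(30, phase = 1.23)
  expect_equal(contour_cost(c1s, c3), contour_cost(c1, c3), tolerance = 1e-4)
  rev3 <- contour2d(unclass(c3)[nrow(c3):1, ])
  expect_equal(contour_cost(c1, rev3), contour_cost(c1, c3), tolerance = 1e-12)
  expect_error(contour_cost(cbind(1, 2), c1), "degenerate")
  expect_error(contour_cost(c1, c3, magnification = 0), "magnification")
})

test_that("annealed simplex at temperature zero is deterministic Nelder-Mead", {
  # smooth test function with a known optimum
  fn <- function(p) sum((p - c(1.5, -2, 0.5))^2) + 0.3 * sum(p^2)
  r1 <- with_seed(1, mbwm:::anneal_simplex(fn, c(0, 0, 0), rep(1, 3), 0, 0.9,
                                           0, 60, 1e-10, 5000))
  r2 <- with_seed(999, mbwm:::anneal_simplex(fn, c(0, 0, 0), rep(1, 3), 0, 0.9,
                                             0, 60, 1e-10, 5000))
  expect_identical(r1$par, r2$par) # the T = 0 path consumes no randomness
  ref <- optim(c(0, 0, 0), fn, method = "Nelder-Mead",
               control = list(reltol = 1e-12, maxit = 5000))
  expect_equal(r1$value, ref$value, tolerance = 1e-6)
  expect_equal(r1$par, ref$par, tolerance = 1e-3)
  expect_true(r1$converged)
})

test_that("annealing escapes a local basin that plain descent falls into", {
  # shallow double well: local minimum at +2 (value 0.3), global at -2 (0)
  fn <- function(p) {
    x <- p[1]
    min(0.2 * (x - 2)^2 + 0.3, 0.2 * (x + 2)^2) + 0.05 * p[2]^2
  }
  cold <- with_seed(4, mbwm:::anneal_simplex(fn, c(1.9, 0), c(0.3, 0.3), 0, 0.9,
                                             0, 30, 1e-9, 4000))
  expect_gt(cold$par[1], 0) # descent stays in the nearer well
  hot <- with_seed(4, mbwm:::anneal_simplex(fn, c(1.9, 0), c(1, 1), 1.5, 0.95,
                                            120, 6, 1e-9, 8000))
  expect_lt(hot$par[1], 0) # annealing crosses to the global well
  expect_lt(hot$value, cold$value)
})

# asymmetric L-shaped bracket: every rotation axis changes its silhouette
l_bracket <- function() {
  a <- triangle_mesh(sweep(cube_mesh()$vertices, 2, c(0.5, 0.5, 0.5)) %*%
                       diag(c(30, 14, 10)), cube_mesh()$faces)
  b <- triangle_mesh(sweep(cube_mesh()$vertices, 2, c(0.5, 0.5, 0.5)) %*%
                       diag(c(10, 18, 8)) + rep(1, 8) %o% c(10, 9, 3),
                     cube_mesh()$faces)
  triangle_mesh(rbind(a$vertices, b$vertices),
                rbind(a$faces, b$faces + nrow(a$vertices)))
}

test_that("pose registration recovers a noiseless bracket pose (fixed point + perturbed)", {
  g <- imaging_geometry(sdd = 1150, dpi = 96, detector_size = c(360, 360))
  bracket <- l_bracket()
  truth <- rigid_transform(2, -3, 575, 8, 12, 5)
  # fractional-coverage contour: sub-pixel, like the Canny-refined contours
  # the study pipeline feeds the optimizer
  covm <- render_silhouette(bracket, truth, g, supersample = 3, coverage = TRUE)
  ic <- silhouette_to_contour(covm, g)
  # fixed point: init at the truth
  r0 <- register_pose(bracket, ic, g, truth, reg_config(seed = 2))
  expect_lt(r0$final_residual, 0.02)
  expect_true(r0$converged)
  expect_lt(max(abs(r0$pose$translation[1:2] - truth$translation[1:2])), 0.05)
  # perturbed init: 2 mm / 2 deg
  init <- rigid_transform(2 + 1.6, -3 - 1.8, 575, 8 + 1.7, 12 - 1.5, 5 + 1.9)
  r1 <- register_pose(bracket, ic, g, init, reg_config(seed = 3))
  expect_true(r1$converged)
  expect_lt(r1$final_residual, 0.03)
  expect_lt(max(abs(r1$pose$translation[1:2] - truth$translation[1:2])), 0.05)
  # in-plane rotation is strongly observable; out-of-plane ones less so
  expect_lt(abs(r1$pose$rotation[3] - truth$rotation[3]), 0.3)
  expect_lt(max(abs(r1$pose$rotation[1:2] - truth$rotation[1:2])), 1.5)
  # beam-axis translation was frozen, never silently moved
  expect_equal(r1$pose$translation[3], 575)
  # determinism for a fixed seed
  r2 <- register_pose(bracket, ic, g, init, reg_config(seed = 3))
  expect_identical(r1$pose, r2$pose)
  expect_identical(r1$final_residual, r2$final_residual)
})

test_that("non-convergence is flagged, never silent", {
  g <- imaging_geometry(sdd = 1150, dpi = 96, detector_size = c(360, 360))
  bracket <- l_bracket()
  truth <- rigid_transform(0, 0, 575)
  ic <- silhouette_to_contour(render_silhouette(bracket, truth, g), g)
  # an evaluation budget far too small to converge
  r <- register_pose(bracket, ic, g, rigid_transform(8, -8, 575, 9, -9, 9),
                     reg_config(seed = 1, max_eval = 12, temp_steps = 1,
                                restarts = 0))
  expect_false(r$converged)
})
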