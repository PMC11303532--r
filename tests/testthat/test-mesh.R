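test_that("ASCII STL round-trips the smallest valid model", {
  txt <- c("solid tri",
           "  facet normal 0 0 1",
           "    outer loop",
           "      vertex 0 0 0",
           "      vertex 1 0 0",
           "      vertex 0 1 0",
           "    endloop",
           "  endfacet",
           "endsolid tri")
  path <- withr::local_tempfile(fileext = ".stl")
  writeLines(txt, path)
  m <- read_stl(path)
  expect_equal(nrow(m$vertices), 3)
  expect_equal(nrow(m$faces), 1)
  expect_equal(m$vertices[m$faces[1, ], ],
               rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)))
})

test_that("binary STL write-then-read preserves geometry and topology", {
  cube <- cube_mesh(side = 12.345)
  path <- withr::local_tempfile(fileext = ".stl")
  write_stl(cube, path, "binary")
  back <- read_stl(path)
  expect_equal(nrow(back$faces), 12)
  expect_equal(nrow(back$vertices), 8)
  # same geometry to float32 precision (1e-6 mm relative scale)
  reorder <- match(
    apply(round(cube$vertices, 5), 1, paste, collapse = ","),
    apply(round(back$vertices, 5), 1, paste, collapse = ","))
  expect_false(anyNA(reorder))
  expect_equal(back$vertices[reorder, ], cube$vertices, tolerance = 1e-6,
               ignore_attr = TRUE)
  # identical face topology after relabelling
  f1 <- t(apply(cube$faces, 1, function(f) sort(reorder[match(f, seq_len(8))])))
  f1 <- matrix(reorder[cube$faces], ncol = 3)
  norm_faces <- function(f) {
    keys <- apply(f, 1, function(r) paste(sort(r), collapse = "-"))
    sort(keys)
  }
  expect_equal(norm_faces(f1), norm_faces(back$faces))
  # ASCII dialect round-trip preserves coordinates to 1e-6
  patha <- withr::local_tempfile(fileext = ".stl")
  write_stl(cube, patha, "ascii")
  backa <- read_stl(patha)
  expect_equal(sort(backa$vertices[, 1]), sort(cube$vertices[, 1]), tolerance = 1e-9)
})

test_that("malformed binary STL reports the truncation byte offset", {
  cube <- cube_mesh()
  path <- withr::local_tempfile(fileext = ".stl")
  write_stl(cube, path, "binary")
  raw <- readBin(path, "raw", file.info(path)$size)
  truncated <- withr::local_tempfile(fileext = ".stl")
  writeBin(raw[1:(length(raw) - 60)], truncated)
  expect_error(read_stl(truncated), "byte offset")
  expect_error(read_stl("no/such/file.stl"), "not found")
})

test_that("rigid transforms preserve distances and invert exactly", {
  t1 <- rigid_transform(1, 2, 3)
  expect_equal(transform_points(rbind(c(0, 0, 0)), t1), cbind(u = 1, v = 2, 3),
               ignore_attr = TRUE)
  # identity
  m <- sphere_mesh(5, n_lat = 6, n_lon = 8)
  expect_equal(transform_mesh(m, rigid_transform())$vertices, m$vertices)
  # rx = 90 twice maps (0,1,0) -> (0,-1,0)
  r90 <- rigid_transform(rx = 90)
  p <- transform_points(transform_points(rbind(c(0, 1, 0)), r90), r90)
  expect_equal(as.numeric(p), c(0, -1, 0), tolerance = 1e-12)
  # random rigid transforms: isometry + exact inverse
  set.seed(11)
  for (i in 1:5) {
    tr <- rigid_transform(runif(1, -50, 50), runif(1, -50, 50), runif(1, -50, 50),
                          runif(1, -180, 180), runif(1, -90, 90), runif(1, -180, 180))
    R <- rotation_matrix(tr)
    expect_equal(t(R) %*% R, diag(3), tolerance = 1e-9)
    expect_equal(det(R), 1, tolerance = 1e-9)
    W <- transform_points(m$vertices, tr)
    d0 <- dist(m$vertices[1:10, ])
    expect_equal(as.numeric(dist(W[1:10, ])), as.numeric(d0), tolerance = 1e-9)
    back <- transform_points(W, invert_transform(tr))
    expect_equal(back, m$vertices, tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("mesh_min_distance matches closed forms and the brute-force oracle", {
  a <- cube_mesh()
  b <- cube_mesh(origin = c(4, 0, 0))
  r <- mesh_min_distance(a, b)
  expect_equal(r$distance, 3, tolerance = 1e-12)
  expect_equal(mesh_min_distance(b, a)$distance, 3, tolerance = 1e-12)
  # mesh vs itself -> 0
  expect_equal(mesh_min_distance(a, a)$distance, 0)
  # spheres r = 5, centres 20 apart: 10 mm within the chord sagitta
  s1 <- sphere_mesh(5, c(0, 0, 0), 14, 20)
  s2 <- sphere_mesh(5, c(20, 0, 0), 14, 20)
  d <- mesh_min_distance(s1, s2)$distance
  sagitta <- 5 * (1 - cos(pi / 14)) + 5 * (1 - cos(pi / 20))
  expect_lt(abs(d - 10), 2 * sagitta + 1e-9)
  expect_equal(d, oracle_mesh_min_distance(s1, s2), tolerance = 1e-9)
  # intersecting meshes -> 0
  expect_equal(mesh_min_distance(a, cube_mesh(origin = c(0.5, 0.5, 0.5)))$distance, 0)
  # transform invariance
  tr <- rigid_transform(3, -7, 11, 20, -35, 50)
  r2 <- mesh_min_distance(transform_mesh(s1, tr), transform_mesh(s2, tr))
  expect_equal(r2$distance, d, tolerance = 1e-9)
})

test_that("random triangle soups agree with the exhaustive oracle", {
  for (i in 1:6) {
    a <- random_soup(25, origin = c(0, 0, 0), seed = 100 + i)
    b <- random_soup(25, origin = c(1.4, 0.3, -0.2), seed = 200 + i)
    expect_equal(mesh_min_distance(a, b)$distance,
                 oracle_mesh_min_distance(a, b), tolerance = 1e-9)
  }
})

test_that("signed point-to-mesh deviation follows the pseudonormal convention", {
  cube <- cube_mesh() # unit cube [0,1]^3
  dev <- point_to_mesh_deviation(cube$vertices, cube)
  expect_equal(dev$signed_distance, rep(0, 8))
  # point above the top face: positive, below inside: negative
  dev2 <- point_to_mesh_deviation(rbind(c(0.5, 0.5, 1.25), c(0.5, 0.5, 0.75)), cube)
  expect_equal(dev2$signed_distance, c(0.25, -0.25), tolerance = 1e-12)
  expect_equal(abs(dev2$signed_distance), dev2$distance)
  expect_equal(dev2$min, -0.25)
  expect_equal(dev2$max, 0.25)
  # cube vertices vs the cube inflated by 0.5 along face normals: ~ -0.5 each
  big <- cube_mesh(origin = c(-0.5, -0.5, -0.5), side = 2)
  dev3 <- point_to_mesh_deviation(cube$vertices, big)
  expect_equal(dev3$signed_distance, rep(-0.5, 8), tolerance = 1e-12)
  expect_error(point_to_mesh_deviation(matrix(0, 0, 3), cube), "empty")
})

test_that("deviation CSV export has the documented columns", {
  cube <- cube_mesh()
  pts <- rbind(c(0.5, 0.5, 1.5), c(0.5, 0.5, 0.5))
  dev <- point_to_mesh_deviation(pts, cube)
  path <- withr::local_tempfile(fileext = ".csv")
  df <- write_deviation_csv(pts, dev, path)
  back <- read.csv(path)
  expect_equal(names(back),
               c("point_id", "dx", "dy", "dz", "signed_distance_mm"))
  expect_equal(back$signed_distance_mm, c(0.5, -0.5))
})

test_that("quadric decimation respects the face budget and surface fidelity", {
  dense <- sphere_mesh(10, n_lat = 80, n_lon = 128) # ~20k faces
  expect_gt(nrow(dense$faces), 19000)
  out <- decimate_mesh(dense, 5000)
  expect_lte(nrow(out$mesh$faces), 5000)
  expect_true(is_watertight(out$mesh))
  # deviation of original vertices below 2% of the radius
  expect_lt(max(abs(out$deviation$signed_distance)), 0.02 * 10)
  # decimating to the current face count leaves topology unchanged
  small <- sphere_mesh(5, n_lat = 8, n_lon = 12)
  same <- decimate_mesh(small, nrow(small$faces))
  expect_equal(same$mesh$faces, small$faces)
  expect_error(decimate_mesh(small, 1), "target_faces")
  # non-manifold input: three faces sharing one edge
  bad <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                             c(0, -1, 0)),
                       rbind(c(1, 2, 3), c(1, 2, 4), c(1, 2, 5)))
  expect_error(decimate_mesh(bad, 4), "non-manifold")
})
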