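#' Triangle surface mesh
#'
#' Light-weight triangle mesh container used throughout the package. All
#' coordinates are in millimetres. Faces are 1-based vertex index triples
#' wound counter-clockwise when viewed from outside, so face normals point
#' out of the material.
#'
#' @param vertices numeric n x 3 matrix of vertex coordinates (mm)
#' @param faces integer m x 3 matrix of vertex indices (1-based)
#' @param labels optional per-vertex labels (e.g. an articulating-surface flag)
#' @return an object of class `triangle_mesh` with elements `vertices`,
#'   `faces` and `labels`
#' @export
triangle_mesh <- function(vertices, faces, labels = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  if (ncol(vertices) != 3) stopf("vertices must be an n x 3 matrix")
  if (!all(is.finite(vertices))) stopf("vertex coordinates must be finite")
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(faces) != 3) stopf("faces must be an m x 3 matrix")
  if (nrow(faces) > 0 && (min(faces) < 1 || max(faces) > nrow(vertices)))
    stopf("face indices out of range [1, %d]", nrow(vertices))
  if (!is.null(labels) && length(labels) != nrow(vertices))
    stopf("labels must have one entry per vertex")
  # drop degenerate (zero-area) faces
  if (nrow(faces) > 0) {
    a <- vertices[faces[, 1], , drop = FALSE]
    b <- vertices[faces[, 2], , drop = FALSE]
    c <- vertices[faces[, 3], , drop = FALSE]
    e1 <- b - a
    e2 <- c - a
    cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
                e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
                e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
    area2 <- sqrt(rowSums(cr^2))
    faces <- faces[area2 > 1e-12, , drop = FALSE]
  }
  structure(list(vertices = vertices, faces = faces, labels = labels),
            class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  bb <- apply(x$vertices, 2, range)
  cat(sprintf("triangle_mesh: %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  cat(sprintf("  bbox x [%.2f, %.2f]  y [%.2f, %.2f]  z [%.2f, %.2f] mm\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  invisible(x)
}

n_faces <- function(mesh) nrow(mesh$faces)
n_vertices <- function(mesh) nrow(mesh$vertices)

#' Rigid transform (3 translations mm, 3 rotations degrees)
#'
#' Rotations are about the fixed world axes, applied in the order X, then Y,
#' then Z (so the rotation matrix is `Rz %*% Ry %*% Rx`), in degrees. A point
#' `p` maps to `R p + t`. This convention is the package's own and is stated
#' here because exported poses are only interpretable together with it.
#'
#' @param tx,ty,tz translation components (mm)
#' @param rx,ry,rz rotations about the world X, Y, Z axes (degrees)
#' @return an object of class `rigid_transform`
#' @export
rigid_transform <- function(tx = 0, ty = 0, tz = 0, rx = 0, ry = 0, rz = 0) {
  v <- c(tx = tx, ty = ty, tz = tz, rx = rx, ry = ry, rz = rz)
  if (!all(is.finite(v))) stopf("transform parameters must be finite")
  structure(list(translation = c(tx, ty, tz), rotation = c(rx, ry, rz)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("rigid_transform: t = (%.4f, %.4f, %.4f) mm, r = (%.4f, %.4f, %.4f) deg (X,Y,Z fixed axes)\n",
              x$translation[1], x$translation[2], x$translation[3],
              x$rotation[1], x$rotation[2], x$rotation[3]))
  invisible(x)
}

#' Rotation matrix of a rigid transform
#' @param transform a [rigid_transform()]
#' @return 3 x 3 orthonormal rotation matrix (det +1)
#' @export
rotation_matrix <- function(transform) {
  r <- transform$rotation * pi / 180
  cx <- cos(r[1]); sx <- sin(r[1])
  cy <- cos(r[2]); sy <- sin(r[2])
  cz <- cos(r[3]); sz <- sin(r[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

# Euler angles (deg, X-Y-Z fixed-axes convention) from a rotation matrix
angles_from_matrix <- function(R) {
  sy <- -R[3, 1]
  sy <- min(1, max(-1, sy))
  ry <- asin(sy)
  if (abs(cos(ry)) > 1e-9) {
    rx <- atan2(R[3, 2], R[3, 3])
    rz <- atan2(R[2, 1], R[1, 1])
  } else { # gimbal lock: put all in-plane rotation into rz
    rx <- 0
    rz <- atan2(-R[1, 2], R[2, 2])
  }
  c(rx, ry, rz) * 180 / pi
}

#' Apply a rigid transform to 3D points
#' @param points n x 3 matrix (mm)
#' @param transform a [rigid_transform()]
#' @export
transform_points <- function(points, transform) {
  points <- rbind(points)
  R <- rotation_matrix(transform)
  sweep(points %*% t(R), 2, transform$translation, "+")
}

#' Apply a rigid transform to a mesh
#' @param mesh a [triangle_mesh()]
#' @param transform a [rigid_transform()]
#' @return the transformed mesh (topology untouched)
#' @export
transform_mesh <- function(mesh, transform) {
  mesh$vertices <- transform_points(mesh$vertices, transform)
  mesh
}

#' Invert a rigid transform
#' @param transform a [rigid_transform()]
#' @export
invert_transform <- function(transform) {
  R <- rotation_matrix(transform)
  Ri <- t(R)
  ti <- -Ri %*% transform$translation
  ang <- angles_from_matrix(Ri)
  rigid_transform(ti[1], ti[2], ti[3], ang[1], ang[2], ang[3])
}

#' Compose two rigid transforms (apply `first`, then `second`)
#' @param first,second [rigid_transform()] objects
#' @export
compose_transforms <- function(first, second) {
  R <- rotation_matrix(second) %*% rotation_matrix(first)
  t <- rotation_matrix(second) %*% first$translation + second$translation
  ang <- angles_from_matrix(R)
  rigid_transform(t[1], t[2], t[3], ang[1], ang[2], ang[3])
}

#' Minimum distance between two triangle meshes
#'
#' Global minimum point-to-triangle distance over all vertex/edge/face feature
#' pairs, with witness points. Queries are accelerated with an axis-aligned
#' bounding-box tree; correctness is defined by the exhaustive triangle-pair
#' minimum (the brute-force oracle used in the test suite). Intersecting
#' meshes return distance 0 with a contact witness.
#'
#' @param a,b [triangle_mesh()] objects (non-empty)
#' @return list with `distance` (mm), `point_a`, `point_b` (closest points)
#' @export
mesh_min_distance <- function(a, b) {
  if (n_faces(a) == 0 || n_faces(b) == 0) stopf("meshes must be non-empty")
  cpp_mesh_min_distance(a$vertices, a$faces, b$vertices, b$faces)
}

#' Signed distances from points to a mesh
#'
#' Positive outside the surface (along the outward normal), negative inside.
#' The sign is taken from angle-weighted pseudonormals, which are robust when
#' the closest feature is an edge or a vertex.
#'
#' @param points n x 3 matrix (mm)
#' @param mesh a [triangle_mesh()]
#' @return list with per-point `signed_distance`, `distance`, `closest`
#'   points, and `min`/`max` summaries of the signed distances
#' @export
point_to_mesh_deviation <- function(points, mesh) {
  points <- rbind(points)
  if (nrow(points) == 0) stopf("empty point set")
  r <- cpp_signed_point_mesh(points, mesh$vertices, mesh$faces)
  r$min <- min(r$signed_distance)
  r$max <- max(r$signed_distance)
  r
}

#' Write a point-to-mesh deviation report as CSV
#' @param points the query points used
#' @param deviation result of [point_to_mesh_deviation()]
#' @param path output CSV path
#' @export
write_deviation_csv <- function(points, deviation, path) {
  d <- points - deviation$closest
  df <- data.frame(point_id = seq_len(nrow(points)),
                   dx = d[, 1], dy = d[, 2], dz = d[, 3],
                   signed_distance_mm = deviation$signed_distance)
  write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Decimate a mesh by quadric edge collapse
#'
#' Iterative edge collapse driven by the quadric error metric, with
#' link-condition and normal-flip guards. Boundary rims are preserved by
#' heavy constraint quadrics. The deviation of the original vertices to the
#' decimated surface is reported alongside the mesh.
#'
#' @param mesh a [triangle_mesh()]; must be edge-manifold
#' @param target_faces requested maximum face count (>= 4)
#' @return list with `mesh` (the decimated [triangle_mesh()]) and `deviation`
#'   (signed distances of the original vertices to the decimated surface)
#' @export
decimate_mesh <- function(mesh, target_faces) {
  if (target_faces < 4) stopf("target_faces must be >= 4 (cannot close a surface)")
  bad <- cpp_nonmanifold_edges(mesh$faces)
  if (nrow(bad) > 0) {
    stopf("non-manifold input: %d edge(s) with > 2 incident faces, e.g. (%s)",
          nrow(bad), paste(bad[1, ], collapse = ", "))
  }
  if (n_faces(mesh) <= target_faces) {
    dev <- point_to_mesh_deviation(mesh$vertices, mesh)
    return(list(mesh = mesh, deviation = dev))
  }
  r <- cpp_decimate(mesh$vertices, mesh$faces, as.integer(target_faces))
  out <- triangle_mesh(r$vertices, r$faces)
  dev <- point_to_mesh_deviation(mesh$vertices, out)
  list(mesh = out, deviation = dev)
}
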