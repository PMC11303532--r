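# Independent brute-force oracles. These share no code with the package's
# C++ distance path: vectorized R implementations of point-to-triangle and
# segment-to-segment distance, combined exhaustively over all feature pairs.

# distances from one point to every triangle (va, vb, vc are m x 3)
oracle_point_triangles <- function(p, va, vb, vc) {
  ab <- vb - va; ac <- vc - va
  ap <- sweep(-va, 2, p, "+")
  d1 <- rowSums(ab * ap); d2 <- rowSums(ac * ap)
  bp <- sweep(-vb, 2, p, "+")
  d3 <- rowSums(ab * bp); d4 <- rowSums(ac * bp)
  cp <- sweep(-vc, 2, p, "+")
  d5 <- rowSums(ab * cp); d6 <- rowSums(ac * cp)
  vc_ <- d1 * d4 - d3 * d2
  vb_ <- d5 * d2 - d1 * d6
  va_ <- d3 * d6 - d5 * d4
  m <- nrow(va)
  q <- matrix(NA_real_, m, 3)
  reg1 <- d1 <= 0 & d2 <= 0
  q[reg1, ] <- va[reg1, , drop = FALSE]
  reg2 <- is.na(q[, 1]) & d3 >= 0 & d4 <= d3
  q[reg2, ] <- vb[reg2, , drop = FALSE]
  reg3 <- is.na(q[, 1]) & vc_ <= 0 & d1 >= 0 & d3 <= 0
  t3 <- d1 / (d1 - d3)
  q[reg3, ] <- va[reg3, , drop = FALSE] + t3[reg3] * ab[reg3, , drop = FALSE]
  reg4 <- is.na(q[, 1]) & d6 >= 0 & d5 <= d6
  q[reg4, ] <- vc[reg4, , drop = FALSE]
  reg5 <- is.na(q[, 1]) & vb_ <= 0 & d2 >= 0 & d6 <= 0
  t5 <- d2 / (d2 - d6)
  q[reg5, ] <- va[reg5, , drop = FALSE] + t5[reg5] * ac[reg5, , drop = FALSE]
  reg6 <- is.na(q[, 1]) & va_ <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0
  t6 <- (d4 - d3) / ((d4 - d3) + (d5 - d6))
  q[reg6, ] <- vb[reg6, , drop = FALSE] +
    t6[reg6] * (vc[reg6, , drop = FALSE] - vb[reg6, , drop = FALSE])
  rest <- is.na(q[, 1])
  if (any(rest)) {
    denom <- va_ + vb_ + vc_
    v <- vb_ / denom; w <- vc_ / denom
    q[rest, ] <- va[rest, , drop = FALSE] + v[rest] * ab[rest, , drop = FALSE] +
      w[rest] * ac[rest, , drop = FALSE]
  }
  sqrt(rowSums(sweep(q, 2, p, "-")^2))
}

# distances from one segment (p1, q1) to every segment (P2, Q2: m x 3)
oracle_segment_segments <- function(p1, q1, P2, Q2) {
  EPS <- 1e-14
  d1 <- q1 - p1
  D2 <- Q2 - P2
  R <- sweep(-P2, 2, p1, "+")
  a <- sum(d1 * d1)
  e <- rowSums(D2 * D2)
  f <- rowSums(D2 * R)
  cc <- as.vector(R %*% d1)
  b <- as.vector(D2 %*% d1)
  denom <- a * e - b * b
  s <- ifelse(denom > EPS, pmin(pmax((b * f - cc * e) / denom, 0), 1), 0)
  t <- ifelse(e > EPS, (b * s + f) / e, 0)
  s <- ifelse(t < 0, pmin(pmax(-cc / a, 0), 1), s)
  s <- ifelse(t > 1, pmin(pmax((b - cc) / a, 0), 1), s)
  t <- pmin(pmax(t, 0), 1)
  if (a <= EPS) s <- rep(0, length(e))
  c1 <- outer(s, d1) ; c1 <- sweep(c1, 2, p1, "+")
  c2 <- P2 + D2 * t
  sqrt(rowSums((c1 - c2)^2))
}

mesh_edges <- function(mesh) {
  e <- rbind(mesh$faces[, 1:2], mesh$faces[, 2:3], mesh$faces[, c(3, 1)])
  unique(cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
}

# exhaustive vertex-face + edge-edge minimum distance between two meshes
oracle_mesh_min_distance <- function(a, b) {
  best <- Inf
  va <- b$vertices[b$faces[, 1], , drop = FALSE]
  vb <- b$vertices[b$faces[, 2], , drop = FALSE]
  vc <- b$vertices[b$faces[, 3], , drop = FALSE]
  for (i in seq_len(nrow(a$vertices)))
    best <- min(best, oracle_point_triangles(a$vertices[i, ], va, vb, vc))
  ua <- a$vertices[a$faces[, 1], , drop = FALSE]
  ub <- a$vertices[a$faces[, 2], , drop = FALSE]
  uc <- a$vertices[a$faces[, 3], , drop = FALSE]
  for (i in seq_len(nrow(b$vertices)))
    best <- min(best, oracle_point_triangles(b$vertices[i, ], ua, ub, uc))
  ea <- mesh_edges(a)
  eb <- mesh_edges(b)
  P2 <- b$vertices[eb[, 1], , drop = FALSE]
  Q2 <- b$vertices[eb[, 2], , drop = FALSE]
  for (i in seq_len(nrow(ea)))
    best <- min(best, oracle_segment_segments(a$vertices[ea[i, 1], ],
                                              a$vertices[ea[i, 2], ], P2, Q2))
  best
}

# ray-cast silhouette oracle: pixel centre rays vs Moller-Trumbore in R
oracle_raycast_mask <- function(mesh, pose, geometry) {
  W <- mbwm::transform_points(mesh$vertices, pose)
  nr <- geometry$detector_size[1]; nc <- geometry$detector_size[2]
  v1 <- W[mesh$faces[, 1], , drop = FALSE]
  e1 <- W[mesh$faces[, 2], , drop = FALSE] - v1
  e2 <- W[mesh$faces[, 3], , drop = FALSE] - v1
  mask <- matrix(0, nr, nc)
  pitch <- geometry$pixel_pitch
  pp <- geometry$principal_point
  for (r in seq_len(nr)) {
    for (cl in seq_len(nc)) {
      u <- (cl - pp[1]) * pitch
      v <- (pp[2] - r) * pitch
      d <- c(u, v, geometry$sdd)
      h <- cbind(d[2] * e2[, 3] - d[3] * e2[, 2],
                 d[3] * e2[, 1] - d[1] * e2[, 3],
                 d[1] * e2[, 2] - d[2] * e2[, 1])
      det <- rowSums(e1 * h)
      ok <- abs(det) > 1e-12
      if (!any(ok)) next
      inv <- 1 / det[ok]
      s <- -v1[ok, , drop = FALSE]
      uu <- rowSums(s * h[ok, , drop = FALSE]) * inv
      q <- cbind(s[, 2] * e1[ok, 3] - s[, 3] * e1[ok, 2],
                 s[, 3] * e1[ok, 1] - s[, 1] * e1[ok, 3],
                 s[, 1] * e1[ok, 2] - s[, 2] * e1[ok, 1])
      vv <- (q %*% d) * inv
      hit <- uu >= 0 & uu <= 1 & vv >= 0 & (uu + vv) <= 1
      if (any(hit)) mask[r, cl] <- 1
    }
  }
  mask
}
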