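# Mesh fixtures built in code: unit cube, lat-long sphere, slabs.
# Windings are counter-clockwise seen from outside (outward normals).

cube_mesh <- function(origin = c(0, 0, 0), side = 1) {
  v <- as.matrix(expand.grid(x = c(0, side), y = c(0, side), z = c(0, side)))
  v <- sweep(v, 2, origin, "+")
  # vertices: 1 (0,0,0) 2 (1,0,0) 3 (0,1,0) 4 (1,1,0) 5..8 with z = 1
  f <- rbind(c(1, 4, 2), c(1, 3, 4),   # z = 0, normal -z
             c(5, 6, 8), c(5, 8, 7),   # z = 1, normal +z
             c(1, 2, 6), c(1, 6, 5),   # y = 0, normal -y
             c(3, 8, 4), c(3, 7, 8),   # y = 1, normal +y
             c(1, 5, 7), c(1, 7, 3),   # x = 0, normal -x
             c(2, 4, 8), c(2, 8, 6))   # x = 1, normal +x
  triangle_mesh(v, f)
}

# closed lat-long sphere with exact pole vertices
sphere_mesh <- function(radius = 1, center = c(0, 0, 0), n_lat = 16, n_lon = 24) {
  th <- seq(0, pi, length.out = n_lat + 1)[2:n_lat] # exclude poles
  ph <- seq(0, 2 * pi, length.out = n_lon + 1)[-(n_lon + 1)]
  grid <- expand.grid(th = th, ph = ph)
  v <- cbind(radius * sin(grid$th) * cos(grid$ph),
             radius * sin(grid$th) * sin(grid$ph),
             radius * cos(grid$th))
  np <- nrow(v)
  v <- rbind(v, c(0, 0, radius), c(0, 0, -radius))
  top <- np + 1L
  bot <- np + 2L
  id <- function(i, j) ((j - 1) %% n_lon) * (n_lat - 1) + i
  f <- list()
  for (j in seq_len(n_lon)) {
    f[[length(f) + 1]] <- cbind(top, id(1, j), id(1, j + 1))
    f[[length(f) + 1]] <- cbind(bot, id(n_lat - 1, j + 1), id(n_lat - 1, j))
    for (i in seq_len(n_lat - 2)) {
      a <- id(i, j); b <- id(i + 1, j); c <- id(i + 1, j + 1); d <- id(i, j + 1)
      f[[length(f) + 1]] <- rbind(cbind(a, b, c), cbind(a, c, d))
    }
  }
  m <- triangle_mesh(sweep(v, 2, center, "+"), do.call(rbind, f))
  attr(m, "radius") <- radius
  m
}

# random triangle soup inside a unit box at the given origin
random_soup <- function(n_faces, origin = c(0, 0, 0), scale = 1, seed = 1) {
  set.seed(seed)
  v <- matrix(runif(3 * 3 * n_faces), ncol = 3) * scale
  v <- sweep(v, 2, origin, "+")
  triangle_mesh(v, matrix(seq_len(3 * n_faces), ncol = 3, byrow = TRUE))
}

# every undirected edge belongs to exactly two faces
is_watertight <- function(mesh) {
  e <- rbind(mesh$faces[, 1:2], mesh$faces[, 2:3], mesh$faces[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2)
}
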