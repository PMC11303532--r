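# Implant contour detection in a radiograph: Canny edges, sub-pixel
# refinement across the edge normal, linking into ordered contours in
# detector mm, and hint-driven selection of a component's contour.

sobel_gradients <- function(img) {
  kx <- rbind(c(-1, 0, 1), c(-2, 0, 2), c(-1, 0, 1)) / 8
  ky <- t(kx)
  # gx: intensity change along columns (u direction), gy along rows;
  # replicate boundaries so the image border creates no wrap-around edges
  gx <- EBImage::imageData(EBImage::filter2(img, kx, boundary = "replicate"))
  gy <- EBImage::imageData(EBImage::filter2(img, ky, boundary = "replicate"))
  dim(gx) <- dim(img); dim(gy) <- dim(img)
  list(gx = gx, gy = gy, mag = sqrt(gx^2 + gy^2))
}

shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

#' Canny edge map of a radiograph image
#'
#' Standard Canny contract: Gaussian smoothing, Sobel gradients, non-maximum
#' suppression along the quantized gradient direction, and hysteresis
#' thresholding (8-connected). Thresholds are fractions of the maximum
#' gradient magnitude, so the edge map is invariant under adding a constant
#' to the image. A constant image yields an empty edge map.
#'
#' @param image numeric intensity matrix (or a [radiograph()])
#' @param gaussian_sigma_px smoothing sigma in pixels
#' @param low_frac,high_frac hysteresis thresholds as fractions of the max
#'   gradient magnitude, `0 < low_frac < high_frac <= 1`
#' @return logical edge matrix with the smoothed gradients attached as
#'   attributes `gx`, `gy`, `mag` (used for sub-pixel refinement)
#' @export
canny_edge_map <- function(image, gaussian_sigma_px = 1.0,
                           low_frac = 0.1, high_frac = 0.2) {
  if (inherits(image, "radiograph")) image <- image$pixels
  if (!all(is.finite(image))) stopf("image must be finite")
  if (!(low_frac > 0 && low_frac < high_frac && high_frac <= 1))
    stopf("need 0 < low_frac < high_frac <= 1")
  sm <- if (gaussian_sigma_px > 0) gaussian_blur(image, gaussian_sigma_px) else image
  g <- sobel_gradients(sm)
  mag <- g$mag
  mmax <- max(mag)
  # numerically featureless image (constant up to FFT round-off) -> no edges
  if (mmax <= 1e-10 * max(1, max(abs(image)))) {
    edges <- matrix(FALSE, nrow(image), ncol(image))
    attr(edges, "gx") <- g$gx; attr(edges, "gy") <- g$gy; attr(edges, "mag") <- mag
    return(edges)
  }
  # non-maximum suppression, gradient direction quantized to 4 sectors
  ang <- atan2(g$gy, g$gx) # direction of intensity increase (row, col) space
  sector <- floor(((ang + pi) / (pi / 4)) + 0.5) %% 4
  # sector 0: horizontal gradient (compare left/right columns)
  n1 <- shift_mat(mag, 0, 1);  n2 <- shift_mat(mag, 0, -1)
  d1 <- shift_mat(mag, 1, 1);  d2 <- shift_mat(mag, -1, -1)
  v1 <- shift_mat(mag, 1, 0);  v2 <- shift_mat(mag, -1, 0)
  a1 <- shift_mat(mag, 1, -1); a2 <- shift_mat(mag, -1, 1)
  keep <- (sector == 0 & mag >= n1 & mag >= n2) |
          (sector == 1 & mag >= d1 & mag >= d2) |
          (sector == 2 & mag >= v1 & mag >= v2) |
          (sector == 3 & mag >= a1 & mag >= a2)
  strong <- keep & (mag >= high_frac * mmax)
  weak <- keep & (mag >= low_frac * mmax)
  # hysteresis: keep weak components that touch a strong pixel
  lab <- EBImage::bwlabel(weak)
  strong_labels <- unique(lab[strong])
  strong_labels <- strong_labels[strong_labels > 0]
  edges <- matrix(lab %in% strong_labels, nrow(image), ncol(image))
  attr(edges, "gx") <- g$gx
  attr(edges, "gy") <- g$gy
  attr(edges, "mag") <- mag
  edges
}

bilinear_at <- function(m, r, c) {
  nr <- nrow(m); nc <- ncol(m)
  r <- pmin(pmax(r, 1), nr); c <- pmin(pmax(c, 1), nc)
  r0 <- pmin(floor(r), nr - 1); c0 <- pmin(floor(c), nc - 1)
  fr <- r - r0; fc <- c - c0
  m[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    m[cbind(r0 + 1, c0)] * fr * (1 - fc) +
    m[cbind(r0, c0 + 1)] * (1 - fr) * fc +
    m[cbind(r0 + 1, c0 + 1)] * fr * fc
}

# Parabolic sub-pixel refinement of edge positions across the gradient normal.
# Returns refined (row, col) positions for the given integer edge pixels.
subpixel_refine <- function(edge_rc, gx, gy, mag) {
  gxv <- gx[edge_rc]; gyv <- gy[edge_rc]
  gm <- sqrt(gxv^2 + gyv^2)
  gm[gm == 0] <- 1
  # gradient direction in (row, col) space: col step = gx, row step = gy
  dc <- gxv / gm; dr <- gyv / gm
  r <- edge_rc[, 1]; c <- edge_rc[, 2]
  m0 <- mag[edge_rc]
  mp <- bilinear_at(mag, r + dr, c + dc)
  mm <- bilinear_at(mag, r - dr, c - dc)
  denom <- mm - 2 * m0 + mp
  delta <- ifelse(abs(denom) > 1e-12, 0.5 * (mm - mp) / denom, 0)
  delta <- pmin(pmax(delta, -0.5), 0.5)
  cbind(row = r + delta * dr, col = c + delta * dc)
}

#' Link a Canny edge map into ordered contours (detector mm)
#'
#' 8-connected edge chains are ordered into polylines, refined to sub-pixel
#' accuracy across the edge normal (parabolic fit of the gradient magnitude),
#' and converted from pixels to detector-plane mm. Chains shorter than
#' `min_length` pixels are dropped. Contours are returned sorted by enclosed
#' area (largest first).
#'
#' @param edge_map output of [canny_edge_map()]
#' @param geometry an [imaging_geometry()]
#' @param min_length minimum chain length in pixels
#' @param subpixel apply sub-pixel refinement (default TRUE)
#' @return list of [contour2d()] objects
#' @export
link_edges_to_contours <- function(edge_map, geometry, min_length = 10,
                                   subpixel = TRUE) {
  nr <- nrow(edge_map); nc <- ncol(edge_map)
  idx <- which(edge_map)
  if (length(idx) == 0) return(list())
  rows <- ((idx - 1) %% nr) + 1
  cols <- ((idx - 1) %/% nr) + 1
  id <- matrix(0L, nr, nc)
  id[idx] <- seq_along(idx)
  off <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
               dc = c(-1, 0, 1, -1, 1, -1, 0, 1))
  neighbors <- function(k) {
    r <- rows[k] + off[, 1]; c <- cols[k] + off[, 2]
    ok <- r >= 1 & r <= nr & c >= 1 & c <= nc
    n <- id[cbind(r[ok], c[ok])]
    n[n > 0]
  }
  deg <- vapply(seq_along(idx), function(k) length(neighbors(k)), integer(1))
  visited <- logical(length(idx))
  chains <- list()
  trace_from <- function(start) {
    chain <- integer(0)
    cur <- start
    prev <- 0L
    repeat {
      visited[cur] <<- TRUE
      chain <- c(chain, cur)
      nb <- neighbors(cur)
      nb <- nb[!visited[nb]]
      if (length(nb) == 0) break
      if (length(nb) > 1) {
        # prefer 4-connected continuation for a clean ordering
        d4 <- abs(rows[nb] - rows[cur]) + abs(cols[nb] - cols[cur])
        nb <- nb[order(d4)]
      }
      prev <- cur
      cur <- nb[1]
    }
    chain
  }
  # open chains first (endpoints), then remaining loops
  for (start in c(which(deg == 1), seq_along(idx))) {
    if (visited[start]) next
    ch <- trace_from(start)
    if (length(ch) >= 2) chains[[length(chains) + 1]] <- ch
  }
  # merge chains whose endpoints meet: junctions and 1-px NMS gaps split a
  # single silhouette ring into several runs; distinct components sit many
  # pixels apart and are never bridged by this threshold
  gap <- 2.5
  endpts <- function(ch) rbind(c(rows[ch[1]], cols[ch[1]]),
                               c(rows[ch[length(ch)]], cols[ch[length(ch)]]))
  repeat {
    merged <- FALSE
    if (length(chains) >= 2) {
      for (i in seq_along(chains)) {
        for (j in seq_along(chains)) {
          if (i == j) next
          ei <- endpts(chains[[i]]); ej <- endpts(chains[[j]])
          d <- c(tt = sqrt(sum((ei[2, ] - ej[1, ])^2)),  # tail_i -> head_j
                 th = sqrt(sum((ei[2, ] - ej[2, ])^2)),  # tail_i -> tail_j
                 hh = sqrt(sum((ei[1, ] - ej[1, ])^2)))  # head_i -> head_j
          if (min(d) > gap) next
          cj <- chains[[j]]
          chains[[i]] <- switch(names(which.min(d)),
                                tt = c(chains[[i]], cj),
                                th = c(chains[[i]], rev(cj)),
                                hh = c(rev(cj), chains[[i]]))
          chains[[j]] <- NULL
          merged <- TRUE
          break
        }
        if (merged) break
      }
    }
    if (!merged) break
  }
  chains <- Filter(function(ch) length(ch) >= min_length, chains)
  if (length(chains) == 0) return(list())
  gx <- attr(edge_map, "gx"); gy <- attr(edge_map, "gy"); mag <- attr(edge_map, "mag")
  out <- lapply(chains, function(ch) {
    rc <- cbind(rows[ch], cols[ch])
    # closed if the endpoints (nearly) meet, within the junction-gap scale
    closed <- length(ch) >= 3 &&
      sqrt(sum((rc[1, ] - rc[nrow(rc), ])^2)) <= gap
    if (subpixel && !is.null(mag)) rc <- subpixel_refine(rc, gx, gy, mag)
    contour2d(detector_px_to_mm(geometry, rc), closed = closed)
  })
  areas <- vapply(out, function(cc) abs(contour_area(cc)), numeric(1))
  out[order(areas, decreasing = TRUE)]
}

#' Select the contour belonging to one implant component
#'
#' Replaces the interactive step of clinical software: given a hint (a seed
#' point or a rectangle in detector mm, typically stored in the scene
#' configuration), returns the contour with the greatest arc length inside
#' the hint region. Ties are broken by centroid distance to the hint centre,
#' then by contour index (lowest wins).
#'
#' @param contours list of [contour2d()] (e.g. from
#'   [link_edges_to_contours()])
#' @param hint_region either `c(u, v)` (a seed point, a 20 mm box around it is
#'   used) or `c(umin, umax, vmin, vmax)` in detector mm
#' @param halfwidth half-width of the box grown around a seed-point hint (mm)
#' @return the selected [contour2d()]
#' @export
select_component_contour <- function(contours, hint_region, halfwidth = 15) {
  if (length(hint_region) == 2) {
    rect <- c(hint_region[1] - halfwidth, hint_region[1] + halfwidth,
              hint_region[2] - halfwidth, hint_region[2] + halfwidth)
  } else if (length(hint_region) == 4) {
    rect <- hint_region
  } else stopf("hint_region must be c(u, v) or c(umin, umax, vmin, vmax)")
  centre <- c(mean(rect[1:2]), mean(rect[3:4]))
  arc_in <- vapply(contours, function(cc) {
    p <- unclass(cc)
    inside <- p[, 1] >= rect[1] & p[, 1] <= rect[2] &
              p[, 2] >= rect[3] & p[, 2] <= rect[4]
    if (sum(inside) < 2) return(0)
    seg <- sqrt(rowSums(diff(p)^2))
    sum(seg[inside[-length(inside)] & inside[-1]])
  }, numeric(1))
  if (all(arc_in <= 0)) stopf("no contour intersects the hint region")
  best <- which(arc_in == max(arc_in))
  if (length(best) > 1) {
    cd <- vapply(best, function(i)
      sum((colMeans(unclass(contours[[i]])) - centre)^2), numeric(1))
    best <- best[order(cd, best)] # centroid distance, then lowest index
  }
  contours[[best[1]]]
}

#' Export contours as CSV (contour_id, point_index, u_mm, v_mm)
#' @param contours list of [contour2d()]
#' @param path output CSV path
#' @export
write_contours_csv <- function(contours, path) {
  df <- do.call(rbind, lapply(seq_along(contours), function(i) {
    p <- unclass(contours[[i]])
    data.frame(contour_id = i, point_index = seq_len(nrow(p)),
               u_mm = p[, 1], v_mm = p[, 2])
  }))
  write.csv(df, path, row.names = FALSE)
  invisible(df)
}
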