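# Single-plane 2D-to-3D pose registration: the pose of a surface model is
# estimated by minimizing the symmetric nearest-neighbour distance between
# the implant contour detected in the radiograph and the model's projected
# silhouette contour, using a downhill simplex with simulated annealing
# acceptance (difference-minimization, Press-style thermal fluctuations,
# geometric cooling, structured restarts). The optimizer minimizes the RMS
# distance; the reported residual is the mean-distance metric.

contour_segments <- function(points, closed = TRUE) {
  p <- unclass(points)
  n <- nrow(p)
  if (closed) {
    cbind(p[, 1], p[, 2], p[c(2:n, 1), 1], p[c(2:n, 1), 2])
  } else {
    cbind(p[-n, 1], p[-n, 2], p[-1, 1], p[-1, 2])
  }
}

#' Symmetric contour difference (mm, object scale)
#'
#' Symmetric mean nearest-neighbour point-to-polyline distance between two
#' contours in detector mm, divided by the magnification (`sdd / object z`)
#' so the value is comparable across imaging geometries and directly
#' interpretable at the scale of the implant. Zero iff the contours coincide
#' as point sets. Invariant under re-ordering of contour points.
#'
#' @param model_contour,image_contour [contour2d()] objects (or n x 2
#'   matrices, assumed closed)
#' @param magnification projective magnification `sdd / z` of the object
#'   plane (> 0); use 1 for a raw detector-plane distance
#' @return mean contour difference in mm at object scale
#' @export
contour_cost <- function(model_contour, image_contour, magnification = 1) {
  if (magnification <= 0) stopf("magnification must be > 0")
  a <- rbind(unclass(model_contour))
  b <- rbind(unclass(image_contour))
  if (nrow(a) < 2 || nrow(b) < 2) stopf("degenerate contour: need >= 2 points")
  sa <- contour_segments(a, isTRUE(attr(model_contour, "closed") %||% TRUE))
  sb <- contour_segments(b, isTRUE(attr(image_contour, "closed") %||% TRUE))
  d_ab <- mean(cpp_points_to_segments(a, sb))
  d_ba <- mean(cpp_points_to_segments(b, sa))
  (d_ab + d_ba) / 2 / magnification
}

#' Registration optimizer configuration
#'
#' @param seed integer seed (all stochastic steps derive from it)
#' @param temp0 initial annealing temperature, in cost units (mm)
#' @param cooling geometric cooling factor, `T <- cooling * T`
#' @param temp_steps number of cooling steps
#' @param iters_per_temp simplex iterations at each temperature
#' @param restarts maximum restarts (alternating re-exploration around the
#'   initial pose and polish around the incumbent best); restarts stop early
#'   once a converged fit reaches `good_enough`
#' @param tol convergence tolerance on the cost (mm)
#' @param simplex_scale initial simplex edge (mm for translations, degrees
#'   for rotations; the parameter scaling makes one shared scale reasonable)
#' @param supersample subsamples per cost-raster cell edge
#' @param grid_scale cost raster resolution, in cells per detector pixel
#' @param cost_points contour points subsampled per side for the cost
#' @param max_eval hard cap on cost evaluations
#' @param good_enough RMS contour distance (mm, object scale) below which
#'   further restarts are skipped: a converged fit at the raster/noise floor
#'   cannot be improved by re-exploration
#' @export
reg_config <- function(seed = 1, temp0 = 0.05, cooling = 0.9, temp_steps = 50,
                       iters_per_temp = 4, restarts = 5, tol = 1e-3,
                       simplex_scale = 1.0, supersample = 3, grid_scale = 1,
                       cost_points = 350, max_eval = 4000, good_enough = 0.05) {
  as.list(environment())
}

# Projected silhouette contour(s) of a posed mesh on a local raster covering
# the projection; returns list(points = subsampled boundary points,
# segments = polyline segments) in detector mm, or NULL if degenerate.
model_contour_local <- function(V, faces, params, geometry, config) {
  pose <- rigid_transform(params[1], params[2], params[3],
                          params[4], params[5], params[6])
  W <- transform_points(V, pose)
  z <- W[, 3]
  if (any(z <= 1) || any(z >= geometry$sdd - 1)) return(NULL)
  P <- project_points(geometry, W)
  pitch <- geometry$pixel_pitch / config$grid_scale
  margin <- 3 * pitch
  u0 <- min(P[, 1]) - margin
  v0 <- max(P[, 2]) + margin
  nc <- ceiling((max(P[, 1]) + margin - u0) / pitch) + 1
  nr <- ceiling((v0 - (min(P[, 2]) - margin)) / pitch) + 1
  if (nr < 2 || nc < 2 || nr * nc > 4e7) return(NULL)
  cov <- cpp_render_coverage(P, faces, u0, v0, pitch, as.integer(nr),
                             as.integer(nc), as.integer(config$supersample))
  loops <- cpp_marching_squares(cov, 0.5, u0, v0, pitch)
  loops <- Filter(function(l) nrow(l) >= 3, loops)
  if (length(loops) == 0) return(NULL)
  pts <- do.call(rbind, loops)
  # chord-subsampled polylines keep the cost O(cost_points^2); chord error on
  # the smooth silhouettes is far below the raster resolution
  total <- nrow(pts)
  segs <- do.call(rbind, lapply(loops, function(l) {
    k <- max(3, ceiling(2 * config$cost_points * nrow(l) / total))
    contour_segments(subsample_rows(l, k), isTRUE(attr(l, "closed")))
  }))
  list(points = pts, segments = segs)
}

subsample_rows <- function(m, k) {
  n <- nrow(m)
  if (n <= k) return(m)
  m[round(seq(1, n, length.out = k)), , drop = FALSE]
}

#' Registration result
#'
#' @param pose estimated [rigid_transform()]
#' @param final_residual contour difference at the optimum (mm, object scale)
#' @param iterations cost evaluations used
#' @param converged logical; `FALSE` flags non-convergence (never silent)
#' @param seed the seed used
#' @keywords internal
registration_result <- function(pose, final_residual, iterations, converged,
                                seed, history = NULL) {
  structure(list(pose = pose, final_residual = final_residual,
                 iterations = iterations, converged = converged, seed = seed,
                 history = history),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("registration_result: residual %.4f mm (object scale), %d evaluations, %s\n",
              x$final_residual, x$iterations,
              if (x$converged) "converged" else "NOT converged"))
  print(x$pose)
  invisible(x)
}

# Nelder-Mead with simulated-annealing acceptance (thermal fluctuations on
# the stored costs, Press style). At T = 0 this is plain deterministic
# Nelder-Mead. fn must return a finite cost (large penalty for invalid poses).
anneal_simplex <- function(fn, p0, scales, temp0, cooling, temp_steps,
                           iters_per_temp, tol, max_eval) {
  n <- length(p0)
  evals <- 0L
  EV <- function(p) { evals <<- evals + 1L; fn(p) }
  simplex <- matrix(rep(p0, n + 1), n + 1, n, byrow = TRUE)
  for (i in seq_len(n)) simplex[i + 1, i] <- simplex[i + 1, i] + scales[i]
  y <- apply(simplex, 1, EV)
  Tt <- temp0
  best_p <- simplex[which.min(y), ]
  best_y <- min(y)
  fluct <- function(k, T) if (T > 0) -T * log(runif(k)) else numeric(k)
  schedule <- c(rep(Tt * cooling^(seq_len(temp_steps) - 1), each = iters_per_temp),
                rep(0, 10 * n * iters_per_temp))
  converged <- FALSE
  last_span <- Inf
  for (T in schedule) {
    if (evals >= max_eval) break
    yt <- y + fluct(n + 1, T)
    o <- order(yt)
    simplex <- simplex[o, , drop = FALSE]
    y <- y[o]
    yt <- yt[o]
    span <- abs(y[n + 1] - y[1])
    if (T == 0 && span < tol) {
      converged <- TRUE
      break
    }
    last_span <- span
    centroid <- colMeans(simplex[1:n, , drop = FALSE])
    # reflection
    pr <- centroid + (centroid - simplex[n + 1, ])
    yr <- EV(pr)
    yrt <- yr - fluct(1, T)
    if (yr < best_y) { best_y <- yr; best_p <- pr }
    if (yrt < yt[1]) {
      # expansion
      pe <- centroid + 2 * (centroid - simplex[n + 1, ])
      ye <- EV(pe)
      yet <- ye - fluct(1, T)
      if (ye < best_y) { best_y <- ye; best_p <- pe }
      if (yet < yrt) {
        simplex[n + 1, ] <- pe; y[n + 1] <- ye
      } else {
        simplex[n + 1, ] <- pr; y[n + 1] <- yr
      }
    } else if (yrt < yt[n]) {
      simplex[n + 1, ] <- pr; y[n + 1] <- yr
    } else {
      # contraction
      pc <- centroid + 0.5 * (simplex[n + 1, ] - centroid)
      yc <- EV(pc)
      yct <- yc - fluct(1, T)
      if (yc < best_y) { best_y <- yc; best_p <- pc }
      if (yct < yt[n + 1]) {
        simplex[n + 1, ] <- pc; y[n + 1] <- yc
      } else {
        # shrink toward best vertex
        for (i in 2:(n + 1)) {
          simplex[i, ] <- simplex[1, ] + 0.5 * (simplex[i, ] - simplex[1, ])
          y[i] <- EV(simplex[i, ])
          if (y[i] < best_y) { best_y <- y[i]; best_p <- simplex[i, ] }
        }
      }
    }
  }
  if (y[which.min(y)] < best_y) {
    best_y <- min(y)
    best_p <- simplex[which.min(y), ]
  }
  list(par = best_p, value = best_y, evals = evals, converged = converged)
}

#' Register a component's 6-DOF pose to an image contour
#'
#' Minimizes [contour_cost()] between the contour detected in the radiograph
#' and the posed model's projected silhouette contour. The optimizer is a
#' downhill simplex with simulated-annealing acceptance: simplex moves that
#' worsen the cost are accepted with probability `exp(-dE/T)`, the
#' temperature cools geometrically, and the search restarts from the
#' perturbed best vertex. Deterministic for a fixed seed. The initial pose
#' must lie within the capture range (about +/- 10 mm in-plane, +/- 10
#' degrees for phantom scenes).
#'
#' @param mesh the component's [triangle_mesh()] (model frame)
#' @param image_contour [contour2d()] of the component in the radiograph
#' @param geometry the [imaging_geometry()]
#' @param init_pose initial [rigid_transform()]
#' @param opt_config a [reg_config()]
#' @param fixed character vector of pose parameters frozen at their initial
#'   value, from `c("tx","ty","tz","rx","ry","rz")`. Defaults to `"tz"`:
#'   out-of-plane translation is weakly observable from one view and the
#'   protocol assumes the source-knee-detector distances are known.
#' @return a `registration_result`; `converged = FALSE` flags residual
#'   stagnation above tolerance after all restarts (never silent)
#' @export
register_pose <- function(mesh, image_contour, geometry, init_pose,
                          opt_config = reg_config(), fixed = "tz") {
  par_names <- c("tx", "ty", "tz", "rx", "ry", "rz")
  if (!all(fixed %in% par_names)) stopf("fixed must be pose parameter names")
  free <- setdiff(par_names, fixed)
  free_i <- match(free, par_names)
  p_full <- c(init_pose$translation, init_pose$rotation)
  img_pts <- subsample_rows(rbind(unclass(image_contour)), opt_config$cost_points)
  img_segs <- contour_segments(
    subsample_rows(rbind(unclass(image_contour)), 2 * opt_config$cost_points),
    isTRUE(attr(image_contour, "closed") %||% TRUE))
  V <- mesh$vertices
  faces <- mesh$faces
  # The optimizer minimizes the ROOT-MEAN-SQUARE symmetric contour distance:
  # short but pose-critical silhouette features (fixation pegs, side walls)
  # occupy little arc length, and under a plain mean their mismatch can be
  # traded away against a tilt of the whole component; squaring restores
  # their leverage. The reported final residual remains the mean-distance
  # metric of contour_cost().
  cost_of <- function(pfree) {
    p <- p_full
    p[free_i] <- pfree
    mc <- model_contour_local(V, faces, p, geometry, opt_config)
    if (is.null(mc)) return(1e6)
    mag <- geometry$sdd / p[3]
    mpts <- subsample_rows(mc$points, opt_config$cost_points)
    d1 <- cpp_points_to_segments(img_pts, mc$segments)
    d2 <- cpp_points_to_segments(mpts, img_segs)
    sqrt((mean(d1^2) + mean(d2^2)) / 2) / mag
  }
  scales <- rep(opt_config$simplex_scale, length(free_i))
  total_evals <- 0L
  with_seed(opt_config$seed, {
    p_init <- p_full[free_i]
    best <- NULL
    converged <- FALSE
    # Structured restart starts: the single-view cost surface can hold
    # shallow false basins a few degrees away along the weakly observable
    # out-of-plane rotations (e.g. plate tilt trading against vertical
    # shift), so after the plain run the search restarts from the initial
    # pose offset by +/- 2.5 degrees on each free out-of-plane rotation.
    # Restarts stop as soon as a converged fit reaches the raster-noise
    # floor (`good_enough`); clean fits therefore cost a single run.
    offsets <- list(numeric(length(free_i)))
    for (ax in intersect(c("rx", "ry"), free)) {
      for (s in c(-2.5, 2.5)) {
        o <- numeric(length(free_i))
        o[match(ax, free)] <- s
        offsets[[length(offsets) + 1]] <- o
      }
    }
    n_runs <- min(length(offsets), opt_config$restarts + 1)
    for (r in seq_len(n_runs)) {
      p0 <- p_init + offsets[[r]]
      res <- anneal_simplex(cost_of, p0, scales, opt_config$temp0,
                            opt_config$cooling, opt_config$temp_steps,
                            opt_config$iters_per_temp, opt_config$tol,
                            opt_config$max_eval)
      total_evals <- total_evals + res$evals
      if (is.null(best) || res$value < best$value) {
        best <- res
        converged <- res$converged
      }
      if (converged && best$value < opt_config$good_enough) break
    }
    # final polish from the incumbent best on a cooled schedule
    if (best$value >= opt_config$good_enough || !converged) {
      res <- anneal_simplex(cost_of, best$par, scales * 0.5,
                            opt_config$temp0 * 0.25, opt_config$cooling,
                            opt_config$temp_steps, opt_config$iters_per_temp,
                            opt_config$tol, opt_config$max_eval)
      total_evals <- total_evals + res$evals
      if (res$value < best$value) {
        best <- res
        converged <- res$converged
      }
    }
    p_hat <- p_full
    p_hat[free_i] <- best$par
    pose <- rigid_transform(p_hat[1], p_hat[2], p_hat[3],
                            p_hat[4], p_hat[5], p_hat[6])
    # final residual with the full (non-subsampled) symmetric cost
    full_cfg <- opt_config
    full_cfg$cost_points <- .Machine$integer.max / 4
    mc <- model_contour_local(V, faces, p_hat, geometry, full_cfg)
    resid <- if (is.null(mc)) best$value else {
      mag <- geometry$sdd / p_hat[3]
      img_full <- rbind(unclass(image_contour))
      segs_full <- contour_segments(img_full,
                                    isTRUE(attr(image_contour, "closed") %||% TRUE))
      d1 <- mean(cpp_points_to_segments(img_full, mc$segments))
      d2 <- mean(cpp_points_to_segments(mc$points, segs_full))
      (d1 + d2) / 2 / mag
    }
    registration_result(pose, resid, total_evals, converged, opt_config$seed)
  })
}
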