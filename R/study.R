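# End-to-end study runner: generate (or reuse) the synthetic dataset,
# extract contours, register both components in every scene, measure mJSW
# and wear, and run the validation statistics.

#' Run the full model-based wear measurement study
#'
#' Pipeline: generate-dataset (skipped when `dataset` is supplied) ->
#' extract contours -> register femur and tray in every scene -> measure
#' per-condyle mJSW -> linear wear -> statistics. Initial poses emulate the
#' operator's rough manual alignment: the true pose perturbed by up to
#' `perturb` (in-plane translation mm, rotation degrees), seeded. Every
#' random draw derives from the master seed, so a rerun reproduces the
#' report bit for bit.
#'
#' @param config a [scenario_config()]
#' @param dataset optional pre-generated `phantom_dataset` (resume support)
#' @param seed master seed; defaults to the config's
#' @param doubles re-register every radiograph a second time with an
#'   independent seed (the "double experiment" giving the precision /
#'   Bland-Altman statistics)
#' @param perturb `c(translation mm, rotation deg)` bounds of the seeded
#'   initial-pose offset
#' @param opt a [reg_config()] template (its seed is re-derived per scene)
#' @param tray_fixed pose parameters frozen for the tibial-tray registration
#'   (default: the beam-axis translation, as for the femur)
#' @param allow_nonconverged continue into the statistics stage even if a
#'   registration did not converge
#' @param out_dir optional directory for `study_table.csv`, `report.json`
#'   and figures
#' @param verbose print per-scene progress
#' @return an object of class `mbwm_study`
#' @export
run_study <- function(config = scenario_config(), dataset = NULL,
                      seed = config$seed, doubles = FALSE,
                      perturb = c(2, 2), opt = reg_config(),
                      tray_fixed = "tz",
                      allow_nonconverged = FALSE, out_dir = NULL,
                      verbose = FALSE) {
  t0 <- Sys.time()
  if (is.null(dataset)) {
    config$seed <- seed
    dataset <- generate_dataset(config, verbose = verbose)
  } else {
    config <- dataset$config
  }
  geometry <- config$geometry
  rows <- list()
  regs <- list()
  k <- 0L
  for (sc in dataset$scenes) {
    k <- k + 1L
    if (verbose) message("scene ", sc$scene_id)
    edges <- canny_edge_map(sc$radiograph$pixels)
    contours <- link_edges_to_contours(edges, geometry, min_length = 30)
    femur_contour <- select_component_contour(contours, sc$meta$hint_femur)
    tray_contour <- select_component_contour(contours, sc$meta$hint_tray)
    truth <- dataset$truth[dataset$truth$scene_id == sc$scene_id, ]
    for (rep_i in seq_len(if (doubles) 2L else 1L)) {
      reg_seed <- derive_seed(seed, 1000L * rep_i + k)
      init <- with_seed(reg_seed, {
        d <- runif(2, -perturb[1], perturb[1])
        a <- runif(3, -perturb[2], perturb[2])
        list(femur = perturb_pose(sc$femur_pose, d, a),
             tray = perturb_pose(sc$tray_pose,
                                 runif(2, -perturb[1], perturb[1]),
                                 runif(3, -perturb[2], perturb[2])))
      })
      oc <- opt
      oc$seed <- reg_seed
      reg_f <- register_pose(sc$femur_mesh, femur_contour, geometry,
                             init$femur, oc)
      oc$seed <- reg_seed + 1L
      reg_t <- register_pose(sc$tray_mesh, tray_contour, geometry,
                             init$tray, oc, fixed = tray_fixed)
      regs[[length(regs) + 1]] <- data.frame(
        scene_id = sc$scene_id, replicate = rep_i,
        component = c("femur", "tray"),
        residual_mm = c(reg_f$final_residual, reg_t$final_residual),
        iterations = c(reg_f$iterations, reg_t$iterations),
        converged = c(reg_f$converged, reg_t$converged),
        seed = c(reg_f$seed, reg_t$seed))
      frame <- tibial_frame_from_pose(reg_t$pose)
      meas <- measure_mjsw(sc$femur_mesh, reg_f$pose, frame,
                           rim_height = config$rim_height,
                           scene_id = sc$scene_id, flexion_angle = sc$angle)
      for (cd in c("medial", "lateral")) {
        rows[[length(rows) + 1]] <- data.frame(
          inlay_id = sc$inlay_id, state = sc$state, angle_deg = sc$angle,
          condyle = cd,
          mbwm_mm = if (cd == "medial") meas$mjsw_medial else meas$mjsw_lateral,
          cmm_mm = truth$cmm_mm[truth$condyle == cd],
          true_mjsw_mm = truth$true_mjsw_mm[truth$condyle == cd],
          replicate = rep_i)
      }
    }
  }
  registrations <- do.call(rbind, regs)
  if (!all(registrations$converged)) {
    msg <- sprintf("%d registration(s) did not converge",
                   sum(!registrations$converged))
    if (!allow_nonconverged)
      stopf("%s; statistics stage halted (set allow_nonconverged = TRUE to override)", msg)
    warnf(msg)
  }
  table <- wear_study_table(do.call(rbind, rows))
  report <- accuracy_report(table)
  wt <- linear_wear_table(table)
  wt1 <- wt[wt$replicate == 1L, ]
  # effect of pose (flexion) on accuracy: paired t-tests on the absolute
  # mJSW errors between flexion angles, per condyle
  t1 <- table[table$replicate == 1L, ]
  t1$abs_err <- abs(t1$mbwm_mm - t1$cmm_mm)
  angles <- sort(unique(t1$angle_deg))
  ttests <- list()
  for (cd in unique(t1$condyle)) {
    for (i in seq_along(angles)) for (j in seq_along(angles)) {
      if (j <= i) next
      a <- t1[t1$condyle == cd & t1$angle_deg == angles[i], ]
      b <- t1[t1$condyle == cd & t1$angle_deg == angles[j], ]
      key <- paste(a$inlay_id, a$state)
      b <- b[match(key, paste(b$inlay_id, b$state)), ]
      tt <- paired_t_test(a$abs_err, b$abs_err)
      ttests[[sprintf("%s_%g_vs_%g", cd, angles[i], angles[j])]] <- tt
    }
  }
  wear_groups <- split(abs(wt1$mbwm_wear_mm - wt1$cmm_wear_mm), wt1$angle_deg)
  wear_anova <- if (length(wear_groups) >= 2 && all(lengths(wear_groups) >= 2))
    anova_oneway(wear_groups) else NULL
  precision <- NULL
  if (doubles) {
    precision <- lapply(split(table, table$condyle), function(d) {
      r1 <- d[d$replicate == 1L, ]
      r2 <- d[d$replicate == 2L, ]
      key <- paste(r1$inlay_id, r1$state, r1$angle_deg)
      r2 <- r2[match(key, paste(r2$inlay_id, r2$state, r2$angle_deg)), ]
      bland_altman(r1$mbwm_mm, r2$mbwm_mm)
    })
  }
  no_wear_detected <- all(dataset$truth$imposed_wear_mm == 0) &&
    all(abs(wt1$mbwm_wear_mm) < 0.12)
  out <- structure(list(table = table, wear_table = wt, report = report,
                        registrations = registrations, t_tests = ttests,
                        wear_anova = wear_anova, precision = precision,
                        no_wear_detected = no_wear_detected,
                        config = config, seed = seed,
                        elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
                   class = "mbwm_study")
  if (!is.null(out_dir)) write_study_outputs(out, out_dir)
  out
}

perturb_pose <- function(pose, d_trans, d_rot) {
  rigid_transform(pose$translation[1] + d_trans[1],
                  pose$translation[2] + d_trans[2],
                  pose$translation[3],
                  pose$rotation[1] + d_rot[1],
                  pose$rotation[2] + d_rot[2],
                  pose$rotation[3] + d_rot[3])
}

#' @export
print.mbwm_study <- function(x, ...) {
  cat(sprintf("mbwm_study: %d scenes, %d measurements (seed %d, %.0f s)\n",
              length(unique(x$registrations$scene_id)),
              sum(x$table$replicate == 1L), x$seed, x$elapsed_s))
  cat(sprintf("  registration residuals: %.3f-%.3f mm (object scale), %d/%d converged\n",
              min(x$registrations$residual_mm), max(x$registrations$residual_mm),
              sum(x$registrations$converged), nrow(x$registrations)))
  ov <- x$report$overall
  for (i in seq_len(nrow(ov)))
    cat(sprintf("  mJSW MAE %-7s %.3f +/- %.3f mm (across flexion angles)\n",
                ov$condyle[i], ov$mae[i], ov$sd_mae[i]))
  cat(sprintf("  linear wear MAE %.3f +/- %.3f mm\n",
              x$report$wear_overall$mae, x$report$wear_overall$sd_mae))
  if (!is.null(x$precision)) {
    for (cd in names(x$precision)) {
      p <- x$precision[[cd]]
      cat(sprintf("  precision %-7s mean diff %+.4f mm, 95%% LoA [%.3f, %.3f]\n",
                  cd, p$mean_difference, p$loa_low, p$loa_high))
    }
  }
  if (x$no_wear_detected) cat("  no wear detected (all estimates within the noise floor)\n")
  invisible(x)
}

write_study_outputs <- function(study, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(study$table, file.path(out_dir, "study_table.csv"), row.names = FALSE)
  rep <- list(
    seed = study$seed,
    overall = study$report$overall,
    mjsw = study$report$mjsw,
    mjsw_pooled = study$report$mjsw_pooled,
    wear = study$report$wear,
    wear_overall = study$report$wear_overall,
    registrations = study$registrations,
    t_tests = lapply(study$t_tests, function(t) t[c("t", "df", "p", "defined")]),
    wear_anova = study$wear_anova[c("F", "df1", "df2", "p")],
    precision = lapply(study$precision, function(p)
      p[c("mean_difference", "sd_difference", "loa_low", "loa_high", "n")]),
    no_wear_detected = study$no_wear_detected)
  jsonlite::write_json(rep, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       pretty = TRUE)
  # figures: error boxplots per angle/condyle and Bland-Altman plots
  err <- with(study$table[study$table$replicate == 1L, ],
              data.frame(angle_deg = angle_deg, condyle = condyle,
                         error = mbwm_mm - cmm_mm))
  grDevices::png(file.path(out_dir, "error_boxplot.png"), 800, 600)
  graphics::boxplot(error ~ interaction(condyle, angle_deg), data = err,
                    ylab = "mJSW error (mm)", xlab = "condyle.angle")
  graphics::abline(h = 0, lty = 3)
  grDevices::dev.off()
  if (!is.null(study$precision)) {
    for (cd in names(study$precision)) {
      grDevices::png(file.path(out_dir, sprintf("bland_altman_%s.png", cd)), 700, 500)
      plot(study$precision[[cd]], main = sprintf("Repeatability, %s condyle", cd))
      grDevices::dev.off()
    }
  }
  invisible(out_dir)
}
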