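# Validation statistics for the wear study: measurement error and MAE,
# Bland-Altman limits of agreement, paired t-test, one-way ANOVA and
# profilometric roughness metrics. SD is the sample SD (n - 1) throughout.

#' Measurement error (bias)
#'
#' `mbwm - cmm`, exactly, vectorized. This signed error is the bias surface
#' of the method: negative values mean the model-based measurement
#' underestimates the reference.
#' @param mbwm model-based measurements (mm)
#' @param cmm reference (CMM) measurements (mm)
#' @export
measurement_error <- function(mbwm, cmm) {
  stopifnot(length(mbwm) == length(cmm))
  if (!all(is.finite(mbwm)) || !all(is.finite(cmm))) stopf("inputs must be finite")
  mbwm - cmm
}

#' Mean absolute error
#'
#' MAE = mean of |errors|; the SD reported alongside is the sample SD of the
#' absolute errors.
#' @param errors vector of signed errors (mm)
#' @return list with `mae` and `sd`
#' @export
mean_absolute_error <- function(errors) {
  if (length(errors) == 0) stopf("empty error list")
  a <- abs(errors)
  list(mae = mean(a), sd = if (length(a) > 1) sd(a) else NA_real_)
}

#' Bland-Altman agreement between paired measurements
#'
#' Differences are `second - first`; limits of agreement are
#' `mean +/- 1.96 * SD` (95% LoA), with the sample SD.
#' @param first,second equal-length paired measurement vectors (n >= 2)
#' @return object of class `bland_altman`: `mean_difference`,
#'   `sd_difference`, `loa_low`, `loa_high`, `n`, and the per-pair means and
#'   differences for plotting
#' @export
bland_altman <- function(first, second) {
  if (length(first) != length(second)) stopf("paired lists must have equal length")
  n <- length(first)
  if (n < 2) stopf("need at least 2 pairs")
  d <- second - first
  m <- mean(d)
  s <- sd(d)
  structure(list(mean_difference = m, sd_difference = s,
                 loa_low = m - 1.96 * s, loa_high = m + 1.96 * s, n = n,
                 means = (first + second) / 2, differences = d),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman: mean difference %.4f mm (SD %.4f), 95%% LoA [%.4f, %.4f], n = %d\n",
              x$mean_difference, x$sd_difference, x$loa_low, x$loa_high, x$n))
  invisible(x)
}

#' Bland-Altman plot
#' @param x a [bland_altman()] result
#' @param ... passed to [graphics::plot()]
#' @export
plot.bland_altman <- function(x, ...) {
  graphics::plot(x$means, x$differences,
                 xlab = "Mean of measurements (mm)",
                 ylab = "Difference (mm)", pch = 19, ...)
  graphics::abline(h = x$mean_difference, lwd = 2)
  graphics::abline(h = c(x$loa_low, x$loa_high), lty = 2)
  invisible(x)
}

#' Paired t-test (closed form)
#'
#' `t = mean(d) / (sd(d) / sqrt(n))` on the paired differences
#' `d = second - first`, with `df = n - 1` and a two-sided p-value. All-zero
#' differences give `t = 0, p = 1`; zero-variance non-zero differences leave
#' t undefined and are flagged, never silently dropped.
#' @param first,second paired samples (n >= 2)
#' @return list with `t`, `df`, `p`, `mean_difference`, `sd_difference`,
#'   `defined`
#' @export
paired_t_test <- function(first, second) {
  if (length(first) != length(second)) stopf("paired samples must have equal length")
  n <- length(first)
  if (n < 2) stopf("need at least 2 pairs")
  d <- second - first
  s <- sd(d)
  m <- mean(d)
  if (s == 0) {
    if (m == 0) return(list(t = 0, df = n - 1, p = 1, mean_difference = 0,
                            sd_difference = 0, defined = TRUE))
    return(list(t = NA_real_, df = n - 1, p = NA_real_, mean_difference = m,
                sd_difference = 0, defined = FALSE))
  }
  t <- m / (s / sqrt(n))
  list(t = t, df = n - 1, p = 2 * pt(-abs(t), df = n - 1),
       mean_difference = m, sd_difference = s, defined = TRUE)
}

#' One-way ANOVA (closed form)
#'
#' Classical between/within mean-square ratio `F(k - 1, N - k)`.
#' @param groups list of numeric vectors, >= 2 groups with n >= 2 each
#' @return list with `F`, `df1`, `df2`, `p`, `ss_between`, `ss_within`
#' @export
anova_oneway <- function(groups) {
  if (length(groups) < 2) stopf("need at least 2 groups")
  n_i <- lengths(groups)
  if (any(n_i < 2)) stopf("every group needs n >= 2")
  N <- sum(n_i)
  k <- length(groups)
  all_x <- unlist(groups)
  gm <- mean(all_x)
  means <- vapply(groups, mean, numeric(1))
  ssb <- sum(n_i * (means - gm)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df1 <- k - 1
  df2 <- N - k
  msb <- ssb / df1
  msw <- ssw / df2
  Fv <- if (msw == 0) { if (msb == 0) 0 else Inf } else msb / msw
  p <- if (is.finite(Fv)) pf(Fv, df1, df2, lower.tail = FALSE) else 0
  list(F = Fv, df1 = df1, df2 = df2, p = p, ss_between = ssb, ss_within = ssw)
}

#' Profilometric roughness metrics Ra and Rp
#'
#' Heights are de-trended to their mean line internally. Ra is the mean
#' absolute deviation from the mean line, Rp the maximum peak height above
#' it. A list of patches (the four measurement locations of a profilometry
#' protocol) returns metrics averaged across patches.
#'
#' @param profile numeric vector/matrix of height samples (micrometres), or a
#'   list of such patches
#' @return list with `ra` and `rp` (micrometres)
#' @export
roughness_metrics <- function(profile) {
  if (is.list(profile) && !is.numeric(profile)) {
    per <- lapply(profile, roughness_metrics)
    return(list(ra = mean(vapply(per, `[[`, numeric(1), "ra")),
                rp = mean(vapply(per, `[[`, numeric(1), "rp"))))
  }
  h <- as.numeric(profile)
  if (length(h) < 2) stopf("need >= 2 height samples")
  if (!all(is.finite(h))) stopf("heights must be finite")
  d <- h - mean(h)
  list(ra = mean(abs(d)), rp = max(d))
}

#' Validate and normalize a wear study table
#'
#' The substrate of all statistics: one row per
#' (inlay, state, angle, condyle, replicate) with the model-based (`mbwm_mm`)
#' and reference (`cmm_mm`) measurements.
#' @param table data frame with columns `inlay_id`, `state`, `angle_deg`,
#'   `condyle`, `mbwm_mm`, `cmm_mm` and optionally `replicate`
#' @export
wear_study_table <- function(table) {
  need <- c("inlay_id", "state", "angle_deg", "condyle", "mbwm_mm", "cmm_mm")
  miss <- setdiff(need, names(table))
  if (length(miss) > 0) stopf("missing columns: %s", paste(miss, collapse = ", "))
  if (is.null(table$replicate)) table$replicate <- 1L
  if (!all(is.finite(table$mbwm_mm)) || !all(is.finite(table$cmm_mm)))
    stopf("mbwm_mm and cmm_mm must be finite")
  if (any(table$mbwm_mm <= 0) || any(table$cmm_mm <= 0))
    stopf("mbwm_mm and cmm_mm must be > 0")
  key <- with(table, paste(inlay_id, state, angle_deg, condyle, replicate))
  if (anyDuplicated(key)) stopf("duplicate (inlay, state, angle, condyle, replicate) rows")
  class(table) <- c("wear_study_table", "data.frame")
  table
}

#' Linear-wear table from paired new/worn measurements
#'
#' For every (inlay, angle, condyle, replicate) present in both states,
#' computes linear wear `mjsw_new - mjsw_worn` for the model-based and the
#' reference measurement. A wear row whose state pairing is missing is an
#' error naming the inlay and angle.
#' @param table a [wear_study_table()]
#' @export
linear_wear_table <- function(table) {
  table <- wear_study_table(table)
  new <- table[table$state == "new", ]
  worn <- table[table$state == "worn", ]
  key <- function(d) paste(d$inlay_id, d$angle_deg, d$condyle, d$replicate)
  kn <- key(new); kw <- key(worn)
  unmatched <- setdiff(kw, kn)
  if (length(unmatched) > 0)
    stopf("missing new-state pairing for wear row(s): %s",
          paste(head(unmatched, 3), collapse = "; "))
  m <- match(kw, kn)
  data.frame(inlay_id = worn$inlay_id, angle_deg = worn$angle_deg,
             condyle = worn$condyle, replicate = worn$replicate,
             mbwm_wear_mm = new$mbwm_mm[m] - worn$mbwm_mm,
             cmm_wear_mm = new$cmm_mm[m] - worn$cmm_mm)
}

#' Accuracy report: per-angle/condyle error and MAE tables
#'
#' Reproduces the structure of the validation study's accuracy tables:
#' mJSW measurement error and MAE per flexion angle x condyle, a pooled
#' both-condyle column recomputed from the raw per-measurement errors, overall
#' per-condyle accuracies (mean of the per-angle MAEs across flexion angles),
#' and linear-wear error/MAE per flexion angle pooled over condyles.
#'
#' @param table a [wear_study_table()] containing new and worn states
#' @return list of data frames: `mjsw` (angle x condyle), `mjsw_pooled`
#'   (angle, both condyles), `overall` (per condyle), `wear` (per angle),
#'   `wear_overall`
#' @export
accuracy_report <- function(table) {
  table <- wear_study_table(table)
  t1 <- table[table$replicate == 1L, ]
  err <- measurement_error(t1$mbwm_mm, t1$cmm_mm)
  grp <- interaction(t1$angle_deg, t1$condyle, drop = TRUE)
  rows <- lapply(split(seq_along(err), grp), function(ix) {
    e <- err[ix]
    m <- mean_absolute_error(e)
    data.frame(angle_deg = t1$angle_deg[ix[1]], condyle = t1$condyle[ix[1]],
               n = length(e), mean_error = mean(e),
               sd_error = if (length(e) > 1) sd(e) else NA_real_,
               mae = m$mae, sd_mae = m$sd)
  })
  mjsw <- do.call(rbind, rows)
  mjsw <- mjsw[order(mjsw$angle_deg, mjsw$condyle), ]
  rownames(mjsw) <- NULL
  pooled <- do.call(rbind, lapply(split(seq_along(err), t1$angle_deg), function(ix) {
    m <- mean_absolute_error(err[ix])
    data.frame(angle_deg = t1$angle_deg[ix[1]], n = length(ix),
               mae = m$mae, sd_mae = m$sd)
  }))
  rownames(pooled) <- NULL
  overall <- do.call(rbind, lapply(split(mjsw, mjsw$condyle), function(d) {
    data.frame(condyle = d$condyle[1], mae = mean(d$mae),
               sd_mae = if (nrow(d) > 1) sd(d$mae) else NA_real_)
  }))
  rownames(overall) <- NULL
  wt <- linear_wear_table(table)
  wt1 <- wt[wt$replicate == 1L, ]
  werr <- wt1$mbwm_wear_mm - wt1$cmm_wear_mm
  wear <- do.call(rbind, lapply(split(seq_along(werr), wt1$angle_deg), function(ix) {
    e <- werr[ix]
    m <- mean_absolute_error(e)
    data.frame(angle_deg = wt1$angle_deg[ix[1]], n = length(e),
               mean_error = mean(e), sd_error = if (length(e) > 1) sd(e) else NA_real_,
               mae = m$mae, sd_mae = m$sd)
  }))
  rownames(wear) <- NULL
  wear_overall <- data.frame(mae = mean(wear$mae),
                             sd_mae = if (nrow(wear) > 1) sd(wear$mae) else NA_real_)
  list(mjsw = mjsw, mjsw_pooled = pooled, overall = overall,
       wear = wear, wear_overall = wear_overall)
}

#' Per-angle accuracy table of the physical phantom validation study
#'
#' The published per-flexion-angle accuracy summaries (measurement error and
#' MAE of mJSW per condyle, and MAE of linear wear) of the physical phantom
#' experiment that this package's synthetic study emulates, shipped as a
#' plain-text table. Used to recompute the pooled across-angle accuracies.
#' @return data frame with columns `table`, `angle_deg`, `condyle`,
#'   `mean_error_mm`, `sd_error_mm`, `mae_mm`, `sd_mae_mm`
#' @export
phantom_reference_table <- function() {
  path <- system.file("extdata", "phantom_study_accuracy.csv", package = "mbwm")
  read.csv(path, stringsAsFactors = FALSE)
}
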