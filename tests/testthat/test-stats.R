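test_that("measurement error is the exact signed difference", {
  expect_equal(measurement_error(9.78, 10.00), -0.22)
  expect_equal(measurement_error(7.5, 7.5), 0)
  expect_equal(measurement_error(c(1, 2), c(2, 1)), c(-1, 1))
  expect_error(measurement_error(NA, 1), "finite")
  # grouped bias recovery on a synthetic table with injected bias
  set.seed(8)
  cmm <- runif(60, 9, 15)
  mbwm <- cmm - 0.1 + rnorm(60, 0, 0.02)
  e <- measurement_error(mbwm, cmm)
  expect_lt(abs(mean(e) + 0.1), 0.01)
})

test_that("MAE pools absolute errors with a sample SD", {
  # averaging the three per-angle medial MAEs reproduces the pooled accuracy
  expect_equal(round(mean(c(0.11, 0.21, 0.08)), 2), 0.13)
  m <- mean_absolute_error(c(-0.1, 0.1))
  expect_equal(m$mae, 0.1)
  expect_equal(m$sd, 0)
  z <- mean_absolute_error(rep(0, 5))
  expect_equal(z$mae, 0)
  expect_equal(z$sd, 0)
  expect_error(mean_absolute_error(numeric(0)), "empty")
  # MAE >= |mean error| for any error vector
  set.seed(2)
  for (i in 1:20) {
    e <- rnorm(sample(2:30, 1))
    expect_gte(mean_absolute_error(e)$mae, abs(mean(e)))
  }
})

test_that("Bland-Altman limits of agreement are mean +/- 1.96 sample SD", {
  ident <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unlist(ident[c("mean_difference", "sd_difference",
                              "loa_low", "loa_high")]),
               c(0, 0, 0, 0), ignore_attr = TRUE)
  # hand computation: differences {+0.1, -0.1}
  ba <- bland_altman(c(0, 0), c(0.1, -0.1))
  expect_equal(ba$mean_difference, 0)
  expect_equal(ba$sd_difference, 0.1414214, tolerance = 1e-6)
  expect_equal(ba$loa_high, 0.2771859, tolerance = 1e-6)
  expect_equal(ba$loa_low, -0.2771859, tolerance = 1e-6)
  # swapping the arguments negates the mean and mirrors the limits
  x <- c(10, 11, 12, 13)
  y <- c(10.2, 10.9, 12.1, 13.3)
  b1 <- bland_altman(x, y)
  b2 <- bland_altman(y, x)
  expect_equal(b1$mean_difference, -b2$mean_difference)
  expect_equal(b1$loa_low, -b2$loa_high)
  expect_error(bland_altman(1, 1), "at least 2")
})

test_that("paired t-test matches the closed form and stats::t.test", {
  same <- paired_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  # zero-variance non-zero differences: flagged undefined, never silent
  flat <- paired_t_test(c(0, 0, 0, 0), c(1, 1, 1, 1))
  expect_false(flat$defined)
  expect_true(is.na(flat$t))
  # hand computation: d = {0.2, 0.1, 0.3} -> t = 0.2 / (0.1 / sqrt(3))
  h <- paired_t_test(c(0, 0, 0), c(0.2, 0.1, 0.3))
  expect_equal(h$t, 0.2 / (0.1 / sqrt(3)), tolerance = 1e-9)
  expect_equal(h$df, 2)
  expect_equal(h$p, 2 * pt(-h$t, 2), tolerance = 1e-12)
  # independent route: stats::t.test on random pairs
  set.seed(3)
  for (i in 1:10) {
    a <- rnorm(8)
    b <- rnorm(8, 0.3)
    ours <- paired_t_test(a, b)
    ref <- t.test(b, a, paired = TRUE)
    expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-9)
  }
})

test_that("one-way ANOVA matches the closed form and stats::aov", {
  same <- anova_oneway(list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3)))
  expect_equal(same$F, 0)
  # hand computation: {1,2},{3,4},{5,6} -> SSB 16, SSW 1.5, F = 16 on (2, 3)
  h <- anova_oneway(list(c(1, 2), c(3, 4), c(5, 6)))
  expect_equal(h$ss_between, 16)
  expect_equal(h$ss_within, 1.5)
  expect_equal(h$F, 16)
  expect_equal(c(h$df1, h$df2), c(2, 3))
  expect_equal(h$p, pf(16, 2, 3, lower.tail = FALSE), tolerance = 1e-12)
  # independent route: aov on random groups
  set.seed(4)
  for (i in 1:5) {
    g <- lapply(1:3, function(k) rnorm(6, k * 0.2))
    ours <- anova_oneway(g)
    df <- data.frame(y = unlist(g), grp = factor(rep(1:3, each = 6)))
    ref <- summary(aov(y ~ grp, df))[[1]]
    expect_equal(ours$F, ref[["F value"]][1], tolerance = 1e-9)
    expect_equal(ours$p, ref[["Pr(>F)"]][1], tolerance = 1e-9)
  }
  expect_error(anova_oneway(list(1, c(2, 3))), "n >= 2")
  expect_error(anova_oneway(list(c(1, 2))), "2 groups")
})

test_that("roughness metrics follow their profile definitions", {
  flat <- roughness_metrics(rep(3.3, 100))
  expect_equal(flat$ra, 0)
  expect_equal(flat$rp, 0)
  # unit-amplitude sine: Ra -> 2/pi, Rp -> 1
  x <- sin(seq(0, 2 * pi, length.out = 20001)[-1])
  s <- roughness_metrics(x)
  expect_equal(s$ra, 2 / pi, tolerance = 1e-3)
  expect_equal(s$rp, 1, tolerance = 1e-6)
  # de-trending: a constant offset changes nothing
  s2 <- roughness_metrics(x + 100)
  expect_equal(s2$ra, s$ra)
  # patch averaging, as when several locations are probed
  p1 <- c(-0.8, 0.8)
  p2 <- c(-0.9, 0.9)
  both <- roughness_metrics(list(p1, p2))
  expect_equal(both$ra, 0.85)
  expect_error(roughness_metrics(3), ">= 2")
})

test_that("accuracy report reproduces injected errors exactly", {
  grid <- expand.grid(inlay_id = c("i1", "i2"), state = c("new", "worn"),
                      angle_deg = c(0, 30, 60), condyle = c("medial", "lateral"),
                      stringsAsFactors = FALSE)
  grid$cmm_mm <- 12
  # injected error: +0.05 per angle step, negated laterally
  inject <- 0.05 * (grid$angle_deg / 30 + 1) * ifelse(grid$condyle == "medial", 1, -1)
  grid$mbwm_mm <- grid$cmm_mm + inject
  rep <- accuracy_report(grid)
  med0 <- rep$mjsw[rep$mjsw$angle_deg == 0 & rep$mjsw$condyle == "medial", ]
  expect_equal(med0$mean_error, 0.05)
  expect_equal(med0$mae, 0.05)
  expect_equal(med0$sd_error, 0)
  lat60 <- rep$mjsw[rep$mjsw$angle_deg == 60 & rep$mjsw$condyle == "lateral", ]
  expect_equal(lat60$mean_error, -0.15)
  expect_equal(lat60$mae, 0.15)
  # pooled both-condyle column recomputed from raw errors
  expect_equal(rep$mjsw_pooled$mae, c(0.05, 0.10, 0.15))
  # overall per-condyle = mean of per-angle MAEs
  expect_equal(rep$overall$mae[rep$overall$condyle == "medial"],
               mean(c(0.05, 0.10, 0.15)))
  # wear rows: states cancel the injected bias exactly -> zero wear error
  expect_equal(rep$wear$mae, rep(0, 3))
  # missing pairing is an error naming the inlay
  broken <- grid[!(grid$inlay_id == "i1" & grid$state == "new" &
                     grid$angle_deg == 0 & grid$condyle == "medial"), ]
  expect_error(accuracy_report(broken), "i1")
})

test_that("study table validation catches malformed input", {
  tab <- data.frame(inlay_id = "i", state = "new", angle_deg = 0,
                    condyle = "medial", mbwm_mm = 10, cmm_mm = 10)
  expect_s3_class(wear_study_table(tab), "wear_study_table")
  expect_error(wear_study_table(tab[, -5]), "missing columns")
  expect_error(wear_study_table(transform(tab, mbwm_mm = -1)), "> 0")
  expect_error(wear_study_table(rbind(tab, tab)), "duplicate")
})

test_that("the published per-angle accuracy table pools to the reported values", {
  ref <- phantom_reference_table()
  mjsw <- ref[ref$table == "mjsw", ]
  expect_equal(round(mean(mjsw$mae_mm[mjsw$condyle == "medial"]), 2), 0.13)
  expect_equal(round(mean(mjsw$mae_mm[mjsw$condyle == "lateral"]), 2), 0.14)
  wear <- ref[ref$table == "wear", ]
  expect_equal(round(mean(wear$mae_mm), 2), 0.07)
})
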