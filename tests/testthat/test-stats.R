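test_that("group-wise standardization", {
  tab <- data.frame(group = c("a", "a", "b", "b"),
                    age = c(60, 70, 50, 90), moca = c(20, 30, 25, 27))
  z <- standardize_predictors(tab, c("age", "moca"))
  expect_equal(z$age_z, c(-1, 1, -1, 1) / sqrt(2))
  # hand-computed: group b ages 50, 90 -> mean 70, sd 28.284
  expect_equal(z$age_z[3], (50 - 70) / sd(c(50, 90)))
  for (g in c("a", "b")) {
    expect_equal(mean(z$age_z[z$group == g]), 0)
    expect_equal(sd(z$moca_z[z$group == g]), 1)
  }
  tab$age[3:4] <- 55
  expect_error(standardize_predictors(tab, "age"), "age.*'b'")
  zg <- standardize_predictors(tab, "moca", by_group = FALSE)
  expect_equal(mean(zg$moca_z), 0)
})

test_that("log lesion volume is the natural log", {
  expect_equal(log_wmh_volume(1), 0)
  expect_equal(log_wmh_volume(exp(1)), 1)
  v <- c(0.2, 0.5, 3)
  expect_true(all(diff(log_wmh_volume(v)) > 0))
  expect_error(log_wmh_volume(0), "> 0")
})

test_that("distance contrast codes are orthonormal polynomials", {
  cp <- quadratic_contrast()
  expect_equal(dim(cp), c(6L, 2L))
  expect_lt(abs(sum(cp[, 1] * cp[, 2])), 1e-12)
  expect_lt(max(abs(colSums(cp))), 1e-12)
  expect_equal(unname(colSums(cp^2)), c(1, 1))
  # quadratic column symmetric about the middle levels
  expect_equal(unname(cp[, 2]), rev(unname(cp[, 2])))
  # Gram-Schmidt oracle on scores 1..6
  gs <- gram_schmidt_quadratic(6)
  expect_equal(abs(unname(cp[, 1])), abs(unname(gs[, 1])), tolerance = 1e-12)
  expect_equal(abs(unname(cp[, 2])), abs(unname(gs[, 2])), tolerance = 1e-12)
})

test_that("fixed effects equal OLS when random-effect variance is nil", {
  tab <- simulate_roi_table(6, 6, effects = list(
    grand = 80, profile = gradient_profile(80, 90), group_shift = 0.5,
    wmh_interaction = 0, sd_scanner = 0, sd_subject = 0, sd_resid = 1),
    seed = 13)
  f <- suppressWarnings(suppressMessages(fit_distance_group(tab, "GMT2")))
  tab2 <- tab[tab$metric == "GMT2", ]
  tab2$distance <- factor(as.character(tab2$distance_level),
                          levels = c("WMH", "2", "4", "6", "8", "10"))
  contrasts(tab2$distance, how.many = 2) <- quadratic_contrast()
  tab2$group <- factor(tab2$group, levels = c("older_adult", "stroke"))
  tab2 <- standardize_predictors(tab2, c("age", "moca"))
  ols <- lm(mean ~ age_z + moca_z + distance * group, data = tab2)
  b <- coef(f)
  expect_equal(unname(b[names(coef(ols))]), unname(coef(ols)), tolerance = 1e-5)
})

test_that("programmed gradients and interactions are detected", {
  tab <- simulate_roi_table(16, 12, effects = list(
    grand = 80, profile = gradient_profile(80, 95), group_shift = 2,
    wmh_interaction = 0, sd_scanner = 0.4, sd_subject = 1, sd_resid = 0.8),
    metric = "GMT2", seed = 5)
  f <- suppressWarnings(fit_distance_group(tab, "GMT2"))
  dq <- term_row(f, "distance.Q")
  expect_lt(dq$p, 0.05)
  # profile decreasing away from the lesion: positive curvature
  expect_gt(dq$estimate, 0)
  expect_lt(term_row(f, "groupstroke")$p, 0.05)

  # stroke-only WMH deficit: interaction detected
  ti <- simulate_roi_table(14, 12, effects = list(
    grand = 0.12, profile = NULL, group_shift = 0,
    wmh_interaction = -0.03, sd_scanner = 0.002, sd_subject = 0.005,
    sd_resid = 0.004), metric = "MWF", seed = 6)
  fi <- suppressWarnings(fit_distance_group(ti, "MWF"))
  expect_lt(term_row(fi, "distance.Q:groupstroke")$p, 0.05)
})

test_that("distance-group model validates its inputs", {
  tab <- simulate_roi_table(4, 4, seed = 2)
  expect_error(fit_distance_group(tab, "FA"), "no rows")
  t2 <- tab[tab$distance_level != "6", ]
  expect_error(fit_distance_group(t2, "GMT2"), "absent distance levels")
  t3 <- tab[tab$group == "stroke", ]
  expect_error(suppressWarnings(fit_distance_group(t3, "GMT2")))
})

test_that("hemisphere model finds programmed asymmetry and nulls", {
  mk_hemi <- function(offset, seed) {
    tab <- simulate_roi_table(1, 14, effects = list(
      grand = 80, profile = gradient_profile(80, 90), group_shift = 0,
      wmh_interaction = 0, sd_scanner = 0.3, sd_subject = 1, sd_resid = 0.7),
      metric = "GMT2", seed = seed)
    tab <- tab[tab$group == "stroke", ]
    ip <- tab; ip$hemisphere <- "ipsilesional"; ip$mean <- ip$mean + offset
    co <- tab; co$hemisphere <- "contralesional"
    set.seed(seed + 1)
    ip$mean <- ip$mean + rnorm(nrow(ip), 0, 0.3)
    co$mean <- co$mean + rnorm(nrow(co), 0, 0.3)
    rbind(ip, co)
  }
  fh <- suppressWarnings(fit_distance_hemisphere(mk_hemi(1.5, 31), "GMT2"))
  expect_lt(term_row(fh, "hemisphereipsilesional")$p, 0.05)
  expect_gt(term_row(fh, "hemisphereipsilesional")$estimate, 0)
  f0 <- suppressWarnings(fit_distance_hemisphere(mk_hemi(0, 32), "GMT2"))
  expect_gt(term_row(f0, "hemisphereipsilesional")$p, 0.05)
})

test_that("bilateral-stroke subjects are excluded from the hemisphere model", {
  tab <- simulate_roi_table(1, 10, effects = list(
    grand = 80, profile = NULL, group_shift = 0, wmh_interaction = 0,
    sd_scanner = 0.3, sd_subject = 1, sd_resid = 0.7),
    metric = "GMT2", seed = 41)
  tab <- tab[tab$group == "stroke", ]
  tab$hemisphere_of_stroke[tab$subject_id == "sub-002"] <- "bilateral"
  ip <- tab; ip$hemisphere <- "ipsilesional"
  co <- tab; co$hemisphere <- "contralesional"
  both <- rbind(ip, co)
  expect_message(
    f <- suppressWarnings(fit_distance_hemisphere(both, "GMT2")),
    "bilateral")
  expect_false("sub-002" %in%
                 rownames(lme4::ranef(f$model)$subject_id))
})

test_that("lesion-volume model recovers programmed coupling and nulls", {
  set.seed(51)
  tab <- simulate_roi_table(14, 14, effects = list(
    grand = 95, profile = NULL, group_shift = 0, wmh_interaction = 0,
    sd_scanner = 0.3, sd_subject = 0.4, sd_resid = 0.3),
    metric = "GMT2", seed = 51)
  tab$mean <- tab$mean + 3 * log(tab$wmh_volume_ml)
  fv <- suppressWarnings(fit_wmh_volume_model(tab, "GMT2"))
  r <- term_row(fv, "log_wmh_volume_z")
  expect_lt(r$p, 0.05)
  expect_gt(r$estimate, 0)
  # shuffled volumes: null
  tabs <- tab[tab$distance_level == "WMH", ]
  tabs$wmh_volume_ml <- sample(tabs$wmh_volume_ml)
  # duplicate rows rejected
  expect_error(fit_wmh_volume_model(rbind(tabs, tabs), "GMT2"), "duplicate")
})

test_that("Tukey post hoc families have the right size and ordering", {
  tab <- simulate_roi_table(10, 8, effects = list(
    grand = 80, profile = gradient_profile(80, 92), group_shift = 0.5,
    wmh_interaction = 0, sd_scanner = 0.3, sd_subject = 1, sd_resid = 0.8),
    metric = "GMT2", seed = 61)
  f <- suppressWarnings(fit_distance_group(tab, "GMT2"))
  ph <- suppressMessages(tukey_posthoc(f, "distance"))
  expect_equal(nrow(ph), 15) # 6 choose 2
  expect_true(all(ph$p_adj >= ph$p_raw - 1e-12))
  phi <- suppressMessages(tukey_posthoc(f, "interaction"))
  expect_equal(nrow(phi), 15 * 2 + 6)
})

test_that("Tukey adjustment agrees with the studentized-range distribution", {
  tab <- simulate_roi_table(8, 8, effects = list(
    grand = 80, profile = gradient_profile(80, 88), group_shift = 0,
    wmh_interaction = 0, sd_scanner = 0.2, sd_subject = 0.8, sd_resid = 1),
    metric = "GMT2", seed = 71)
  f <- suppressWarnings(fit_distance_group(tab, "GMT2"))
  emm <- emmeans::emmeans(f$model, "distance")
  raw <- as.data.frame(emmeans::contrast(emm, "pairwise", adjust = "none"))
  adj <- as.data.frame(emmeans::contrast(emm, "pairwise", adjust = "tukey"))
  manual <- stats::ptukey(sqrt(2) * abs(raw$t.ratio), nmeans = 6,
                          df = raw$df, lower.tail = FALSE)
  expect_equal(adj$p.value, manual, tolerance = 1e-8)
})

test_that("simulate_roi_table is deterministic and realizes its nulls", {
  t1 <- simulate_roi_table(5, 5, seed = 81)
  t2 <- simulate_roi_table(5, 5, seed = 81)
  expect_identical(t1, t2)
  # programmed null: no distance structure in expectation
  agg <- tapply(t1$mean, t1$distance_level, mean)
  expect_lt(diff(range(agg)), 2)
})
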