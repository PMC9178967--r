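test_that("label volumes are deterministic and respect placement rules", {
  lv1 <- make_label_volume(c(40, 40, 32), c(1, 1, 1), n_deep_wmh = 2,
                           n_pv_wmh = 1, seed = 7)
  lv2 <- make_label_volume(c(40, 40, 32), c(1, 1, 1), n_deep_wmh = 2,
                           n_pv_wmh = 1, seed = 7)
  expect_identical(lv1$labels, lv2$labels)
  lab <- lv1$labels
  expect_true(all(lab %in% 0:6))

  # a periventricular component shares at least one face with the ventricles
  wmh <- array(lab == 5, dim(lab))
  vent <- array(lab == 1, dim(lab))
  expect_true(any(wmh))
  d <- dim(lab)
  face_touch <- FALSE
  idx <- which(wmh, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    for (s in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                   c(0, 0, 1), c(0, 0, -1))) {
      p <- idx[r, ] + s
      if (all(p >= 1) && all(p <= d) && vent[p[1], p[2], p[3]])
        face_touch <- TRUE
    }
  }
  expect_true(face_touch)

  # deep components stay >= 2 mm from ventricular CSF
  cl <- classify_wmh(wmh, vent)
  expect_true("periventricular" %in% cl$class)
  expect_true("deep" %in% cl$class)
  dv <- distance_map_mm(vent, lv1$voxel_size_mm)
  for (k in which(cl$class == "deep"))
    expect_gte(min(dv[cl$component_labels == k]), 2)
})

test_that("zero-lesion volumes and impossible placements", {
  lv0 <- make_label_volume(c(32, 32, 32), n_deep_wmh = 0, n_pv_wmh = 0,
                           seed = 1)
  expect_false(any(lv0$labels == 5))
  expect_error(
    make_label_volume(c(32, 32, 32), n_deep_wmh = 1, n_pv_wmh = 0, seed = 1,
                      wmh_radius_mm = 50),
    "deep WMH blob 1")
  expect_error(make_label_volume(c(20, 40, 40)), "32")
})

test_that("stroke lesions are confined to one hemisphere", {
  for (hemi in c("left", "right")) {
    lv <- make_label_volume(c(40, 40, 32), with_stroke = TRUE, seed = 3,
                            stroke_hemisphere = hemi)
    idx <- which(array(lv$labels == 6, dim(lv$labels)), arr.ind = TRUE)
    expect_gt(nrow(idx), 0)
    if (hemi == "left") expect_lt(max(idx[, 1]), 21)
    else expect_gt(min(idx[, 1]), 20)
  }
})

test_that("painted maps reproduce the programmed profile exactly", {
  lv <- make_label_volume(c(40, 40, 32), n_deep_wmh = 1, n_pv_wmh = 1, seed = 2)
  pg <- gradient_profile(80, 95)
  pm <- gradient_profile(0.8e-3, 1.1e-3)
  gt <- paint_ground_truth(lv, pg, pm, group = "stroke", seed = 2)
  lab <- lv$labels
  wmh <- array(lab == 5, dim(lab))
  d <- distance_map_mm(wmh, lv$voxel_size_mm)
  naw <- lab == 4
  expect_equal(gt$ie_t2_true[naw], profile_value(pg, d[naw]), tolerance = 1e-12)
  expect_equal(gt$md_true[naw], profile_value(pm, d[naw]), tolerance = 1e-12)
  # endpoints: lesion value inside, exact baseline beyond the reach
  expect_true(all(gt$ie_t2_true[wmh] == 95))
  far <- naw & d >= pg$reach_mm
  expect_true(all(gt$ie_t2_true[far] == 80))
  # MWF deficit inside the lesion for the stroke group, flat NAWM
  expect_true(all(gt$mwf_true[naw] == 0.12))
  expect_true(all(gt$mwf_true[wmh] == 0.12 - gt$mwf_wmh_deficit))
  expect_gt(gt$mwf_wmh_deficit, 0)
  # flip field smooth and in range
  brain <- lab > 0
  expect_true(all(gt$flip_angle_true[brain] >= 109 &
                    gt$flip_angle_true[brain] <= 180))
})

test_that("older-adult ground truth has no WMH myelin deficit", {
  lv <- make_label_volume(c(40, 40, 32), seed = 4)
  gt <- paint_ground_truth(lv, group = "older_adult", mwf_wmh_deficit = 0.04,
                           seed = 4)
  wmh <- lv$labels == 5
  naw <- lv$labels == 4
  expect_equal(max(abs(gt$mwf_true[wmh] - unique(gt$mwf_true[naw]))), 0)
})

test_that("profile validation rejects out-of-range lesion values", {
  lv <- make_label_volume(c(32, 32, 32), seed = 5)
  expect_error(paint_ground_truth(lv, gradient_profile(80, 300)), "range")
  expect_error(gradient_profile(80, 95, reach_mm = -1), "reach")
})

test_that("simulated echo trains follow the two-pool forward model", {
  seqp <- sequence_params(32, 10, 1000, 1000)
  # single pool at 180: mono-exponential
  et <- simulate_echo_train(0, 80, 180, seqp, 1, 0)
  expect_lt(max(abs(et$signal - exp(-10 * (1:32) / 80))), 1e-12)
  # two-pool cross-check against the relaxometry EPG basis
  et2 <- simulate_echo_train(0.15, 80, 140, seqp, 1, 0)
  ref <- 0.15 * epg_basis_curve(20, seqp, 140) + 0.85 * epg_basis_curve(80, seqp, 140)
  expect_equal(et2$signal, ref, tolerance = 1e-12)
  expect_error(simulate_echo_train(0.15, 80, 190, seqp), "flip")
  expect_error(simulate_echo_train(1.5, 80, 150, seqp), "mwf")
})

test_that("zero-signal noise is Rayleigh with the nominal scale", {
  set.seed(21)
  seqp <- sequence_params(2000, 10, 1000, 1000)
  et <- simulate_echo_train(0, 80, 180, seqp, s0 = 0, noise_sigma = 2)
  x <- et$signal
  # Rayleigh(sigma): mean sigma*sqrt(pi/2), var (2 - pi/2) sigma^2
  expect_equal(mean(x), 2 * sqrt(pi / 2), tolerance = 0.05)
  expect_equal(var(x), (2 - pi / 2) * 4, tolerance = 0.1)
  ks <- suppressWarnings(stats::ks.test(x, function(q) 1 - exp(-q^2 / (2 * 4))))
  expect_gt(ks$p.value, 0.001)
})

test_that("simulate_dwi validates tensors", {
  sch <- default_scheme()
  expect_error(simulate_dwi(matrix(rnorm(9), 3), sch), "symmetric")
  D <- diag(c(-1, 1, 1)) * 1e-3
  expect_error(simulate_dwi(D, sch), "semi-definite")
})

test_that("a small cohort writes a complete, reproducible bundle", {
  td <- withr::local_tempdir()
  cfg <- cohort_config(shape = c(32L, 32L, 32L), write_truth = FALSE)
  t1 <- simulate_cohort(2, 2, cfg, seed = 9, out_dir = file.path(td, "a"))
  expect_equal(nrow(t1), 4)
  for (id in t1$subject_id) {
    for (f in c("labels.nii.gz", "mwi.nii.gz", "dwi.nii.gz", "dwi.bval",
                "dwi.bvec"))
      expect_true(file.exists(file.path(td, "a", id, f)))
  }
  expect_true(all(t1$wmh_volume_ml[t1$group == "older_adult"] < 10))
  expect_true(all(t1$hemisphere_of_stroke[t1$group == "stroke"] %in%
                    c("left", "right")))
  t2 <- simulate_cohort(2, 2, cfg, seed = 9, out_dir = file.path(td, "b"))
  expect_identical(unname(tools::md5sum(file.path(td, "a", "participants.tsv"))),
                   unname(tools::md5sum(file.path(td, "b", "participants.tsv"))))
})

test_that("stroke-group lesion volumes stochastically dominate older adults", {
  # distributional check on the generator's lesion-volume draws across a
  # 20 + 20 cohort of label volumes (signal synthesis not needed)
  set.seed(31)
  vols <- function(group, n) sapply(seq_len(n), function(i) {
    cfg <- cohort_config()
    min(cfg$wmh_cap_ml, max(0.03, rlnorm(1, cfg$wmh_meanlog[[group]],
                                         cfg$wmh_sdlog[[group]])))
  })
  vo <- vols("older_adult", 20)
  vs <- vols("stroke", 20)
  expect_gt(median(vs), median(vo))
})
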