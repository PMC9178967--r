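test_that("distance maps honor geometry and anisotropy", {
  m <- array(FALSE, c(7, 7, 7)); m[4, 4, 4] <- TRUE
  d <- distance_map_mm(m, c(1, 1, 1))
  expect_equal(d[4, 4, 4], 0)
  expect_equal(d[5, 4, 4], 1)
  expect_equal(d[5, 5, 4], sqrt(2))
  expect_equal(d[5, 5, 5], sqrt(3))
  d3 <- distance_map_mm(m, c(1, 1, 3))
  expect_equal(d3[4, 4, 5], 3)
  expect_equal(d3[5, 4, 5], sqrt(10))
  expect_error(distance_map_mm(array(FALSE, c(5, 5, 5)), c(1, 1, 1)), "empty")
})

test_that("distance and dilation match the brute-force oracle", {
  set.seed(33)
  for (i in 1:6) {
    dims <- c(20, 20, 20)
    sp <- list(c(1, 1, 1), c(0.94, 0.94, 3), c(1, 1.5, 2))[[1 + i %% 3]]
    m <- array(runif(prod(dims)) < 0.02, dims)
    if (!any(m)) m[3, 17, 9] <- TRUE
    d <- distance_map_mm(m, sp)
    b <- brute_edt(m, sp)
    expect_lt(max(abs(d - b)), 1e-9)
    for (r in c(0, 2.5, 6)) {
      expect_identical(dilate_mm(m, r, sp), b <= r + 1e-12)
    }
  }
})

test_that("dilation is monotone and a superset of the mask", {
  m <- array(FALSE, c(15, 15, 15)); m[8, 8, 8] <- TRUE; m[3, 3, 3] <- TRUE
  d1 <- dilate_mm(m, 2, c(1, 1, 1))
  d2 <- dilate_mm(m, 4, c(1, 1, 1))
  expect_identical(dilate_mm(m, 0, c(1, 1, 1)), m)
  expect_true(all(d1[m]))
  expect_true(all(d2[d1]))
})

test_that("rings tile the perilesional shell and honor the boundary rule", {
  dims <- c(25, 25, 25)
  wmh <- array(FALSE, dims); wmh[13, 13, 13] <- TRUE
  nawm <- !wmh
  csf <- array(FALSE, dims)
  rs <- make_rings(wmh, nawm, csf, NULL, c(1, 1, 1))
  # voxel at exactly 2.0 mm belongs to ring 1 (half-open intervals)
  expect_true(rs$rings[["2"]][15, 13, 13])
  expect_false(rs$rings[["4"]][15, 13, 13])
  # union of rings = (10 mm dilation minus WMH) within NAWM
  u <- Reduce(`|`, rs$rings)
  expect_identical(u, dilate_mm(wmh, 10, c(1, 1, 1)) & nawm & !wmh)
  # pairwise disjoint, no ring voxel inside the WMH
  expect_false(any(u & rs$wmh_roi))
  counts <- sapply(rs$rings, sum)
  expect_equal(sum(u), sum(counts))
})

test_that("rings equal the brute-force oracle with CSF/stroke exclusions", {
  for (s in 1:4) {
    dims <- c(20, 20, 20)
    sp <- list(c(1, 1, 1), c(0.94, 0.94, 3))[[1 + s %% 2]]
    expect_rings_match_oracle(random_ring_masks(dims, sp, seed = 100 + s))
  }
})

test_that("no retained voxel sits within the exclusion radii", {
  m <- random_ring_masks(c(24, 24, 24), c(1, 1, 1), seed = 55)
  rs <- suppressWarnings(make_rings(m$wmh, m$nawm, m$csf, m$stroke, m$sp))
  dcsf <- brute_edt(m$csf, m$sp)
  dstr <- brute_edt(m$stroke, m$sp)
  all_roi <- rs$wmh_roi | Reduce(`|`, rs$rings)
  expect_gt(min(dcsf[all_roi]), 1)
  expect_gt(min(dstr[all_roi]), 10)
})

test_that("make_rings validates inputs", {
  dims <- c(32, 32, 32)
  a <- array(FALSE, dims); a[5, 5, 5] <- TRUE
  expect_error(make_rings(a, a, array(FALSE, dims), NULL, c(1, 1, 1)),
               "disjoint")
  expect_error(make_rings(array(FALSE, dims), a, array(FALSE, dims), NULL,
                          c(1, 1, 1)), "empty WMH")
})

test_that("WMH components are classified by ventricular contact", {
  dims <- c(12, 12, 12)
  vent <- array(FALSE, dims); vent[6, 6, 6] <- TRUE
  wmh <- array(FALSE, dims)
  wmh[7, 6, 6] <- TRUE      # face contact
  wmh[9, 9, 9] <- TRUE      # distant
  cl <- classify_wmh(wmh, vent)
  expect_equal(sort(cl$class), c("deep", "periventricular"))
  # diagonal-only contact counts as periventricular under 26-connectivity
  wmh2 <- array(FALSE, dims); wmh2[7, 7, 7] <- TRUE
  expect_equal(classify_wmh(wmh2, vent)$class, "periventricular")
  # two voxels away on every axis: deep
  wmh3 <- array(FALSE, dims); wmh3[8, 8, 8] <- TRUE
  expect_equal(classify_wmh(wmh3, vent)$class, "deep")
  dm <- deep_wmh_mask(wmh, vent)
  expect_true(dm[9, 9, 9])
  expect_false(dm[7, 6, 6])
})

test_that("WMH volume arithmetic", {
  m <- array(FALSE, c(32, 32, 32)); m[1:10, 1:10, 1:10] <- TRUE
  expect_equal(wmh_volume_ml(m, c(1, 1, 1)), 1.0)
  expect_equal(wmh_volume_ml(array(FALSE, c(5, 5, 5)), c(1, 1, 1)), 0)
  one <- array(FALSE, c(5, 5, 5)); one[1, 1, 1] <- TRUE
  expect_equal(wmh_volume_ml(one, c(0.94, 0.94, 3)), 0.94 * 0.94 * 3 / 1000)
})

test_that("ROI means reproduce constant and programmed-profile maps", {
  dims <- c(25, 25, 25)
  wmh <- array(FALSE, dims); wmh[13, 13, 13] <- TRUE
  nawm <- !wmh
  rs <- make_rings(wmh, nawm, array(FALSE, dims), NULL, c(1, 1, 1))
  subj <- data.frame(subject_id = "s1", group = "older_adult", age = 70,
                     moca = 27, scanner = "A_32echo",
                     hemisphere_of_stroke = "none", wmh_volume_ml = 0.001)
  const <- array(7.5, dims)
  tab <- extract_roi_means(rs, list(FA = const), subj)
  expect_equal(tab$mean, rep(7.5, 6))
  expect_equal(as.character(tab$distance_level), c("WMH", "2", "4", "6", "8", "10"))
  # programmed profile: ring means lie between the profile at ring edges
  pg <- gradient_profile(80, 95, reach_mm = 6, shape = 2)
  d <- distance_map_mm(wmh, c(1, 1, 1))
  prof_map <- array(profile_value(pg, d), dims)
  tp <- extract_roi_means(rs, list(GMT2 = prof_map), subj)
  for (k in 1:5) {
    lo <- profile_value(pg, 2 * k); hi <- profile_value(pg, 2 * (k - 1))
    mean_k <- tp$mean[tp$distance_level == as.character(2 * k)]
    expect_gte(mean_k, lo - 1e-9)
    expect_lte(mean_k, hi + 1e-9)
  }
  # NaN voxels excluded
  nanmap <- const; nanmap[rs$rings[[1]]][1] <- NaN
  nanmap[which(rs$rings[[1]])[1]] <- NaN
  t2 <- extract_roi_means(rs, list(FA = nanmap), subj)
  expect_equal(t2$mean, rep(7.5, 6))
  expect_equal(t2$n_voxels[t2$distance_level == "2"], sum(rs$rings[[1]]) - 1L)
})

test_that("hemisphere split partitions every ROI", {
  dims <- c(24, 24, 24)
  wmh <- array(FALSE, dims); wmh[c(6, 18), 12, 12] <- TRUE
  nawm <- !wmh
  rs <- make_rings(wmh, nawm, array(FALSE, dims), NULL, c(1, 1, 1))
  sp <- split_by_hemisphere(rs, "left")
  for (nm in names(rs$rings)) {
    expect_identical(sp$ipsilesional$rings[[nm]] | sp$contralesional$rings[[nm]],
                     rs$rings[[nm]])
    expect_false(any(sp$ipsilesional$rings[[nm]] & sp$contralesional$rings[[nm]]))
  }
  # left stroke: ipsilesional is the low-index half
  expect_true(all(which(sp$ipsilesional$wmh_roi, arr.ind = TRUE)[, 1] <= 12))
  expect_error(split_by_hemisphere(rs, "bilateral"), "unilateral")
  expect_error(split_by_hemisphere(rs, "none"), "unilateral")
})

test_that("ring sets serialize to coded ROI volumes", {
  dims <- c(24, 24, 24)
  wmh <- array(FALSE, dims); wmh[12, 12, 12] <- TRUE
  rs <- make_rings(wmh, !wmh, array(FALSE, dims), NULL, c(1, 1, 1))
  v <- ring_set_to_volume(rs)
  expect_equal(sort(unique(as.vector(v))), c(0L, 10L, 11L, 12L, 13L, 14L, 15L))
  expect_equal(sum(v == 10L), sum(rs$wmh_roi))
  expect_equal(sum(v == 13L), sum(rs$rings[[3]]))
})
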