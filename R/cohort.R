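#' Cohort simulation settings
#'
#' Defaults define the simulated study conditions: two scanner
#' configurations (32-echo / 10 ms and 48-echo / 8 ms multi-echo trains),
#' a 60-direction b = 700 s/mm^2 diffusion scheme, SNR 200 at the first
#' echo for the multi-echo data, and group-dependent log-normal WMH volume
#' distributions (stroke-like subjects drawn with larger lesions). Lesion
#' tissue parameters scale with log lesion volume; the WMH myelin deficit
#' applies to the stroke group only.
#'
#' @param shape Phantom grid size.
#' @param voxel_size_mm Voxel dimensions, mm.
#' @param scheme A [diffusion_scheme()].
#' @param snr_mwi Named first-echo SNR per scanner configuration.
#' @param snr_dwi SNR of the unweighted diffusion volume.
#' @param wmh_meanlog,wmh_sdlog Named (per group) log-normal parameters of
#'   the target WMH volume, mL.
#' @param wmh_cap_ml Upper cap on simulated lesion volume, mL.
#' @param write_truth Also write ground-truth maps per subject.
#' @return A list of settings for [simulate_cohort()].
#' @export
cohort_config <- function(shape = c(40L, 40L, 32L), voxel_size_mm = c(1, 1, 1),
                          scheme = default_scheme(),
                          snr_mwi = c(A_32echo = 200, B_48echo = 180),
                          snr_dwi = 50,
                          wmh_meanlog = c(older_adult = log(0.15),
                                          stroke = log(0.9)),
                          wmh_sdlog = c(older_adult = 0.7, stroke = 0.7),
                          wmh_cap_ml = 2.5, write_truth = TRUE) {
  list(shape = shape, voxel_size_mm = voxel_size_mm, scheme = scheme,
       snr_mwi = snr_mwi, snr_dwi = snr_dwi, wmh_meanlog = wmh_meanlog,
       wmh_sdlog = wmh_sdlog, wmh_cap_ml = wmh_cap_ml,
       write_truth = write_truth)
}

subject_seed <- function(master_seed, i) {
  as.integer((as.numeric(master_seed) * 1009 + 97 * i) %% 2147483647L)
}

# lesion tissue parameters as a function of lesion severity
# (log lesion volume relative to a 0.3 mL reference)
severity_profiles <- function(v_ml, group) {
  s <- log(v_ml) - log(0.3)
  list(
    gmt2 = gradient_profile(80, min(110, max(85, 95 + 3 * s))),
    md = gradient_profile(0.80e-3, (1.10 + 0.06 * s) * 1e-3),
    fa = gradient_profile(0.45, min(0.40, max(0.22, 0.30 - 0.02 * s))),
    mwf_deficit = if (group == "stroke")
      min(0.105, max(0.005, 0.04 + 0.05 * (log(v_ml) - log(0.5)))) else 0)
}

write_nifti_vol <- function(arr, voxel_size_mm, file, datatype = "float") {
  img <- RNifti::asNifti(arr)
  pd <- RNifti::pixdim(img)
  pd[1:3] <- voxel_size_mm
  RNifti::pixdim(img) <- pd
  RNifti::writeNifti(img, file, datatype = datatype)
  invisible(file)
}

simulate_subject <- function(id, group, scanner, stroke_hemisphere, cfg,
                             seed, dir) {
  set.seed(seed)
  v_target <- min(cfg$wmh_cap_ml,
                  max(0.03, rlnorm(1, cfg$wmh_meanlog[[group]],
                                   cfg$wmh_sdlog[[group]])))
  n_pv <- 1L + (v_target > 0.8)
  # split large lesion loads over more blobs; cap the blob radii so deep
  # blobs always fit between the ventricles and the cortical ribbon
  n_deep <- min(5L, max(1L, as.integer(ceiling(v_target / 0.35))))
  n_blobs <- n_pv + n_deep
  r_raw <- (3 * (v_target / n_blobs) * 1000 / (4 * pi))^(1 / 3) *
    runif(n_blobs, 0.9, 1.1)
  r_mm <- pmax(1.1, pmin(c(rep(4.5, n_pv), rep(3.2, n_deep)), r_raw))
  lv <- make_label_volume(cfg$shape, cfg$voxel_size_mm,
                          n_deep_wmh = n_deep, n_pv_wmh = n_pv,
                          with_stroke = group == "stroke", seed = seed,
                          wmh_radius_mm = r_mm,
                          stroke_hemisphere = if (stroke_hemisphere %in%
                                                  c("left", "right"))
                            stroke_hemisphere else "left")
  v_ml <- wmh_volume_ml(lv$labels == LBL[["wmh"]], lv$voxel_size_mm)
  prof <- severity_profiles(v_ml, group)
  gt <- paint_ground_truth(lv, prof$gmt2, prof$md, prof$fa,
                           group = group, mwf_wmh_deficit = prof$mwf_deficit,
                           seed = seed)

  seqp <- scanner_sequence(scanner)
  lab <- lv$labels
  brain <- lab > 0L
  idx <- which(brain)
  sig <- epg_two_pool_batch_cpp(gt$mwf_true[idx], gt$ie_t2_true[idx],
                                gt$flip_angle_true[idx], 20, seqp$t1_ms,
                                seqp$echo_spacing_ms, seqp$n_echoes)
  # scanner noise is spatially uniform; SNR referenced to the mean NAWM
  # first-echo amplitude
  nawm_i <- lab[idx] == LBL[["nawm"]]
  ref <- if (any(nawm_i)) mean(sig[1, nawm_i]) else mean(sig[1, ])
  sigma_mwi <- ref / cfg$snr_mwi[[scanner]]
  echo4d <- array(0, c(dim(lab), seqp$n_echoes))
  for (e in seq_len(seqp$n_echoes)) {
    vol <- array(0, dim(lab)); vol[idx] <- sig[e, ]
    echo4d[, , , e] <- vol
  }
  echo4d[] <- add_rician(echo4d, sigma_mwi)

  # diffusion signals from axially symmetric tensors matching fa/md truth
  sch <- cfg$scheme
  nv <- length(idx)
  u <- matrix(rnorm(3 * nv), 3)
  u <- sweep(u, 2, sqrt(colSums(u^2)), "/")
  fav <- gt$fa_true[idx]; mdv <- gt$md_true[idx]
  alpha <- fav / sqrt(3 - 2 * fav^2)
  l2 <- mdv * (1 - alpha); dl <- 3 * mdv * alpha
  M2 <- crossprod(u, sch$bvecs)^2                  # nv x n_meas
  Q <- sweep(M2, 1, dl, "*") + matrix(l2, nv, ncol(M2))
  S <- exp(-sweep(Q, 2, sch$bvals, "*"))
  dwi4d <- array(0, c(dim(lab), length(sch$bvals)))
  for (m in seq_along(sch$bvals)) {
    vol <- array(0, dim(lab)); vol[idx] <- S[, m]
    dwi4d[, , , m] <- vol
  }
  dwi4d[] <- add_rician(dwi4d, 1 / cfg$snr_dwi)

  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vs <- lv$voxel_size_mm
  write_nifti_vol(lab, vs, file.path(dir, "labels.nii.gz"), "uint8")
  write_nifti_vol(echo4d, vs, file.path(dir, "mwi.nii.gz"), "float")
  write_nifti_vol(dwi4d, vs, file.path(dir, "dwi.nii.gz"), "float")
  write_bval_bvec(sch, file.path(dir, "dwi.bval"), file.path(dir, "dwi.bvec"))
  if (isTRUE(cfg$write_truth)) {
    for (nm in c("mwf_true", "ie_t2_true", "fa_true", "md_true",
                 "flip_angle_true"))
      write_nifti_vol(gt[[nm]], vs,
                      file.path(dir, paste0("truth_", nm, ".nii.gz")), "float")
  }
  list(wmh_volume_ml = v_ml)
}

#' Simulate a synthetic cohort
#'
#' Generates per-subject phantom volumes (tissue labels, multi-echo and
#' diffusion-weighted NIfTI, FSL-style `bval`/`bvec` gradient tables,
#' ground-truth maps) plus a tab-separated covariate table
#' (`participants.tsv`). Subjects are split across the two scanner
#' configurations; stroke-group subjects carry a single-hemisphere stroke
#' lesion (hemisphere alternating by subject index) and are drawn with
#' larger WMH volumes. Ages are uniform on 45-80 years. All per-subject
#' seeds derive reproducibly from `seed`.
#'
#' @param n_older,n_stroke Group sizes (each >= 1).
#' @param config A [cohort_config()].
#' @param seed Master integer seed.
#' @param out_dir Output directory (one subdirectory per subject).
#' @return Invisibly, the subject covariate data frame.
#' @export
simulate_cohort <- function(n_older, n_stroke, config = cohort_config(),
                            seed = 1L, out_dir) {
  stopifnot(n_older >= 1, n_stroke >= 1)
  groups <- c(rep("older_adult", n_older), rep("stroke", n_stroke))
  n <- length(groups)
  ids <- sprintf("sub-%03d", seq_len(n))
  scanners <- rep_len(c("A_32echo", "B_48echo"), n)
  hemis <- ifelse(groups == "stroke",
                  rep_len(c("left", "right"), n), "none")
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    sseed <- subject_seed(seed, i)
    res <- tryCatch(
      simulate_subject(ids[i], groups[i], scanners[i], hemis[i], config,
                       sseed, file.path(out_dir, ids[i])),
      error = function(e) stop(sprintf("simulate failed for %s: %s", ids[i],
                                       conditionMessage(e)), call. = FALSE))
    set.seed(subject_seed(seed, i + 100000L))
    age <- round(runif(1, 45, 80), 1)
    moca <- if (groups[i] == "stroke") round(rnorm(1, 25, 3))
            else round(rnorm(1, 27, 2))
    rows[[i]] <- data.frame(
      subject_id = ids[i], group = groups[i], age = age,
      moca = max(0L, min(30L, as.integer(moca))), scanner = scanners[i],
      hemisphere_of_stroke = hemis[i],
      wmh_volume_ml = round(res$wmh_volume_ml, 6),
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write.table(tab, file.path(out_dir, "participants.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(tab)
}
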