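RUN_CONFIG_KEYS <- c("seed", "n_older", "n_stroke", "shape", "voxel_size_mm",
                     "snr_mwi", "snr_dwi", "n_bins", "t2_min_ms", "t2_max_ms",
                     "chi2_window", "angle_step_deg", "ring_width_mm",
                     "n_rings", "csf_exclude_mm", "stroke_exclude_mm",
                     "metrics", "deep_only", "hemisphere_split", "out_root",
                     "write_truth")

#' Pipeline run configuration
#'
#' All stages read their parameters from this object; it is serialized
#' alongside the outputs.
#'
#' @param seed Master seed; every stage derives its seeds from it.
#' @param n_older,n_stroke Cohort sizes.
#' @param shape,voxel_size_mm Phantom grid.
#' @param snr_mwi,snr_dwi Noise levels (see [cohort_config()]).
#' @param n_bins,t2_min_ms,t2_max_ms T2 grid settings.
#' @param chi2_window Regularization misfit window.
#' @param angle_step_deg Flip-angle search step, degrees.
#' @param ring_width_mm,n_rings Perilesional ring geometry.
#' @param csf_exclude_mm,stroke_exclude_mm Exclusion radii, mm.
#' @param metrics Outcome maps to analyse.
#' @param deep_only Restrict the WMH ROI to deep (non-periventricular)
#'   components.
#' @param hemisphere_split Also extract per-hemisphere ROI rows and fit
#'   the distance-by-hemisphere model.
#' @param out_root Output directory.
#' @param write_truth Keep ground-truth maps with the cohort.
#' @return A named list of class `run_config`.
#' @export
run_config <- function(seed = 1L, n_older = 4L, n_stroke = 4L,
                       shape = c(40L, 40L, 32L), voxel_size_mm = c(1, 1, 1),
                       snr_mwi = c(A_32echo = 200, B_48echo = 180),
                       snr_dwi = 50, n_bins = 40L, t2_min_ms = 10,
                       t2_max_ms = 2000, chi2_window = c(1.02, 1.025),
                       angle_step_deg = 2, ring_width_mm = 2, n_rings = 5L,
                       csf_exclude_mm = 1, stroke_exclude_mm = 10,
                       metrics = c("FA", "MD", "MWF", "GMT2"),
                       deep_only = FALSE, hemisphere_split = FALSE,
                       out_root = tempfile("penumbra_run_"),
                       write_truth = TRUE) {
  cfg <- mget(RUN_CONFIG_KEYS)
  structure(cfg, class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Unknown keys are rejected (fail-closed).
#'
#' @param path YAML file with `run_config()` fields.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  bad <- setdiff(names(vals), RUN_CONFIG_KEYS)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  for (k in c("snr_mwi")) if (k %in% names(vals)) vals[[k]] <- unlist(vals[[k]])
  do.call(run_config, vals)
}

cfg_grid <- function(cfg) t2_grid(cfg$n_bins, cfg$t2_min_ms, cfg$t2_max_ms)
cfg_angles <- function(cfg) seq(90, 180, by = cfg$angle_step_deg)

subject_dirs <- function(cfg) {
  ids <- sprintf("sub-%03d", seq_len(cfg$n_older + cfg$n_stroke))
  list(ids = ids,
       cohort = file.path(cfg$out_root, "cohort", ids),
       maps = file.path(cfg$out_root, "maps", ids))
}

stage_done <- function(files) length(files) > 0 && all(file.exists(files))

# voxels that can enter the ROI analysis: the WMH plus NAWM within the
# outermost ring edge of the lesion (maps are NA elsewhere)
analysis_mask <- function(lab, cfg) {
  dims <- dim(lab)
  wmh <- array(lab == LBL[["wmh"]], dims)
  nawm <- array(lab == LBL[["nawm"]], dims)
  if (!any(wmh)) return(nawm | wmh)
  reach <- cfg$ring_width_mm * cfg$n_rings
  wmh | (nawm & dilate_mm(wmh, reach, cfg$voxel_size_mm))
}

read_vol <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  attr(arr, "pixdim") <- RNifti::pixdim(img)
  arr
}

#' @rdname run_all
#' @export
stage_simulate <- function(cfg) {
  sd_ <- subject_dirs(cfg)
  outs <- c(file.path(cfg$out_root, "cohort", "participants.tsv"),
            file.path(sd_$cohort, "labels.nii.gz"))
  if (stage_done(outs)) { message("simulate: up to date"); return(invisible(outs)) }
  cc <- cohort_config(shape = cfg$shape, voxel_size_mm = cfg$voxel_size_mm,
                      snr_mwi = cfg$snr_mwi, snr_dwi = cfg$snr_dwi,
                      write_truth = cfg$write_truth)
  simulate_cohort(cfg$n_older, cfg$n_stroke, cc, cfg$seed,
                  file.path(cfg$out_root, "cohort"))
  invisible(outs)
}

#' @rdname run_all
#' @export
stage_fit_mwi <- function(cfg) {
  sd_ <- subject_dirs(cfg)
  outs <- file.path(sd_$maps, "mwf.nii.gz")
  if (stage_done(outs)) { message("fit-mwi: up to date"); return(invisible(outs)) }
  grid <- cfg_grid(cfg)
  part <- read_participants(cfg)
  for (i in seq_along(sd_$ids)) {
    lab <- read_vol(file.path(sd_$cohort[i], "labels.nii.gz"))
    echo <- read_vol(file.path(sd_$cohort[i], "mwi.nii.gz"))
    seqp <- scanner_sequence(part$scanner[i])
    mask <- analysis_mask(lab, cfg)
    maps <- fit_mwi_volume(echo, mask, seqp, grid, cfg$chi2_window,
                           cfg_angles(cfg), verbose = TRUE)
    dir.create(sd_$maps[i], recursive = TRUE, showWarnings = FALSE)
    write_nifti_vol(maps$mwf, cfg$voxel_size_mm,
                    file.path(sd_$maps[i], "mwf.nii.gz"))
    write_nifti_vol(maps$gmt2, cfg$voxel_size_mm,
                    file.path(sd_$maps[i], "gmt2.nii.gz"))
    write_nifti_vol(maps$flip, cfg$voxel_size_mm,
                    file.path(sd_$maps[i], "flip.nii.gz"))
    jsonlite::write_json(
      list(t2_grid_ms = grid$t2_values_ms, mwf_window_ms = c(10, 40),
           gmt2_window_ms = c(40, 200), chi2_window = cfg$chi2_window,
           n_rejected = maps$n_rejected,
           n_low_confidence = maps$n_low_confidence,
           version = as.character(utils::packageVersion("wmhpenumbra"))),
      file.path(sd_$maps[i], "mwi.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(outs)
}

#' @rdname run_all
#' @export
stage_fit_dti <- function(cfg) {
  sd_ <- subject_dirs(cfg)
  outs <- file.path(sd_$maps, "fa.nii.gz")
  if (stage_done(outs)) { message("fit-dti: up to date"); return(invisible(outs)) }
  for (i in seq_along(sd_$ids)) {
    lab <- read_vol(file.path(sd_$cohort[i], "labels.nii.gz"))
    dwi <- read_vol(file.path(sd_$cohort[i], "dwi.nii.gz"))
    sch <- read_bval_bvec(file.path(sd_$cohort[i], "dwi.bval"),
                          file.path(sd_$cohort[i], "dwi.bvec"))
    mask <- analysis_mask(lab, cfg)
    maps <- fit_dti_volume(dwi, sch, mask, verbose = TRUE)
    dir.create(sd_$maps[i], recursive = TRUE, showWarnings = FALSE)
    write_nifti_vol(maps$fa, cfg$voxel_size_mm,
                    file.path(sd_$maps[i], "fa.nii.gz"))
    write_nifti_vol(maps$md, cfg$voxel_size_mm,
                    file.path(sd_$maps[i], "md.nii.gz"))
  }
  invisible(outs)
}

read_participants <- function(cfg) {
  read.delim(file.path(cfg$out_root, "cohort", "participants.tsv"),
             stringsAsFactors = FALSE, colClasses = c(subject_id = "character"))
}

#' @rdname run_all
#' @export
stage_rois <- function(cfg) {
  out_tsv <- file.path(cfg$out_root, "rois", "roi_table.tsv")
  if (stage_done(out_tsv)) { message("rois: up to date"); return(invisible(out_tsv)) }
  sd_ <- subject_dirs(cfg)
  part <- read_participants(cfg)
  rows <- list()
  for (i in seq_along(sd_$ids)) {
    lab <- read_vol(file.path(sd_$cohort[i], "labels.nii.gz"))
    dims <- dim(lab)
    wmh <- array(lab == LBL[["wmh"]], dims)
    if (cfg$deep_only)
      wmh <- deep_wmh_mask(wmh, array(lab == LBL[["ventricular_csf"]], dims))
    if (!any(wmh)) { message("no WMH voxels for ", sd_$ids[i], "; skipped"); next }
    nawm <- array(lab == LBL[["nawm"]], dims)
    csf <- array(lab %in% c(LBL[["ventricular_csf"]], LBL[["sulcal_csf"]]),
                 dims)
    strk <- array(lab == LBL[["stroke"]], dims)
    rs <- make_rings(wmh, nawm, csf, if (any(strk)) strk else NULL,
                     cfg$voxel_size_mm, cfg$ring_width_mm, cfg$n_rings,
                     cfg$csf_exclude_mm, cfg$stroke_exclude_mm)
    map_files <- c(FA = "fa.nii.gz", MD = "md.nii.gz", MWF = "mwf.nii.gz",
                   GMT2 = "gmt2.nii.gz")
    maps <- lapply(map_files[cfg$metrics], function(f)
      read_vol(file.path(sd_$maps[i], f)))
    subj <- part[i, , drop = FALSE]
    rows[[length(rows) + 1L]] <- extract_roi_means(rs, maps, subj)
    if (cfg$hemisphere_split &&
        subj$hemisphere_of_stroke %in% c("left", "right")) {
      sp <- split_by_hemisphere(rs, subj$hemisphere_of_stroke)
      for (h in names(sp))
        rows[[length(rows) + 1L]] <-
          extract_roi_means(sp[[h]], maps, subj, hemisphere = h)
    }
    dir.create(file.path(cfg$out_root, "rois"), recursive = TRUE,
               showWarnings = FALSE)
    write_nifti_vol(ring_set_to_volume(rs), cfg$voxel_size_mm,
                    file.path(cfg$out_root, "rois",
                              paste0(sd_$ids[i], "_rois.nii.gz")), "uint8")
  }
  tab <- do.call(rbind, rows)
  write.table(tab, out_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out_tsv)
}

#' @rdname run_all
#' @export
stage_stats <- function(cfg) {
  out_dir <- file.path(cfg$out_root, "stats")
  outs <- file.path(out_dir, paste0("model_distance_group_",
                                    cfg$metrics, ".tsv"))
  if (stage_done(outs)) { message("stats: up to date"); return(invisible(outs)) }
  tab <- read.delim(file.path(cfg$out_root, "rois", "roi_table.tsv"),
                    stringsAsFactors = FALSE,
                    colClasses = c(distance_level = "character"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fits <- list()
  main_tab <- tab[is.na(tab$hemisphere), , drop = FALSE]
  for (met in cfg$metrics) {
    fg <- fit_distance_group(main_tab, met)
    fits[[paste0("distance_group_", met)]] <- fg
    write_fit_tsv(fg, file.path(out_dir,
                                paste0("model_distance_group_", met, ".tsv")))
    fv <- fit_wmh_volume_model(main_tab, met)
    fits[[paste0("wmh_volume_", met)]] <- fv
    write_fit_tsv(fv, file.path(out_dir,
                                paste0("model_wmh_volume_", met, ".tsv")))
    ph <- tryCatch(tukey_posthoc(fg, "distance"), error = function(e) {
      message(sprintf("post hoc contrasts unavailable for %s: %s", met,
                      conditionMessage(e)))
      NULL
    })
    if (!is.null(ph))
      write.table(ph, file.path(out_dir,
                                paste0("contrasts_distance_", met, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    if (cfg$hemisphere_split) {
      hem_tab <- tab[!is.na(tab$hemisphere), , drop = FALSE]
      if (nrow(hem_tab)) {
        fh <- fit_distance_hemisphere(hem_tab, met)
        fits[[paste0("distance_hemisphere_", met)]] <- fh
        write_fit_tsv(fh, file.path(out_dir,
                                    paste0("model_distance_hemisphere_",
                                           met, ".tsv")))
      }
    }
  }
  invisible(fits)
}

write_fit_tsv <- function(fit, path) {
  tt <- merge(fit$headline, fit$terms, by = "term", sort = FALSE)
  tt <- tt[match(fit$headline$term, tt$term),
           c("label", "term", "estimate", "se", "df", "t", "p")]
  full <- fit$terms
  full$label <- ""
  write.table(rbind(tt, full[, names(tt)]), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Run the full pipeline
#'
#' Orchestrates simulate -> fit-mwi -> fit-dti -> rois -> stats from a
#' [run_config()]. Stages whose outputs already exist are skipped
#' (stage-level resume); a manifest with MD5 checksums and a config
#' snapshot are written at the end.
#'
#' @param cfg A [run_config()] (or path to a YAML config).
#' @return Invisibly, the list of fitted models from the stats stage.
#' @export
run_all <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_root, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(unclass(cfg), file.path(cfg$out_root, "config.yaml"))
  stage_simulate(cfg)
  stage_fit_mwi(cfg)
  stage_fit_dti(cfg)
  stage_rois(cfg)
  fits <- stage_stats(cfg)
  files <- list.files(cfg$out_root, recursive = TRUE, full.names = TRUE)
  files <- setdiff(files, file.path(cfg$out_root, "manifest.json"))
  manifest <- data.frame(
    path = sub(paste0("^", cfg$out_root, "/?"), "", files),
    md5 = unname(tools::md5sum(files)), stringsAsFactors = FALSE)
  jsonlite::write_json(manifest, file.path(cfg$out_root, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(fits)
}
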