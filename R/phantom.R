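#' Perilesional gradient profile
#'
#' Programmed radial profile for fluid-linked tissue parameters around a
#' WMH: at distance `d` (mm) from the lesion the painted value is
#' `baseline + (lesion_value - baseline) * max(0, 1 - d/reach_mm)^shape`,
#' so the profile equals `lesion_value` inside the lesion (d = 0) and
#' returns exactly to `baseline` at `d >= reach_mm`.
#'
#' @param baseline Value in unaffected NAWM.
#' @param lesion_value Value inside the WMH.
#' @param reach_mm Support of the gradient, mm (> 0).
#' @param shape Exponent (2 = quadratic decay of the perturbation).
#' @return An object of class `gradient_profile`.
#' @export
gradient_profile <- function(baseline, lesion_value, reach_mm = 6, shape = 2) {
  if (reach_mm <= 0) stop("reach_mm must be > 0")
  structure(list(baseline = baseline, lesion_value = lesion_value,
                 reach_mm = reach_mm, shape = shape),
            class = "gradient_profile")
}

#' Evaluate a gradient profile at distances
#'
#' @param profile A [gradient_profile()].
#' @param d_mm Distances from the lesion boundary, mm.
#' @return Numeric vector of profile values.
#' @export
profile_value <- function(profile, d_mm) {
  with(profile,
       baseline + (lesion_value - baseline) *
         pmax(0, 1 - d_mm / reach_mm)^shape)
}

new_label_volume <- function(labels, voxel_size_mm) {
  if (any(voxel_size_mm <= 0)) stop("voxel_size_mm components must be > 0")
  storage.mode(labels) <- "integer"
  if (!all(labels %in% LBL)) stop("labels contain codes outside the declared set")
  structure(list(labels = labels, voxel_size_mm = as.numeric(voxel_size_mm)),
            class = "label_volume")
}

# physical mm coordinates of voxel centers (0-based index * spacing)
voxel_coords <- function(shape, voxel_size_mm) {
  list(x = (seq_len(shape[1]) - 1) * voxel_size_mm[1],
       y = (seq_len(shape[2]) - 1) * voxel_size_mm[2],
       z = (seq_len(shape[3]) - 1) * voxel_size_mm[3])
}

# TRUE inside the axis-aligned ellipsoid centered at `c0` with semi-axes `s`
ellipsoid_mask <- function(shape, voxel_size_mm, c0, s) {
  co <- voxel_coords(shape, voxel_size_mm)
  r2 <- outer(outer(((co$x - c0[1]) / s[1])^2, ((co$y - c0[2]) / s[2])^2, "+"),
              ((co$z - c0[3]) / s[3])^2, "+")
  r2 <= 1
}

# voxels of `ref` that are face-adjacent (6-neighborhood) to `mask`
face_adjacent <- function(mask) {
  d <- dim(mask)
  out <- array(FALSE, d)
  sh <- function(m, ax, by) {
    r <- array(FALSE, d)
    i <- lapply(d, seq_len)
    j <- i
    i[[ax]] <- seq_len(d[ax] - abs(by))
    j[[ax]] <- i[[ax]] + abs(by)
    if (by > 0) r[j[[1]], j[[2]], j[[3]]] <- m[i[[1]], i[[2]], i[[3]]]
    else        r[i[[1]], i[[2]], i[[3]]] <- m[j[[1]], j[[2]], j[[3]]]
    r
  }
  for (ax in 1:3) out <- out | sh(mask, ax, 1) | sh(mask, ax, -1)
  out & !mask
}

place_blob <- function(labels, voxel_size_mm, candidates, radius_mm, code,
                       what) {
  if (length(candidates) == 0)
    stop(sprintf("grid too small to place %s", what))
  ctr <- candidates[sample.int(length(candidates), 1)]
  d <- dim(labels)
  ijk <- arrayInd(ctr, d)
  c0 <- (ijk - 1) * voxel_size_mm
  semi <- radius_mm * runif(3, 0.85, 1.15)
  blob <- ellipsoid_mask(d, voxel_size_mm, c0, semi)
  sel <- blob & labels == LBL[["nawm"]]
  labels[sel] <- code
  labels[ctr] <- code
  labels
}

#' Synthetic brain label volume
#'
#' Builds a simplified supratentorial geometry on a 3-D grid: a brain
#' ellipsoid with a sulcal CSF rim, a grey matter shell, a white matter
#' interior, paired ventricles, periventricular and deep WMH blobs, and an
#' optional single-hemisphere stroke lesion. Periventricular blobs are
#' grown from a voxel adjacent to ventricular CSF; deep blobs are kept at
#' least 2 mm from the ventricles.
#'
#' @param shape Grid size (3 integers, each >= 32).
#' @param voxel_size_mm Voxel dimensions, mm.
#' @param n_deep_wmh,n_pv_wmh Number of deep / periventricular WMH blobs.
#' @param with_stroke Add a stroke lesion confined to one hemisphere.
#' @param seed Integer seed; the volume is deterministic given the seed.
#' @param wmh_radius_mm Nominal blob radius, mm (recycled over blobs).
#' @param stroke_radius_mm Stroke lesion radius, mm.
#' @param stroke_hemisphere `"left"` or `"right"` (low / high first-axis
#'   indices).
#' @return A `label_volume` (see [label_codes()] for the code table).
#' @export
make_label_volume <- function(shape = c(40L, 40L, 32L),
                              voxel_size_mm = c(1, 1, 1),
                              n_deep_wmh = 1L, n_pv_wmh = 1L,
                              with_stroke = FALSE, seed = 1L,
                              wmh_radius_mm = 2.2, stroke_radius_mm = 6,
                              stroke_hemisphere = c("left", "right")) {
  if (any(shape < 32L)) stop("shape must be >= 32 voxels in each dimension")
  stroke_hemisphere <- match.arg(stroke_hemisphere)
  set.seed(as.integer(seed))
  ext <- (shape - 1) * voxel_size_mm
  ctr <- ext / 2
  co <- voxel_coords(shape, voxel_size_mm)
  semi <- ext * 0.48
  r2 <- outer(outer(((co$x - ctr[1]) / semi[1])^2,
                    ((co$y - ctr[2]) / semi[2])^2, "+"),
              ((co$z - ctr[3]) / semi[3])^2, "+")
  labels <- array(LBL[["background"]], shape)
  labels[r2 <= 1] <- LBL[["sulcal_csf"]]
  labels[r2 <= 0.88] <- LBL[["grey_matter"]]
  labels[r2 <= 0.68] <- LBL[["nawm"]]

  # paired lateral ventricles, one per hemisphere
  for (sgn in c(-1, 1)) {
    vc <- ctr + c(sgn * 0.16 * ext[1], 0, 0)
    vent <- ellipsoid_mask(shape, voxel_size_mm, vc,
                           c(0.07 * ext[1], 0.22 * ext[2], 0.20 * ext[3]))
    labels[vent & labels == LBL[["nawm"]]] <- LBL[["ventricular_csf"]]
  }

  vmask <- labels == LBL[["ventricular_csf"]]
  dv <- edt_mm_cpp(vmask, dim(labels), voxel_size_mm)
  wm <- labels == LBL[["nawm"]]
  rad <- rep_len(wmh_radius_mm, n_pv_wmh + n_deep_wmh)

  for (i in seq_len(n_pv_wmh)) {
    cand <- which(wm & face_adjacent(vmask))
    labels <- place_blob(labels, voxel_size_mm, cand, rad[i], LBL[["wmh"]],
                         sprintf("periventricular WMH blob %d", i))
    wm <- labels == LBL[["nawm"]]
  }
  for (i in seq_len(n_deep_wmh)) {
    cand <- which(wm & dv >= 2 + rad[n_pv_wmh + i] * 1.2 & r2 <= 0.62)
    labels <- place_blob(labels, voxel_size_mm, cand, rad[n_pv_wmh + i],
                         LBL[["wmh"]], sprintf("deep WMH blob %d", i))
    wm <- labels == LBL[["nawm"]]
  }

  if (with_stroke) {
    xmid <- ctr[1]
    xo <- if (stroke_hemisphere == "left") co$x < xmid - stroke_radius_mm - 1
          else co$x > xmid + stroke_radius_mm + 1
    hemi <- array(rep(xo, times = prod(shape[2:3])), shape)
    cand <- which(wm & hemi & r2 <= 0.5)
    if (length(cand) == 0) stop("grid too small to place stroke lesion blob")
    ctr_v <- cand[sample.int(length(cand), 1)]
    c0 <- (arrayInd(ctr_v, shape) - 1) * voxel_size_mm
    blob <- ellipsoid_mask(shape, voxel_size_mm, c0,
                           stroke_radius_mm * runif(3, 0.8, 1.1))
    # stroke is removed from every other tissue class, but stays in-hemisphere
    blob <- blob & hemi & labels %in% c(LBL[["grey_matter"]], LBL[["nawm"]],
                                        LBL[["wmh"]])
    labels[blob] <- LBL[["stroke"]]
  }
  new_label_volume(labels, voxel_size_mm)
}

#' @export
print.label_volume <- function(x, ...) {
  cat("Synthetic label volume", paste(dim(x$labels), collapse = " x "),
      "voxels @", paste(x$voxel_size_mm, collapse = " x "), "mm\n")
  tb <- table(factor(x$labels, levels = LBL, labels = names(LBL)))
  print(tb)
  invisible(x)
}

#' Ground-truth parameter maps for a label volume
#'
#' Paints voxelwise true tissue parameters over a [make_label_volume()]
#' phantom. Fluid-linked maps (intra/extracellular T2, MD, FA) follow the
#' programmed perilesional [gradient_profile()]s as a function of distance
#' from the WMH; the true MWF is flat across NAWM in both groups and
#' reduced inside the WMH only for the stroke group (by
#' `mwf_wmh_deficit`). The refocusing flip-angle field is a smooth
#' quadratic polynomial spanning about 110-180 degrees.
#'
#' @param lv A `label_volume`.
#' @param profile_gmt2 [gradient_profile()] for the intra/extracellular T2
#'   (ms) driving GMT2.
#' @param profile_md [gradient_profile()] for MD (mm^2/s).
#' @param profile_fa [gradient_profile()] for FA.
#' @param group `"older_adult"` or `"stroke"`.
#' @param mwf_wmh_deficit MWF reduction inside the WMH for the stroke
#'   group; forced to 0 for older adults (programmed null).
#' @param mwf_nawm True MWF in NAWM.
#' @param seed Integer seed (flip-angle field jitter).
#' @return An object of class `ground_truth_maps` with 3-D arrays
#'   `mwf_true`, `ie_t2_true`, `fa_true`, `md_true`, `flip_angle_true`.
#' @export
paint_ground_truth <- function(lv,
                               profile_gmt2 = gradient_profile(80, 95),
                               profile_md = gradient_profile(0.80e-3, 1.10e-3),
                               profile_fa = gradient_profile(0.45, 0.30),
                               group = c("older_adult", "stroke"),
                               mwf_wmh_deficit = 0.04,
                               mwf_nawm = 0.12, seed = 1L) {
  stopifnot(inherits(lv, "label_volume"))
  group <- match.arg(group)
  for (p in list(profile_gmt2)) {
    if (p$lesion_value < 40 || p$lesion_value > 200)
      stop("profile_gmt2 lesion_value outside the tissue range [40, 200] ms")
  }
  set.seed(as.integer(seed))
  lab <- lv$labels
  shape <- dim(lab)
  wmh <- lab == LBL[["wmh"]]
  d <- if (any(wmh)) distance_map_mm(array(wmh, shape), lv$voxel_size_mm)
       else array(Inf, shape)

  mwf <- array(0, shape)
  ie <- array(NA_real_, shape)
  fa <- array(NA_real_, shape)
  md <- array(NA_real_, shape)

  in_prof <- lab %in% c(LBL[["nawm"]], LBL[["wmh"]])
  ie[in_prof] <- profile_value(profile_gmt2, d[in_prof])
  md[in_prof] <- profile_value(profile_md, d[in_prof])
  fa[in_prof] <- profile_value(profile_fa, d[in_prof])

  gm <- lab == LBL[["grey_matter"]]
  csf <- lab %in% c(LBL[["ventricular_csf"]], LBL[["sulcal_csf"]])
  strk <- lab == LBL[["stroke"]]
  ie[gm] <- 90; ie[csf] <- 1500; ie[strk] <- 150
  md[gm] <- 0.90e-3; md[csf] <- 3.0e-3; md[strk] <- 1.2e-3
  fa[gm] <- 0.15; fa[csf] <- 0.02; fa[strk] <- 0.10

  mwf[lab == LBL[["nawm"]]] <- mwf_nawm
  mwf[gm] <- 0.03
  mwf[strk] <- 0.02
  deficit <- if (group == "stroke") mwf_wmh_deficit else 0
  mwf[wmh] <- max(0, mwf_nawm - deficit)

  # smooth quadratic flip-angle field in [~110, 180]
  ext <- (shape - 1) * lv$voxel_size_mm
  c0 <- ext / 2 + runif(3, -0.08, 0.08) * ext
  co <- voxel_coords(shape, lv$voxel_size_mm)
  rho2 <- outer(outer(((co$x - c0[1]) / (0.75 * ext[1]))^2,
                      ((co$y - c0[2]) / (0.75 * ext[2]))^2, "+"),
                ((co$z - c0[3]) / (0.75 * ext[3]))^2, "+")
  flip <- 180 - 70 * pmin(rho2, 1)

  structure(list(mwf_true = mwf, ie_t2_true = ie, fa_true = fa, md_true = md,
                 flip_angle_true = flip, group = group,
                 mwf_wmh_deficit = deficit),
            class = "ground_truth_maps")
}

add_rician <- function(noiseless, sigma) {
  if (sigma <= 0) return(noiseless)
  n <- length(noiseless)
  sqrt((noiseless + rnorm(n, 0, sigma))^2 + rnorm(n, 0, sigma)^2)
}

#' Simulate a two-pool multi-echo decay
#'
#' Noiseless signal
#' `s0 * (mwf * EPG(T2 = myelin_t2) + (1 - mwf) * EPG(T2 = ie_t2))` with
#' Rician noise (magnitude of a complex Gaussian perturbation). Uses the
#' current R random number state.
#'
#' @param mwf Myelin water fraction in [0, 1].
#' @param ie_t2 Intra/extracellular T2, ms.
#' @param flip_angle Refocusing flip angle, degrees in (0, 180].
#' @param seq A [sequence_params()] object.
#' @param s0 Signal amplitude.
#' @param noise_sigma Rician noise sigma (same units as `s0`).
#' @param myelin_t2 Myelin pool T2, ms.
#' @return An [echo_train()].
#' @export
simulate_echo_train <- function(mwf, ie_t2, flip_angle, seq, s0 = 1,
                                noise_sigma = 0, myelin_t2 = 20) {
  if (mwf < 0 || mwf > 1) stop("mwf must be in [0, 1]")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (flip_angle <= 0 || flip_angle > 180)
    stop("non-physical flip angle (must be in (0, 180])")
  sig <- s0 * (mwf * epg_basis_curve(myelin_t2, seq, flip_angle) +
                 (1 - mwf) * epg_basis_curve(ie_t2, seq, flip_angle))
  echo_train(add_rician(sig, noise_sigma), seq)
}

#' Simulate diffusion-weighted signals
#'
#' Noiseless `S_i = s0 * exp(-b_i * g_i' D g_i)` with Rician noise.
#'
#' @param tensor 3 x 3 symmetric positive semi-definite tensor, mm^2/s.
#' @param scheme A [diffusion_scheme()].
#' @param s0 Unweighted signal.
#' @param noise_sigma Rician noise sigma.
#' @return Numeric vector of signals, one per scheme entry.
#' @export
simulate_dwi <- function(tensor, scheme, s0 = 1, noise_sigma = 0) {
  D <- if (inherits(tensor, "dti_tensor")) tensor$D else as.matrix(tensor)
  if (max(abs(D - t(D))) > 1e-12) stop("tensor must be symmetric")
  if (min(eigen(D, symmetric = TRUE, only.values = TRUE)$values) < -1e-12)
    stop("tensor must be positive semi-definite")
  g <- scheme$bvecs
  q <- colSums(g * (D %*% g))
  add_rician(s0 * exp(-scheme$bvals * q), noise_sigma)
}

# axially symmetric tensor with given FA, MD and principal axis u
tensor_from_fa_md <- function(fa, md, u) {
  alpha <- fa / sqrt(3 - 2 * fa^2)
  l2 <- md * (1 - alpha)
  dl <- 3 * md * alpha
  diag(rep(l2, 3)) + dl * tcrossprod(u)
}
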