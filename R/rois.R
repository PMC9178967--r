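#' Euclidean distance map in millimetres
#'
#' Distance from each voxel center to the nearest mask-voxel center in
#' physical mm, honoring anisotropic voxel dimensions; 0 inside the mask.
#' Exact (separable lower-envelope transform).
#'
#' @param mask Non-empty 3-D logical array.
#' @param voxel_size_mm Voxel dimensions, mm.
#' @return 3-D numeric array of distances, mm.
#' @export
distance_map_mm <- function(mask, voxel_size_mm) {
  if (is.null(dim(mask)) || length(dim(mask)) != 3)
    stop("mask must be a 3-D array (note: `%in%` drops dims; wrap in array())")
  if (!any(mask)) stop("distance_map_mm: empty mask")
  if (any(voxel_size_mm <= 0)) stop("voxel_size_mm components must be > 0")
  # snap to 1e-9 mm so ring/dilation boundaries are insensitive to the
  # floating-point summation order of the squared per-axis offsets
  round(edt_mm_cpp(mask, dim(mask), as.numeric(voxel_size_mm)), 9)
}

#' Metric dilation of a mask
#'
#' All voxels whose center lies within `d_mm` of a mask-voxel center.
#' A superset of the mask and monotone in `d_mm`.
#'
#' @inheritParams distance_map_mm
#' @param d_mm Dilation radius, mm (>= 0).
#' @return 3-D logical array.
#' @export
dilate_mm <- function(mask, d_mm, voxel_size_mm) {
  if (d_mm < 0) stop("d_mm must be >= 0")
  distance_map_mm(mask, voxel_size_mm) <= d_mm
}

#' WMH ROI and perilesional NAWM distance rings
#'
#' Order of operations: (1) exclusions -- NAWM and WMH are trimmed of all
#' voxels within `csf_exclude_mm` (default 1 mm) of CSF and within
#' `stroke_exclude_mm` (default 10 mm) of a stroke lesion; (2) ring k
#' (k = 1..5) collects the trimmed NAWM voxels whose distance to the
#' *original* WMH lies in `(2(k-1), 2k]` mm (half-open, so a voxel at
#' exactly 2 mm belongs to ring 1).
#'
#' @param wmh_mask,nawm_mask,csf_mask 3-D logical arrays (mutually
#'   disjoint). `csf_mask` should include both sulcal and ventricular CSF.
#' @param stroke_mask Optional 3-D logical array; `NULL` for none.
#' @param voxel_size_mm Voxel dimensions, mm.
#' @param ring_width_mm Ring increment, mm.
#' @param n_rings Number of rings.
#' @param csf_exclude_mm,stroke_exclude_mm Exclusion radii, mm.
#' @return An object of class `ring_set`: `wmh_roi`, list `rings`
#'   (named by outer edge, mm), `voxel_size_mm`, `ring_edges_mm`.
#' @export
make_rings <- function(wmh_mask, nawm_mask, csf_mask, stroke_mask = NULL,
                       voxel_size_mm, ring_width_mm = 2, n_rings = 5L,
                       csf_exclude_mm = 1, stroke_exclude_mm = 10) {
  if (any(wmh_mask & nawm_mask) || any(wmh_mask & csf_mask) ||
      any(nawm_mask & csf_mask))
    stop("input masks must be mutually disjoint")
  if (!any(wmh_mask)) stop("make_rings: empty WMH mask (subject excluded)")
  keep <- !array(FALSE, dim(wmh_mask))
  if (any(csf_mask))
    keep <- keep & !dilate_mm(csf_mask, csf_exclude_mm, voxel_size_mm)
  if (!is.null(stroke_mask) && any(stroke_mask))
    keep <- keep & !dilate_mm(stroke_mask, stroke_exclude_mm, voxel_size_mm)
  nawm2 <- nawm_mask & keep
  wmh_roi <- wmh_mask & keep

  d <- distance_map_mm(wmh_mask, voxel_size_mm)
  edges <- ring_width_mm * seq_len(n_rings)
  rings <- vector("list", n_rings)
  for (k in seq_len(n_rings)) {
    rings[[k]] <- nawm2 & d > ring_width_mm * (k - 1) & d <= edges[k]
    if (!any(rings[[k]]))
      warning(sprintf("ring (%g, %g] mm is empty",
                      ring_width_mm * (k - 1), edges[k]))
  }
  names(rings) <- as.character(edges)
  structure(list(wmh_roi = wmh_roi, rings = rings,
                 voxel_size_mm = as.numeric(voxel_size_mm),
                 ring_edges_mm = edges),
            class = "ring_set")
}

#' @export
print.ring_set <- function(x, ...) {
  cat("Perilesional ring set (voxel counts):\n")
  cat(sprintf("  WMH ROI : %d\n", sum(x$wmh_roi)))
  for (nm in names(x$rings))
    cat(sprintf("  <= %s mm : %d\n", nm, sum(x$rings[[nm]])))
  invisible(x)
}

#' Classify WMH components as periventricular or deep
#'
#' Connected components of the WMH mask (26-connectivity) are
#' periventricular iff any component voxel is 26-adjacent to (or overlaps)
#' ventricular CSF, deep otherwise.
#'
#' @param wmh_mask,ventricular_csf_mask 3-D logical arrays.
#' @return List with integer array `component_labels` (0 background) and
#'   character vector `class` (one entry per component).
#' @export
classify_wmh <- function(wmh_mask, ventricular_csf_mask) {
  lab <- label_components26_cpp(wmh_mask, dim(wmh_mask))
  n <- max(lab)
  if (n == 0L) return(list(component_labels = lab, class = character(0)))
  pv <- touches26_cpp(lab, ventricular_csf_mask, dim(wmh_mask), n)
  list(component_labels = lab,
       class = ifelse(pv, "periventricular", "deep"))
}

#' Restrict a ring set to deep WMH components
#'
#' Drops periventricular components from the WMH ROI (rings are rebuilt by
#' the caller when needed).
#'
#' @param wmh_mask Full WMH mask.
#' @param ventricular_csf_mask Ventricular CSF mask.
#' @return Logical mask of deep-WMH voxels.
#' @export
deep_wmh_mask <- function(wmh_mask, ventricular_csf_mask) {
  cl <- classify_wmh(wmh_mask, ventricular_csf_mask)
  if (length(cl$class) == 0) return(wmh_mask & FALSE)
  deep <- which(cl$class == "deep")
  array(cl$component_labels %in% deep, dim(wmh_mask))
}

#' WMH volume in millilitres
#'
#' @param wmh_mask 3-D logical array.
#' @param voxel_size_mm Voxel dimensions, mm.
#' @return Volume in mL (voxel count x voxel volume / 1000).
#' @export
wmh_volume_ml <- function(wmh_mask, voxel_size_mm) {
  sum(wmh_mask) * prod(voxel_size_mm) / 1000
}

#' Split a ring set by cerebral hemisphere
#'
#' Intersects every ROI with the two half-spaces on either side of the
#' mid-sagittal plane (first array axis). Only unilateral-stroke subjects
#' are eligible.
#'
#' @param ring_set A [make_rings()] result.
#' @param hemisphere_of_stroke `"left"` or `"right"` (`"bilateral"` and
#'   `"none"` are rejected).
#' @param midline_index Last first-axis index of the left half; defaults
#'   to `floor(nx / 2)`.
#' @return List with `ipsilesional` and `contralesional` ring sets.
#' @export
split_by_hemisphere <- function(ring_set, hemisphere_of_stroke,
                                midline_index = NULL) {
  if (!hemisphere_of_stroke %in% c("left", "right"))
    stop("hemisphere split requires a unilateral stroke (left or right)")
  d <- dim(ring_set$wmh_roi)
  if (is.null(midline_index)) midline_index <- floor(d[1] / 2)
  left <- array(rep(seq_len(d[1]) <= midline_index, times = prod(d[2:3])), d)
  half <- function(rs, m) {
    rs$wmh_roi <- rs$wmh_roi & m
    rs$rings <- lapply(rs$rings, function(r) r & m)
    rs
  }
  ipsi_mask <- if (hemisphere_of_stroke == "left") left else !left
  list(ipsilesional = half(ring_set, ipsi_mask),
       contralesional = half(ring_set, !ipsi_mask))
}

#' Encode a ring set as an integer ROI volume
#'
#' Codes: 10 = WMH ROI, 11-15 = rings from 2 mm to 10 mm.
#'
#' @param ring_set A [make_rings()] result.
#' @return 3-D integer array.
#' @export
ring_set_to_volume <- function(ring_set) {
  out <- array(0L, dim(ring_set$wmh_roi))
  out[ring_set$wmh_roi] <- 10L
  for (k in seq_along(ring_set$rings)) out[ring_set$rings[[k]]] <- 10L + k
  out
}

#' Extract per-ROI metric means
#'
#' Mean over finite voxels of each metric map in the WMH ROI and each
#' ring; rows with zero finite voxels are dropped with a message.
#'
#' @param ring_set A [make_rings()] result.
#' @param maps Named list of 3-D metric maps (e.g. FA, MD, MWF, GMT2) on
#'   the same grid as the ring set.
#' @param subject One-row data frame (or list) of subject covariates;
#'   carried onto every output row.
#' @param hemisphere Optional hemisphere label carried onto the rows.
#' @return Long-format data frame: one row per ROI x metric with columns
#'   `distance_level` (`WMH`, `2`, ..., `10`), `metric`, `mean`,
#'   `n_voxels`, plus the subject covariates.
#' @export
extract_roi_means <- function(ring_set, maps, subject,
                              hemisphere = NA_character_) {
  rois <- c(list(WMH = ring_set$wmh_roi),
            setNames(ring_set$rings, names(ring_set$rings)))
  subject <- as.data.frame(subject, stringsAsFactors = FALSE)
  out <- list()
  for (lev in names(rois)) {
    for (met in names(maps)) {
      v <- maps[[met]][rois[[lev]]]
      v <- v[is.finite(v)]
      if (length(v) == 0) {
        message(sprintf("dropping %s / %s: no finite voxels", lev, met))
        next
      }
      out[[length(out) + 1L]] <- cbind(
        subject,
        data.frame(distance_level = lev, metric = met, mean = mean(v),
                   n_voxels = length(v), hemisphere = hemisphere,
                   stringsAsFactors = FALSE))
    }
  }
  do.call(rbind, out)
}
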