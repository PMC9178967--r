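#' Multi-echo spin-echo sequence parameters
#'
#' @param n_echoes Number of echoes (>= 8).
#' @param echo_spacing_ms Echo spacing in ms; the first echo occurs at this
#'   time.
#' @param tr_ms Repetition time in ms.
#' @param t1_ms Assumed longitudinal relaxation time used for the stored
#'   longitudinal configuration states during the refocusing train.
#' @return An object of class `sequence_params`.
#' @export
sequence_params <- function(n_echoes = 32L, echo_spacing_ms = 10,
                            tr_ms = 1000, t1_ms = 1000) {
  n_echoes <- as.integer(n_echoes)
  if (n_echoes < 8L) stop("n_echoes must be >= 8")
  if (echo_spacing_ms <= 0) stop("echo_spacing_ms must be > 0")
  structure(list(n_echoes = n_echoes, echo_spacing_ms = echo_spacing_ms,
                 tr_ms = tr_ms, t1_ms = t1_ms),
            class = "sequence_params")
}

#' Scanner configurations for the two multi-echo protocols
#'
#' Two GRASE-style protocols: `A_32echo` (32 echoes, 10 ms spacing,
#' TR 1000 ms) and `B_48echo` (48 echoes, 8 ms spacing, TR 1073 ms).
#'
#' @param scanner `"A_32echo"` or `"B_48echo"`.
#' @return A `sequence_params` object.
#' @export
scanner_sequence <- function(scanner = c("A_32echo", "B_48echo")) {
  scanner <- match.arg(scanner)
  if (scanner == "A_32echo") sequence_params(32L, 10, 1000, 1000)
  else sequence_params(48L, 8, 1073, 1000)
}

#' Logarithmic T2 grid
#'
#' Logarithmically spaced T2 bins for spectrum fitting. The default 40 bins
#' from 10 to 2000 ms place no bin exactly at 40 ms, so the myelin-water
#' (10-40 ms) and intra/extracellular (40-200 ms) windows never share a bin.
#'
#' @param n_bins Number of bins.
#' @param t2_min_ms,t2_max_ms Grid range in ms.
#' @return An object of class `t2_grid` with element `t2_values_ms`.
#' @export
t2_grid <- function(n_bins = 40L, t2_min_ms = 10, t2_max_ms = 2000) {
  if (t2_min_ms > 10 || t2_max_ms < 200) stop("grid must span at least 10-200 ms")
  v <- exp(seq(log(t2_min_ms), log(t2_max_ms), length.out = as.integer(n_bins)))
  v[1] <- t2_min_ms
  v[length(v)] <- t2_max_ms
  structure(list(t2_values_ms = v, n_bins = as.integer(n_bins)),
            class = "t2_grid")
}

#' One voxel's multi-echo decay
#'
#' @param signal Non-negative echo magnitudes, length `seq$n_echoes`.
#' @param seq A [sequence_params()] object.
#' @return An object of class `echo_train`.
#' @export
echo_train <- function(signal, seq) {
  stopifnot(inherits(seq, "sequence_params"))
  if (length(signal) != seq$n_echoes)
    stop("signal length does not match seq$n_echoes")
  if (any(signal < 0, na.rm = TRUE))
    stop("echo magnitudes must be >= 0")
  structure(list(signal = as.numeric(signal), seq = seq), class = "echo_train")
}

#' EPG decay basis curve
#'
#' Echo amplitudes of a single T2 species for unit initial magnetization,
#' computed by propagating extended phase graph configuration states
#' (F+, F-, Z) through the refocusing train with relaxation between pulses.
#' At a 180 degree refocusing angle this reduces to pure exponential decay
#' `exp(-n * echo_spacing / t2)`; at lower angles stimulated-echo pathways
#' redistribute signal to later echoes.
#'
#' @param t2_ms T2 of the species, ms (> 0).
#' @param seq A [sequence_params()] object.
#' @param flip_angle_deg Refocusing flip angle, degrees in (0, 180].
#' @return Numeric vector of `seq$n_echoes` echo amplitudes.
#' @export
epg_basis_curve <- function(t2_ms, seq, flip_angle_deg) {
  stopifnot(inherits(seq, "sequence_params"))
  if (t2_ms <= 0) stop("t2_ms must be > 0")
  if (flip_angle_deg <= 0 || flip_angle_deg > 180)
    stop("flip_angle_deg must be in (0, 180]")
  as.numeric(epg_echo_train_cpp(t2_ms, seq$t1_ms, seq$echo_spacing_ms,
                                seq$n_echoes, flip_angle_deg))
}

#' EPG decay basis matrix
#'
#' Column j is [epg_basis_curve()] evaluated at the j-th grid T2.
#'
#' @param grid A [t2_grid()] object.
#' @inheritParams epg_basis_curve
#' @return `seq$n_echoes` x `grid$n_bins` matrix of non-negative amplitudes.
#' @export
build_basis <- function(grid, seq, flip_angle_deg) {
  stopifnot(inherits(grid, "t2_grid"), inherits(seq, "sequence_params"))
  if (flip_angle_deg <= 0 || flip_angle_deg > 180)
    stop("flip_angle_deg must be in (0, 180]")
  epg_basis_cpp(grid$t2_values_ms, seq$t1_ms, seq$echo_spacing_ms,
                seq$n_echoes, flip_angle_deg)
}

#' Non-negative least squares
#'
#' Minimizes `||basis %*% a - signal||^2` subject to `a >= 0`
#' (Lawson-Hanson active set).
#'
#' @param basis Design matrix.
#' @param signal Response vector.
#' @return List with `amplitudes` and residual sum of squares `rss`.
#' @export
nnls_fit <- function(basis, signal) {
  basis <- as.matrix(basis)
  if (nrow(basis) != length(signal))
    stop("basis and signal are dimensionally inconsistent")
  f <- nnls_cpp(basis, as.numeric(signal))
  list(amplitudes = as.numeric(f$x), rss = f$rss)
}

#' Regularized non-negative least squares
#'
#' Solves `min ||basis a - signal||^2 + mu ||a||^2, a >= 0`, choosing `mu`
#' by bisection so the data misfit chi-squared lies within
#' `chi2_window * chi2_min`, where `chi2_min` is the unregularized NNLS
#' misfit. If the window is unattainable (e.g. a noiseless, exactly
#' representable signal) the unregularized solution is returned with
#' `mu = 0` and `fallback = TRUE`.
#'
#' @inheritParams nnls_fit
#' @param chi2_window Pair `(low, high)` of misfit inflation factors,
#'   `1 < low < high` (default `c(1.02, 1.025)`).
#' @return List with `amplitudes`, `mu`, `chi2`, `chi2_min`, `fallback`.
#' @export
regularized_nnls <- function(basis, signal, chi2_window = c(1.02, 1.025)) {
  basis <- as.matrix(basis)
  if (nrow(basis) != length(signal))
    stop("basis and signal are dimensionally inconsistent")
  if (length(chi2_window) != 2 || chi2_window[1] <= 1 ||
      chi2_window[2] <= chi2_window[1])
    stop("chi2_window must satisfy 1 < low < high")
  f <- regnnls_cpp(basis, as.numeric(signal), chi2_window[1], chi2_window[2])
  if (f$fallback)
    message("regularized_nnls: chi2 window unattainable, returning mu = 0 fit")
  list(amplitudes = as.numeric(f$x), mu = f$mu, chi2 = f$chi2,
       chi2_min = f$chi2_min, fallback = f$fallback)
}

#' Refocusing flip angle estimation
#'
#' Returns the flip angle minimizing the unregularized NNLS residual over
#' `angle_grid`, refined by parabolic interpolation around the grid minimum.
#' The angle search uses a coarse T2 grid for speed. A flat residual profile
#' (pure-noise voxel) returns 180 degrees flagged low confidence.
#'
#' @param echo An [echo_train()] object.
#' @param grid A [t2_grid()]; a coarse (default 8-bin) version is used
#'   internally.
#' @param angle_grid Candidate angles in degrees, covering 90-180.
#' @param coarse_bins Number of bins for the search grid.
#' @return List with `flip_angle_deg` and logical `low_confidence`.
#' @export
estimate_flip_angle <- function(echo, grid = t2_grid(),
                                angle_grid = seq(90, 180, by = 2),
                                coarse_bins = 8L) {
  stopifnot(inherits(echo, "echo_train"))
  if (min(angle_grid) > 90 || max(angle_grid) < 180)
    stop("angle_grid must cover [90, 180]")
  cg <- exp(seq(log(min(grid$t2_values_ms)), log(max(grid$t2_values_ms)),
                length.out = coarse_bins))
  fit <- mwi_fit_batch_cpp(matrix(echo$signal, ncol = 1), grid$t2_values_ms,
                           cg, sort(angle_grid), echo$seq$echo_spacing_ms,
                           echo$seq$t1_ms, 1.02, 1.025, 10, 40, 40, 200, FALSE)
  list(flip_angle_deg = fit$flip[1], low_confidence = fit$flag[1] == 1L)
}

#' Myelin water fraction of a T2 spectrum
#'
#' Sum of amplitudes at bins with T2 inside `window_ms` (inclusive both
#' ends) divided by the total amplitude sum.
#'
#' @param spec List with `grid` (a [t2_grid()]) and non-negative
#'   `amplitudes`.
#' @param window_ms Myelin-water window, ms.
#' @return Fraction in [0, 1], or `NA` if the total amplitude is zero.
#' @export
compute_mwf <- function(spec, window_ms = c(10, 40)) {
  t2 <- spec$grid$t2_values_ms
  a <- spec$amplitudes
  stopifnot(length(t2) == length(a))
  tot <- sum(a)
  if (tot <= 0) return(NA_real_)
  sum(a[t2 >= window_ms[1] & t2 <= window_ms[2]]) / tot
}

#' Geometric mean T2 of the intra/extracellular pool
#'
#' Amplitude-weighted mean of log(T2) over bins inside `window_ms`
#' (inclusive), exponentiated.
#'
#' @inheritParams compute_mwf
#' @param window_ms Intra/extracellular window, ms.
#' @return Geometric mean T2 in ms, or `NA` if the window holds no
#'   amplitude.
#' @export
compute_gmt2 <- function(spec, window_ms = c(40, 200)) {
  t2 <- spec$grid$t2_values_ms
  a <- spec$amplitudes
  stopifnot(length(t2) == length(a))
  inw <- t2 >= window_ms[1] & t2 <= window_ms[2]
  w <- sum(a[inw])
  if (w <= 0) return(NA_real_)
  exp(sum(a[inw] * log(t2[inw])) / w)
}

#' Fit one voxel's T2 spectrum
#'
#' Pipeline order: estimate the refocusing flip angle, build the EPG basis
#' at that angle, fit the regularized NNLS spectrum, then summarize as MWF
#' and GMT2.
#'
#' @param echo An [echo_train()] object.
#' @param grid A [t2_grid()].
#' @param chi2_window Misfit window for [regularized_nnls()].
#' @param angle_grid Flip-angle search grid, degrees.
#' @return An object of class `mwi_fit` with elements `spectrum`, `mwf`,
#'   `gmt2_ms`, `flip_angle_deg`, `chi2`, `regularizer_mu`, `flag`.
#' @export
fit_voxel <- function(echo, grid = t2_grid(), chi2_window = c(1.02, 1.025),
                      angle_grid = seq(90, 180, by = 2)) {
  stopifnot(inherits(echo, "echo_train"))
  if (any(!is.finite(echo$signal))) stop("non-finite signal: voxel rejected")
  cg <- exp(seq(log(min(grid$t2_values_ms)), log(max(grid$t2_values_ms)),
                length.out = 8))
  f <- mwi_fit_batch_cpp(matrix(echo$signal, ncol = 1), grid$t2_values_ms,
                         cg, sort(angle_grid), echo$seq$echo_spacing_ms,
                         echo$seq$t1_ms, chi2_window[1], chi2_window[2],
                         10, 40, 40, 200, TRUE)
  structure(list(
    spectrum = list(grid = grid, amplitudes = as.numeric(f$spectra[, 1])),
    mwf = f$mwf[1], gmt2_ms = f$gmt2[1], flip_angle_deg = f$flip[1],
    chi2 = f$chi2[1], regularizer_mu = f$mu[1], flag = f$flag[1],
    seq = echo$seq), class = "mwi_fit")
}

#' @export
print.mwi_fit <- function(x, ...) {
  cat("Myelin water fit\n")
  cat(sprintf("  MWF        : %.4f\n", x$mwf))
  cat(sprintf("  GMT2       : %.2f ms\n", x$gmt2_ms))
  cat(sprintf("  flip angle : %.1f deg\n", x$flip_angle_deg))
  cat(sprintf("  chi2 = %.4g (mu = %.3g)\n", x$chi2, x$regularizer_mu))
  invisible(x)
}

#' @export
coef.mwi_fit <- function(object, ...) {
  c(mwf = object$mwf, gmt2_ms = object$gmt2_ms,
    flip_angle_deg = object$flip_angle_deg)
}

#' Voxelwise myelin water fitting over a volume
#'
#' Applies the [fit_voxel()] pipeline to every voxel inside `mask` of a 4-D
#' multi-echo array (x, y, z, echo). Voxels outside the mask are `NA`.
#'
#' @param echo4d 4-D numeric array; 4th dimension must equal
#'   `seq$n_echoes`.
#' @param mask 3-D logical array.
#' @param seq A [sequence_params()] object.
#' @param grid A [t2_grid()].
#' @param chi2_window Misfit window for [regularized_nnls()].
#' @param angle_grid Flip-angle search grid, degrees.
#' @param verbose Log progress.
#' @return List of 3-D maps `mwf`, `gmt2`, `flip`, plus `n_fit`,
#'   `n_rejected`, `n_low_confidence`.
#' @export
fit_mwi_volume <- function(echo4d, mask, seq, grid = t2_grid(),
                           chi2_window = c(1.02, 1.025),
                           angle_grid = seq(90, 180, by = 2),
                           verbose = FALSE) {
  d <- dim(echo4d)
  if (length(d) != 4 || d[4] != seq$n_echoes)
    stop("echo data 4th dimension does not match seq$n_echoes")
  if (!all(dim(mask) == d[1:3])) stop("mask dimensions do not match data")
  idx <- which(mask)
  sig <- matrix(aperm(echo4d, c(4, 1, 2, 3)), nrow = d[4])[, idx, drop = FALSE]
  cg <- exp(seq(log(min(grid$t2_values_ms)), log(max(grid$t2_values_ms)),
                length.out = 8))
  f <- mwi_fit_batch_cpp(sig, grid$t2_values_ms, cg, sort(angle_grid),
                         seq$echo_spacing_ms, seq$t1_ms,
                         chi2_window[1], chi2_window[2], 10, 40, 40, 200, FALSE)
  mk <- function(v) { a <- array(NA_real_, d[1:3]); a[idx] <- v; a }
  if (verbose)
    message(sprintf("fit_mwi_volume: %d voxels fit, %d rejected, %d low-confidence flip",
                    sum(f$flag != 2L), sum(f$flag == 2L), sum(f$flag == 1L)))
  list(mwf = mk(f$mwf), gmt2 = mk(f$gmt2), flip = mk(f$flip),
       n_fit = sum(f$flag != 2L), n_rejected = sum(f$flag == 2L),
       n_low_confidence = sum(f$flag == 1L))
}
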