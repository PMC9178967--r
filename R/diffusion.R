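#' Diffusion gradient scheme
#'
#' @param bvals Vector of b-values, s/mm^2.
#' @param bvecs 3 x n matrix of gradient directions; weighted directions
#'   must be unit vectors (non-unit vectors are normalized with a warning).
#' @return An object of class `diffusion_scheme`.
#' @export
diffusion_scheme <- function(bvals, bvecs) {
  bvecs <- as.matrix(bvecs)
  if (nrow(bvecs) != 3 || ncol(bvecs) != length(bvals))
    stop("bvecs must be 3 x length(bvals)")
  nrm <- sqrt(colSums(bvecs^2))
  w <- bvals > 0
  if (sum(w) < 6) stop("need >= 6 weighted directions")
  if (!any(!w)) stop("need >= 1 b = 0 volume")
  bad <- w & abs(nrm - 1) > 1e-6
  if (any(bad)) {
    warning(sprintf("normalizing %d non-unit gradient direction(s)", sum(bad)))
    bvecs[, bad] <- sweep(bvecs[, bad, drop = FALSE], 2, nrm[bad], "/")
  }
  structure(list(bvals = as.numeric(bvals), bvecs = bvecs),
            class = "diffusion_scheme")
}

#' Default 60-direction scheme
#'
#' Sixty approximately uniform non-collinear directions (spherical
#' Fibonacci points on a hemisphere) at b = 700 s/mm^2 plus `n_b0`
#' unweighted volumes, mirroring a HARDI protocol.
#'
#' @param n_dirs Number of weighted directions.
#' @param b Weighted b-value, s/mm^2.
#' @param n_b0 Number of b = 0 volumes.
#' @return A [diffusion_scheme()].
#' @export
default_scheme <- function(n_dirs = 60L, b = 700, n_b0 = 4L) {
  i <- seq_len(n_dirs) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- i / n_dirs              # hemisphere: antipodal directions equivalent
  r <- sqrt(pmax(0, 1 - z^2))
  g <- rbind(r * cos(phi), r * sin(phi), z)
  diffusion_scheme(c(rep(0, n_b0), rep(b, n_dirs)),
                   cbind(matrix(0, 3, n_b0), g))
}

#' Read / write FSL-style gradient tables
#'
#' `read_bval_bvec` parses whitespace-delimited `bval` (1 row) and `bvec`
#' (3 rows) files; `write_bval_bvec` writes them.
#'
#' @param bval_file,bvec_file File paths.
#' @return A [diffusion_scheme()].
#' @export
read_bval_bvec <- function(bval_file, bvec_file) {
  bvals <- scan(bval_file, quiet = TRUE)
  bvecs <- matrix(scan(bvec_file, quiet = TRUE), nrow = 3, byrow = TRUE)
  diffusion_scheme(bvals, bvecs)
}

#' @rdname read_bval_bvec
#' @param scheme A [diffusion_scheme()].
#' @export
write_bval_bvec <- function(scheme, bval_file, bvec_file) {
  writeLines(paste(format(scheme$bvals, trim = TRUE), collapse = " "), bval_file)
  writeLines(apply(scheme$bvecs, 1, function(r)
    paste(format(r, trim = TRUE, digits = 10), collapse = " ")), bvec_file)
  invisible(NULL)
}

# design matrix for ln S = ln S0 - b g' D g
dti_design <- function(scheme) {
  g <- scheme$bvecs; b <- scheme$bvals
  cbind(1, -b * g[1, ]^2, -b * g[2, ]^2, -b * g[3, ]^2,
        -2 * b * g[1, ] * g[2, ], -2 * b * g[1, ] * g[3, ],
        -2 * b * g[2, ] * g[3, ])
}

beta_to_tensor <- function(beta) {
  D <- matrix(c(beta[2], beta[5], beta[6],
                beta[5], beta[3], beta[7],
                beta[6], beta[7], beta[4]), 3, 3)
  structure(list(D = D, s0 = exp(beta[1])), class = "dti_tensor")
}

#' Fit the diffusion tensor in one voxel
#'
#' Two-pass weighted linear least squares on
#' `ln S = ln S0 - b g' D g`: an ordinary LS fit followed by a refit with
#' weights equal to the squared predicted signals. Signals at or below zero
#' are floored at machine epsilon (flagged).
#'
#' @param signals Measured signals, one per scheme entry.
#' @param scheme A [diffusion_scheme()].
#' @return An object of class `dti_tensor` with 3 x 3 matrix `D` (mm^2/s),
#'   `s0`, and `floored` count.
#' @export
fit_tensor <- function(signals, scheme) {
  stopifnot(inherits(scheme, "diffusion_scheme"))
  if (length(signals) != length(scheme$bvals))
    stop("signals length does not match scheme")
  X <- dti_design(scheme)
  qrX <- qr(X)
  if (qrX$rank < 7L) stop("rank-deficient design: gradient directions are collinear")
  floored <- sum(signals <= 0)
  y <- log(pmax(signals, .Machine$double.eps))
  beta <- qr.coef(qrX, y)
  w <- exp(2 * as.numeric(X %*% beta))       # squared predicted signal
  beta <- solve(crossprod(X, w * X), crossprod(X, w * y))
  t <- beta_to_tensor(as.numeric(beta))
  t$floored <- floored
  t
}

tensor_eigs <- function(t) {
  D <- if (inherits(t, "dti_tensor")) t$D else as.matrix(t)
  eigen(D, symmetric = TRUE, only.values = TRUE)$values
}

#' Fractional anisotropy
#'
#' `sqrt(3/2) * ||lambda - mean(lambda)|| / ||lambda||` over the tensor
#' eigenvalues; negative eigenvalues are clamped to zero first. An all-zero
#' tensor has FA defined as 0.
#'
#' @param t A `dti_tensor` or symmetric 3 x 3 matrix.
#' @return FA in [0, 1].
#' @export
fa_of <- function(t) {
  l <- pmax(tensor_eigs(t), 0)
  n2 <- sum(l^2)
  if (n2 <= 0) return(0)
  min(1, sqrt(1.5 * sum((l - mean(l))^2) / n2))
}

#' Mean diffusivity
#'
#' Trace of the tensor divided by 3 (negative eigenvalues clamped to zero).
#'
#' @inheritParams fa_of
#' @return MD in mm^2/s.
#' @export
md_of <- function(t) {
  mean(pmax(tensor_eigs(t), 0))
}

#' Voxelwise diffusion tensor fitting
#'
#' Fits [fit_tensor()] in each voxel inside `mask` and returns FA and MD
#' maps; `NA` outside the mask. The count of voxels with clamped negative
#' eigenvalues is logged.
#'
#' @param dwi4d 4-D array (x, y, z, volume).
#' @param scheme A [diffusion_scheme()].
#' @param mask 3-D logical array.
#' @param verbose Log counts.
#' @return List with `fa`, `md` maps and `n_clamped`.
#' @export
fit_dti_volume <- function(dwi4d, scheme, mask, verbose = FALSE) {
  d <- dim(dwi4d)
  if (length(d) != 4 || d[4] != length(scheme$bvals))
    stop("dwi 4th dimension does not match scheme")
  if (!all(dim(mask) == d[1:3])) stop("mask dimensions do not match data")
  idx <- which(mask)
  S <- matrix(aperm(dwi4d, c(4, 1, 2, 3)), nrow = d[4])[, idx, drop = FALSE]
  X <- dti_design(scheme)
  XtXi <- solve(crossprod(X))
  Y <- log(pmax(S, .Machine$double.eps))
  B <- XtXi %*% crossprod(X, Y)              # OLS pass, all voxels at once
  fa <- md <- rep(NA_real_, length(idx))
  n_clamped <- 0L
  for (v in seq_along(idx)) {
    w <- exp(2 * as.numeric(X %*% B[, v]))
    beta <- tryCatch(solve(crossprod(X, w * X), crossprod(X, w * Y[, v])),
                     error = function(e) B[, v])
    l <- tensor_eigs(beta_to_tensor(as.numeric(beta)))
    if (any(l < 0)) n_clamped <- n_clamped + 1L
    l <- pmax(l, 0)
    n2 <- sum(l^2)
    fa[v] <- if (n2 > 0) min(1, sqrt(1.5 * sum((l - mean(l))^2) / n2)) else 0
    md[v] <- mean(l)
  }
  if (verbose)
    message(sprintf("fit_dti_volume: %d voxels, %d with clamped eigenvalues",
                    length(idx), n_clamped))
  mk <- function(v) { a <- array(NA_real_, d[1:3]); a[idx] <- v; a }
  list(fa = mk(fa), md = mk(md), n_clamped = n_clamped)
}
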