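# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths.

# Bloch rotation-matrix isochromat ensemble for a CPMG train: the reference
# for the EPG propagation.
iso_echo_train <- function(t2, t1, esp, n_echoes, flip_deg, nspins = 2501) {
  th <- seq(-pi, pi, length.out = nspins + 1)[-1]
  a <- flip_deg * pi / 180
  M <- rbind(rep(1, nspins), 0, 0) # transverse after excitation
  E2 <- exp(-0.5 * esp / t2); E1 <- exp(-0.5 * esp / t1)
  rot_x <- matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
  ech <- numeric(n_echoes)
  dephase <- function(M) {
    Mx <- cos(th) * M[1, ] - sin(th) * M[2, ]
    My <- sin(th) * M[1, ] + cos(th) * M[2, ]
    M[1, ] <- Mx; M[2, ] <- My; M
  }
  for (n in seq_len(n_echoes)) {
    M[1:2, ] <- M[1:2, ] * E2; M[3, ] <- M[3, ] * E1
    M <- dephase(M)
    M <- rot_x %*% M
    M[1:2, ] <- M[1:2, ] * E2; M[3, ] <- M[3, ] * E1
    M <- dephase(M)
    ech[n] <- sqrt(mean(M[1, ])^2 + mean(M[2, ])^2)
  }
  ech
}

# Exhaustive active-set enumeration for NNLS instances with few columns:
# the optimum lies on some support set with a non-negative unconstrained
# least-squares solution.
nnls_enum_objective <- function(A, b) {
  n <- ncol(A)
  best <- sum(b^2) # empty support
  for (size in seq_len(n)) {
    for (cols in utils::combn(n, size, simplify = FALSE)) {
      As <- A[, cols, drop = FALSE]
      z <- tryCatch(qr.solve(As, b), error = function(e) NULL)
      if (is.null(z) || any(z < 0)) next
      best <- min(best, sum((As %*% z - b)^2))
    }
  }
  best
}

# O(N * M) brute-force Euclidean distance transform in physical mm
brute_edt <- function(mask, sp) {
  d <- dim(mask)
  idx <- which(mask, arr.ind = TRUE)
  pts <- sweep(idx - 1, 2, sp, "*")
  co <- expand.grid(x = (seq_len(d[1]) - 1) * sp[1],
                    y = (seq_len(d[2]) - 1) * sp[2],
                    z = (seq_len(d[3]) - 1) * sp[3])
  out <- array(Inf, d)
  for (r in seq_len(nrow(pts))) {
    dd <- sqrt((co$x - pts[r, 1])^2 + (co$y - pts[r, 2])^2 +
                 (co$z - pts[r, 3])^2)
    out <- pmin(out, array(dd, d))
  }
  round(out, 9) # same boundary-snapping convention as distance_map_mm
}

# Gram-Schmidt orthonormalization of {x, x^2} against the constant over
# equally spaced scores (reference for orthogonal polynomial codes)
gram_schmidt_quadratic <- function(n) {
  x <- seq_len(n)
  v1 <- rep(1, n)
  proj <- function(v, u) sum(v * u) / sum(u * u) * u
  l <- x - proj(x, v1)
  q <- x^2 - proj(x^2, v1) - proj(x^2, l)
  cbind(L = l / sqrt(sum(l^2)), Q = q / sqrt(sum(q^2)))
}

# random label geometry for ring-oracle checks
random_ring_masks <- function(dims, sp, seed) {
  set.seed(seed)
  n <- prod(dims)
  wmh <- array(FALSE, dims)
  wmh[sample(n, max(2, round(0.005 * n)))] <- TRUE
  rest <- !wmh
  csf <- array(runif(n) < 0.01, dims) & rest
  stroke <- array(FALSE, dims)
  ctr <- dims / 2
  stroke[ctr[1], ctr[2], ctr[3]] <- TRUE
  stroke <- stroke & rest & !csf
  nawm <- rest & !csf & !stroke
  list(wmh = wmh, nawm = nawm, csf = csf, stroke = stroke, sp = sp)
}

expect_rings_match_oracle <- function(m) {
  rs <- suppressWarnings(make_rings(m$wmh, m$nawm, m$csf,
                   if (any(m$stroke)) m$stroke else NULL, m$sp))
  d_wmh <- brute_edt(m$wmh, m$sp)
  keep <- array(TRUE, dim(m$wmh))
  if (any(m$csf)) keep <- keep & !(brute_edt(m$csf, m$sp) <= 1)
  if (any(m$stroke)) keep <- keep & !(brute_edt(m$stroke, m$sp) <= 10)
  expect_identical(rs$wmh_roi, m$wmh & keep)
  for (k in 1:5) {
    oracle <- m$nawm & keep & d_wmh > 2 * (k - 1) & d_wmh <= 2 * k
    expect_identical(rs$rings[[k]], oracle)
  }
  rois <- c(list(rs$wmh_roi), rs$rings)
  for (i in seq_along(rois)) for (j in seq_len(i - 1))
    expect_false(any(rois[[i]] & rois[[j]]))
  invisible(rs)
}
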