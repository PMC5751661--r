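# programmatic fixtures: simple shapes, random star blobs, brute-force
# oracles (the oracles deliberately use naive double loops, independent of
# the package's vectorized implementations)

make_disk <- function(n, R, center = c((n + 1) / 2, (n + 1) / 2)) {
  d <- sqrt(outer((seq_len(n) - center[1])^2,
                  (seq_len(n) - center[2])^2, "+"))
  m <- matrix(0L, n, n)
  m[d <= R] <- 1L
  m
}

make_rect <- function(n, r0, c0, h, w) {
  m <- matrix(0L, n, n)
  m[r0:(r0 + h - 1), c0:(c0 + w - 1)] <- 1L
  m
}

# random star-convex blob from a radial Fourier perturbation
make_blob <- function(n = 128, R = 40, irr = 0.2, seed = 1) {
  set.seed(seed)
  k <- 2:7
  amp <- runif(6, 0.2, 1); amp <- amp / sum(amp) * irr
  ph <- runif(6, 0, 2 * pi)
  ctr <- (n + 1) / 2
  dr <- matrix(seq_len(n) - ctr, n, n)
  dc <- t(dr)
  th <- atan2(dc, dr)
  rho <- R * (1 + Reduce(`+`, lapply(1:6, function(i)
    amp[i] * cos(k[i] * th + ph[i]))))
  m <- matrix(0L, n, n)
  m[sqrt(dr^2 + dc^2) <= rho] <- 1L
  m
}

# star with deep concavities; curvature radius at the valleys is
# rho^2 / |rho - rho''| = (R(1-a))^2 / (R a k^2 - R(1-a)) -- about 4.3 px
# for R = 55, a = 0.3, k = 5, far below the offsets used against it
make_star <- function(n = 160, R = 55, a = 0.3, k = 5) {
  ctr <- (n + 1) / 2
  dr <- matrix(seq_len(n) - ctr, n, n)
  dc <- t(dr)
  th <- atan2(dc, dr)
  rho <- R * (1 + a * cos(k * th))
  m <- matrix(0L, n, n)
  m[sqrt(dr^2 + dc^2) <= rho] <- 1L
  m
}

# brute-force boundary pixels: plain double loop, image border counts as
# background
brute_boundary <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(0L, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (mask[r, c] != 1) next
    bg <- FALSE
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- r + dr; cc <- c + dc
      if (rr < 1 || rr > nr || cc < 1 || cc > nc || mask[rr, cc] == 0)
        bg <- TRUE
    }
    if (bg) out[r, c] <- 1L
  }
  out
}

# brute-force symmetric co-occurrence counts: double loop over all pixel
# pairs in the patch
brute_glcm_counts <- function(q, patch_mask, offset, levels) {
  counts <- matrix(0L, levels, levels)
  idx <- which(patch_mask != 0, arr.ind = TRUE)
  for (a in seq_len(nrow(idx))) for (b in seq_len(nrow(idx))) {
    if (idx[b, 1] - idx[a, 1] == offset[1] &&
        idx[b, 2] - idx[a, 2] == offset[2]) {
      i <- q[idx[a, 1], idx[a, 2]] + 1L
      j <- q[idx[b, 1], idx[b, 2]] + 1L
      counts[i, j] <- counts[i, j] + 1L
      counts[j, i] <- counts[j, i] + 1L
    }
  }
  counts
}

# linear index set of a contour's points in a mask of nr rows
points_to_idx <- function(points, nr) {
  unique((points[, 2] - 1L) * nr + points[, 1])
}

densify <- function(poly, spacing = 0.25) resample_polyline(poly, spacing)
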