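# planar polyline utilities used by the contraction and patch layers;
# all polylines are n x 2 matrices of (row, col) coordinates, closed loops
# repeat their first vertex in the last row

#' Total arc length of a polyline
#' @param poly n x 2 matrix of (row, col) vertices.
#' @return Numeric length in pixels.
#' @export
polyline_length <- function(poly) {
  d <- diff(poly)
  sum(sqrt(rowSums(d^2)))
}

#' Signed area enclosed by a closed polyline (shoelace)
#'
#' Positive for one orientation, negative for the other; callers usually take
#' `abs()`. The polyline must repeat its first vertex last.
#'
#' @param poly closed n x 2 matrix of (row, col) vertices.
#' @return Signed area in square pixels.
#' @export
polygon_area <- function(poly) {
  r <- poly[, 1]; c <- poly[, 2]
  n <- nrow(poly)
  sum(c[-n] * r[-1] - c[-1] * r[-n]) / 2
}

#' Resample a closed polyline at even arc-length spacing
#'
#' @param poly closed n x 2 matrix (first vertex repeated last).
#' @param spacing arc-length step in pixels.
#' @return m x 2 matrix of points at arc lengths 0, spacing, 2*spacing, ...
#'   (open: the coincident closing point is not repeated).
#' @export
resample_polyline <- function(poly, spacing) {
  stopifnot(spacing > 0)
  seg <- sqrt(rowSums(diff(poly)^2))
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  if (total <= 0) return(poly[1, , drop = FALSE])
  s <- seq(0, total - 1e-9, by = spacing)
  idx <- findInterval(s, cum, rightmost.closed = TRUE)
  idx[idx >= nrow(poly)] <- nrow(poly) - 1L
  frac <- (s - cum[idx]) / pmax(seg[idx], 1e-12)
  poly[idx, , drop = FALSE] +
    (poly[idx + 1L, , drop = FALSE] - poly[idx, , drop = FALSE]) * frac
}

# Minimum distance from each point in `pts` to the vertex set `verts`,
# chunked so the pairwise matrix never exceeds ~8e6 cells.
point_min_dist <- function(pts, verts) {
  n <- nrow(pts)
  out <- numeric(n)
  chunk <- max(1L, floor(8e6 / max(nrow(verts), 1L)))
  vr <- verts[, 1]; vc <- verts[, 2]
  i <- 1L
  while (i <= n) {
    j <- min(i + chunk - 1L, n)
    dr <- outer(pts[i:j, 1], vr, "-")
    dc <- outer(pts[i:j, 2], vc, "-")
    out[i:j] <- sqrt(apply(dr * dr + dc * dc, 1, min))
    i <- j + 1L
  }
  out
}

#' Hausdorff distance between two point sets
#'
#' Symmetric max-min Euclidean distance. For curves, pass densely resampled
#' vertices (see [resample_polyline()]).
#'
#' @param a,b matrices with points in rows, 2 columns (row, col).
#' @return Numeric distance in pixels.
#' @export
hausdorff_distance <- function(a, b) {
  max(max(point_min_dist(a, b)), max(point_min_dist(b, a)))
}

#' Test whether a closed polyline is simple (non-self-intersecting)
#'
#' Checks every pair of non-adjacent segments for proper or improper
#' intersection with exact orientation tests. O(n^2), intended for the
#' contraction-quality invariants on desk-scale curves.
#'
#' @param poly closed n x 2 matrix (first vertex repeated last).
#' @param tol segments closer than this at a crossing count as intersecting
#'   endpoint-touch tolerance for collinear near-misses.
#' @return `TRUE` if no two non-adjacent segments intersect.
#' @export
polyline_is_simple <- function(poly, tol = 1e-9) {
  p <- poly[-nrow(poly), , drop = FALSE]        # unique vertices
  n <- nrow(p)
  if (n < 4) return(TRUE)
  a <- p
  b <- p[c(2:n, 1), , drop = FALSE]
  cross <- function(o, u, v) {
    (u[, 1] - o[, 1]) * (v[, 2] - o[, 2]) - (u[, 2] - o[, 2]) * (v[, 1] - o[, 1])
  }
  for (i in seq_len(n - 2L)) {
    # non-adjacent partners of segment i (skip i-1, i, i+1 cyclically)
    j <- (i + 2L):n
    if (i == 1L) j <- j[j != n]               # segment n is adjacent to 1
    if (length(j) == 0L) next
    a1 <- a[rep(i, length(j)), , drop = FALSE]
    b1 <- b[rep(i, length(j)), , drop = FALSE]
    a2 <- a[j, , drop = FALSE]
    b2 <- b[j, , drop = FALSE]
    d1 <- cross(a1, b1, a2)
    d2 <- cross(a1, b1, b2)
    d3 <- cross(a2, b2, a1)
    d4 <- cross(a2, b2, b1)
    hit <- (((d1 > tol & d2 < -tol) | (d1 < -tol & d2 > tol)) &
            ((d3 > tol & d4 < -tol) | (d3 < -tol & d4 > tol)))
    if (any(hit)) return(FALSE)
  }
  TRUE
}
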