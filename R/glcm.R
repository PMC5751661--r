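# gray-level co-occurrence texture over masked pixel sets
#
# C_{dx,dy}(i, j) counts pixel pairs (p, p + offset) whose quantized levels
# are i and j, restricted to pixels inside the patch; the matrix is
# symmetrized and normalized to sum 1. Homogeneity is
# sum_ij GLCM(i, j) / (1 + |i - j|): 1 when all mass is diagonal (paired
# pixels share a level), lower for sharp local intensity transitions.

#' Uniformly quantize an intensity channel
#'
#' Bins the full channel range (`[0, 255]` by default) into `levels` equal
#' bins; monotone, so ordering of intensities is preserved.
#'
#' @param channel_image numeric matrix (or vector) of intensities.
#' @param levels number of gray levels (>= 2).
#' @param range full channel range used for binning.
#' @return Integer array of the same shape with values in `0:(levels-1)`.
#' @export
quantize_channel <- function(channel_image, levels = 32, range = c(0, 255)) {
  if (levels < 2) stop("levels must be >= 2")
  q <- floor((channel_image - range[1]) / diff(range) * levels)
  q[q < 0] <- 0
  q[q > levels - 1] <- levels - 1
  storage.mode(q) <- "integer"
  q
}

#' Co-occurrence matrix of a masked patch
#'
#' Counts ordered pixel pairs (p, p + offset) with both pixels inside the
#' patch pixel set, symmetrizes (each pair counted in both directions) and
#' normalizes to sum 1.
#'
#' @param quantized integer matrix of levels `0:(levels-1)` (full image or
#'   patch bounding box).
#' @param patch_mask logical/0-1 matrix, same shape: pixels belonging to the
#'   patch.
#' @param offset integer `c(drow, dcol)` displacement; the default `c(0, 1)`
#'   is the horizontal offset (dx, dy) = (1, 0) with x = column.
#' @param levels number of gray levels.
#' @param normalize divide by the total count (after symmetrization).
#' @return A `glcm` object: list with `counts` (levels x levels matrix),
#'   `levels`, `offset`, `normalized`.
#' @export
compute_glcm <- function(quantized, patch_mask, offset = c(0L, 1L),
                         levels = 32, normalize = TRUE) {
  stopifnot(all(dim(quantized) == dim(patch_mask)))
  nr <- nrow(quantized); nc <- ncol(quantized)
  dr <- as.integer(offset[1]); dc <- as.integer(offset[2])
  rows <- seq_len(nr); cols <- seq_len(nc)
  r1 <- rows[rows + dr >= 1 & rows + dr <= nr]
  c1 <- cols[cols + dc >= 1 & cols + dc <= nc]
  if (length(r1) == 0 || length(c1) == 0)
    stop("no valid pixel pairs for this offset")
  m <- patch_mask != 0
  ok <- m[r1, c1, drop = FALSE] & m[r1 + dr, c1 + dc, drop = FALSE]
  if (!any(ok)) stop("no valid pixel pairs inside the patch")
  i <- quantized[r1, c1, drop = FALSE][ok]
  j <- quantized[r1 + dr, c1 + dc, drop = FALSE][ok]
  counts <- matrix(tabulate(i * levels + j + 1L, nbins = levels * levels),
                   levels, levels, byrow = TRUE)
  counts <- (counts + t(counts)) * 1.0          # symmetrize
  if (normalize) counts <- counts / sum(counts)
  structure(list(counts = counts, levels = levels, offset = c(dr, dc),
                 normalized = normalize), class = "glcm")
}

#' Homogeneity of a normalized co-occurrence matrix
#'
#' `sum_ij GLCM(i, j) / (1 + |i - j|)`; equals 1 iff all mass lies on the
#' diagonal, and is bounded below by `1/levels` for symmetric matrices with
#' uniform marginals.
#'
#' @param glcm a `glcm` object (must be normalized) or a bare matrix summing
#'   to 1.
#' @return Numeric in (0, 1].
#' @export
glcm_homogeneity <- function(glcm) {
  if (inherits(glcm, "glcm")) {
    if (!isTRUE(glcm$normalized)) stop("glcm must be normalized")
    counts <- glcm$counts
  } else counts <- glcm
  if (abs(sum(counts) - 1) > 1e-8) stop("glcm must be normalized (sum to 1)")
  n <- nrow(counts)
  idx <- seq_len(n)
  w <- 1 / (1 + abs(outer(idx, idx, "-")))
  sum(counts * w)
}

#' Per-patch channel statistics
#'
#' GLCM homogeneity on the quantized patch plus mean and population standard
#' deviation (ddof = 0) of the raw, unquantized channel values.
#'
#' @param channel numeric matrix of raw channel intensities (0-255 scale).
#' @param patch_mask logical/0-1 matrix of patch membership, same shape.
#' @param levels,offset GLCM parameters (see [compute_glcm()]).
#' @return Named numeric `c(homogeneity, mean, std)`.
#' @export
patch_statistics <- function(channel, patch_mask, levels = 32,
                             offset = c(0L, 1L)) {
  q <- quantize_channel(channel, levels = levels)
  g <- compute_glcm(q, patch_mask, offset = offset, levels = levels)
  v <- channel[patch_mask != 0]
  c(homogeneity = glcm_homogeneity(g),
    mean = mean(v),
    std = sqrt(mean((v - mean(v))^2)))
}
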