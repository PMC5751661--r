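# overlapping circular patches tiling the peripheral annulus
#
# The contraction distance is tied to the patch radius as L = 2 r, so a
# radius-r circle centered on the mid-curve (the offset curve at depth r)
# is tangent to both the original and the contracted border; centers are
# sampled along the mid-curve at arc-length spacing r, giving >= 50% overlap
# between consecutive patches.

#' Build the overlapping circular patch layer over the annulus
#'
#' Samples patch centers on the mid-curve between the original and
#' contracted borders and collects, for each patch, the image pixels whose
#' centers lie within `radius_r + 0.5` of the patch center (the pixel
#' intersects the patch disk) intersected with the annulus.
#'
#' @param result a `contraction_result` obtained with
#'   `distance_L = 2 * radius_r`.
#' @param radius_r patch radius in pixels (the study uses 5, 7, 10, 15).
#' @param spacing_factor arc-length step between centers as a multiple of
#'   `radius_r`; must stay below 2 so consecutive patches overlap.
#' @param min_pixels patches with fewer usable pixels are dropped with a
#'   warning.
#' @return A `patch_set`: list with `centers` (m x 2 matrix), `radius_r`,
#'   `spacing`, and `patch_pixel_sets` (list of integer index vectors into
#'   the image matrix).
#' @export
build_patch_layer <- function(result, radius_r, spacing_factor = 1,
                              min_pixels = 9) {
  stopifnot(inherits(result, "contraction_result"))
  if (abs(result$distance_L - 2 * radius_r) > 1e-9)
    stop("patch layer requires contraction distance_L = 2 * radius_r (got L = ",
         result$distance_L, ", r = ", radius_r, ")")
  if (spacing_factor <= 0 || spacing_factor >= 2)
    stop("spacing_factor must be in (0, 2) so consecutive patches overlap")
  annulus <- result$annulus_mask
  if (sum(annulus) == 0) stop("annulus is empty")
  phi0 <- result$field_initial$phi
  if (-min(phi0) <= radius_r)
    stop("lesion too small for patch radius ", radius_r)
  mid <- zero_level_curves(phi0, level = -radius_r)
  spacing <- spacing_factor * radius_r
  centers <- do.call(rbind, lapply(mid, resample_polyline, spacing = spacing))
  nr <- nrow(annulus); nc <- ncol(annulus)
  rad <- radius_r + 0.5
  sets <- vector("list", nrow(centers))
  for (k in seq_len(nrow(centers))) {
    r0 <- max(1L, floor(centers[k, 1] - rad))
    r1 <- min(nr, ceiling(centers[k, 1] + rad))
    c0 <- max(1L, floor(centers[k, 2] - rad))
    c1 <- min(nc, ceiling(centers[k, 2] + rad))
    rr <- r0:r1; cc <- c0:c1
    d2 <- outer((rr - centers[k, 1])^2, (cc - centers[k, 2])^2, "+")
    inside <- d2 <= rad^2 & annulus[rr, cc, drop = FALSE] == 1L
    idx <- which(inside)
    sets[[k]] <- (rep(cc, each = length(rr))[idx] - 1L) * nr +
      rep(rr, times = length(cc))[idx]
  }
  usable <- lengths(sets) >= min_pixels
  if (any(!usable))
    warning(sum(!usable), " patch(es) with fewer than ", min_pixels,
            " usable pixels dropped")
  if (sum(usable) < 4)
    stop("lesion too small for patch radius ", radius_r,
         ": fewer than 4 usable patches")
  structure(list(centers = centers[usable, , drop = FALSE],
                 radius_r = radius_r, spacing = spacing,
                 patch_pixel_sets = sets[usable],
                 grid_shape = c(nr, nc)),
            class = "patch_set")
}

#' @export
print.patch_set <- function(x, ...) {
  cat("Peripheral patch layer: r =", x$radius_r, "px,",
      nrow(x$centers), "patches, spacing", x$spacing, "px\n")
  invisible(x)
}

# fraction of annulus pixels covered by the union of patches
patch_coverage <- function(patches, annulus_mask) {
  covered <- unique(unlist(patches$patch_pixel_sets))
  length(covered) / sum(annulus_mask)
}
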