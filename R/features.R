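# peripheral feature vectors: 6 statistics x channels
#
# Per channel, patch statistics (GLCM homogeneity, color mean, color std)
# are aggregated over all patches by mean and by min, in the fixed order
# (mean-homogeneity, min-homogeneity, mean of patch means, min of patch
# means, mean of patch stds, min of patch stds): 18 features for RGB or
# HSV, 36 for the RGB+HSV concatenation.

feature_stat_names <- c("mean_homogeneity", "min_homogeneity",
                        "mean_colmean", "min_colmean",
                        "mean_colstd", "min_colstd")

#' Names of the feature columns for a color space
#' @param color_space `"RGB"`, `"HSV"` or `"RGB+HSV"`.
#' @return Character vector of length 18 or 36.
#' @export
feature_names <- function(color_space = c("RGB", "HSV", "RGB+HSV")) {
  color_space <- match.arg(color_space)
  chans <- switch(color_space,
                  "RGB" = c("R", "G", "B"),
                  "HSV" = c("H", "S", "V"),
                  "RGB+HSV" = c("R", "G", "B", "H", "S", "V"))
  as.vector(vapply(chans, function(ch) paste(ch, feature_stat_names, sep = "_"),
                   character(6)))
}

# h x w x 3 array in [0,1] -> named list of channel matrices on the 0-255
# scale; hue is scaled to [0,255] so all channels share one quantizer
image_channels <- function(image, color_space) {
  stopifnot(length(dim(image)) == 3, dim(image)[3] >= 3)
  r <- image[, , 1] * 255; g <- image[, , 2] * 255; b <- image[, , 3] * 255
  chans <- list()
  if (color_space %in% c("RGB", "RGB+HSV"))
    chans <- c(chans, list(R = r, G = g, B = b))
  if (color_space %in% c("HSV", "RGB+HSV")) {
    hsv <- grDevices::rgb2hsv(as.vector(r), as.vector(g), as.vector(b),
                              maxColorValue = 255)
    dimfun <- function(v) matrix(v * 255, nrow(r), ncol(r))
    chans <- c(chans, list(H = dimfun(hsv[1, ]), S = dimfun(hsv[2, ]),
                           V = dimfun(hsv[3, ])))
  }
  chans
}

#' Extract the peripheral feature vector of a lesion
#'
#' Tiles the annulus of `result` with overlapping radius-`radius_r` patches
#' and aggregates per-patch GLCM homogeneity and color statistics into the
#' fixed-order feature vector.
#'
#' @param image h x w x 3 RGB array in `[0, 1]` (as read by
#'   [png::readPNG()]); must match the mask dimensions.
#' @param result a `contraction_result` run with `distance_L = 2 * radius_r`.
#' @param radius_r patch radius in pixels.
#' @param color_space `"RGB"`, `"HSV"` or `"RGB+HSV"` (RGB features first).
#' @param glcm_levels,glcm_offset GLCM quantization levels and displacement.
#' @param spacing_factor patch spacing as a multiple of `radius_r`.
#' @param label optional class label stored with the vector.
#' @return A `feature_vector`: list with `values` (named numeric of length
#'   18 or 36), `radius_r`, `color_space`, `label`.
#' @export
extract_features <- function(image, result, radius_r,
                             color_space = c("RGB", "HSV", "RGB+HSV"),
                             glcm_levels = 32, glcm_offset = c(0L, 1L),
                             spacing_factor = 1, label = "unknown") {
  color_space <- match.arg(color_space)
  stopifnot(all(dim(image)[1:2] == dim(result$annulus_mask)))
  patches <- build_patch_layer(result, radius_r,
                               spacing_factor = spacing_factor)
  chans <- image_channels(image, color_space)
  nr <- patches$grid_shape[1]
  npatch <- length(patches$patch_pixel_sets)

  # per-patch bounding boxes and local masks, shared across channels
  boxes <- lapply(patches$patch_pixel_sets, function(idx) {
    r <- (idx - 1L) %% nr + 1L
    cc <- (idx - 1L) %/% nr + 1L
    r0 <- min(r); c0 <- min(cc)
    mloc <- matrix(FALSE, max(r) - r0 + 1L, max(cc) - c0 + 1L)
    mloc[cbind(r - r0 + 1L, cc - c0 + 1L)] <- TRUE
    list(r = r0:max(r), c = c0:max(cc), m = mloc, idx = idx)
  })

  values <- numeric(0)
  for (ch in names(chans)) {
    mat <- chans[[ch]]
    q <- quantize_channel(mat, levels = glcm_levels)
    hom <- mu <- sd0 <- numeric(npatch)
    for (k in seq_len(npatch)) {
      b <- boxes[[k]]
      g <- compute_glcm(q[b$r, b$c, drop = FALSE], b$m,
                        offset = glcm_offset, levels = glcm_levels)
      hom[k] <- glcm_homogeneity(g)
      v <- mat[b$idx]
      mu[k] <- mean(v)
      sd0[k] <- sqrt(mean((v - mu[k])^2))
    }
    values <- c(values, mean(hom), min(hom), mean(mu), min(mu),
                mean(sd0), min(sd0))
  }
  names(values) <- feature_names(color_space)
  structure(list(values = values, radius_r = radius_r,
                 color_space = color_space, label = label),
            class = "feature_vector")
}

#' @export
print.feature_vector <- function(x, ...) {
  cat("Peripheral feature vector (", x$color_space, ", r = ", x$radius_r,
      " px, label ", x$label, "): ", length(x$values), " features\n", sep = "")
  print(round(x$values, 4))
  invisible(x)
}

#' Bind feature vectors into a feature table
#'
#' One row per (image, radius, color_space); the column set is the union of
#' the 36 possible features, with `NA` in channels absent from a row's color
#' space.
#'
#' @param fvs list of `feature_vector`s.
#' @param ids character vector of image ids (recycled against `fvs`).
#' @return data.frame with columns `id`, `label`, `radius`, `color_space`
#'   and the 36 feature columns.
#' @export
features_to_table <- function(fvs, ids) {
  all_cols <- feature_names("RGB+HSV")
  rows <- lapply(seq_along(fvs), function(i) {
    fv <- fvs[[i]]
    v <- stats::setNames(rep(NA_real_, length(all_cols)), all_cols)
    v[names(fv$values)] <- fv$values
    cbind(data.frame(id = ids[i], label = fv$label, radius = fv$radius_r,
                     color_space = fv$color_space,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(v)))
  })
  do.call(rbind, rows)
}
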