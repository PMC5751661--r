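# binary lesion masks: PNG I/O, 8-connected labeling, preprocessing

#' Read a binary lesion mask from PNG
#'
#' Single-channel (or first-channel) PNG, binarized at > 0.5 (i.e. > 127 on
#' the 8-bit scale); foreground (1) is the lesion.
#'
#' @param path PNG file path.
#' @return Integer matrix of 0/1, rows = image rows.
#' @export
read_mask <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  m <- matrix(0L, nrow(img), ncol(img))
  m[img > 0.5] <- 1L
  m
}

#' Write a binary mask as PNG
#' @param mask 0/1 matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask != 0), nrow(mask), ncol(mask)), path)
  invisible(path)
}

assert_mask <- function(mask) {
  if (!is.matrix(mask) || !all(mask %in% c(0, 1)))
    stop("mask must be a matrix with values exactly 0 or 1")
  if (!any(mask == 1)) stop("no foreground: mask has no foreground pixels")
  invisible(mask)
}

#' Label 8-connected foreground components
#'
#' Frontier-based flood fill over the 8-neighborhood (diagonal contacts
#' connect, unlike 4-connected labelers).
#'
#' @param mask 0/1 matrix.
#' @return Integer matrix; 0 background, components numbered from 1 in
#'   scan-order of their first pixel.
#' @export
label_components8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  # pad by one to make neighbor indexing branch-free
  p <- matrix(FALSE, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- mask == 1
  lab <- matrix(0L, nr + 2L, nc + 2L)
  npr <- nr + 2L
  offs <- c(-1L - npr, -npr, 1L - npr, -1L, 1L, npr - 1L, npr, npr + 1L)
  todo <- which(p)
  k <- 0L
  for (s in todo) {
    if (lab[s] != 0L) next
    k <- k + 1L
    lab[s] <- k
    frontier <- s
    while (length(frontier)) {
      nb <- unique(rep(frontier, each = 8L) + offs)
      nb <- nb[p[nb] & lab[nb] == 0L]
      lab[nb] <- k
      frontier <- nb
    }
  }
  lab[2:(nr + 1L), 2:(nc + 1L), drop = FALSE]
}

#' Preprocess a lesion mask for border analysis
#'
#' Keeps only the largest 8-connected foreground component and fills interior
#' holes, yielding the single simply-connected blob the contraction stage
#' assumes.
#'
#' @param mask 0/1 matrix.
#' @return 0/1 integer matrix.
#' @export
preprocess_mask <- function(mask) {
  assert_mask(mask)
  lab <- label_components8(mask)
  if (max(lab) > 1L) {
    sizes <- tabulate(lab[lab > 0L])
    keep <- which.max(sizes)
    mask <- matrix(0L, nrow(mask), ncol(mask))
    mask[lab == keep] <- 1L
  }
  filled <- EBImage::fillHull(mask)
  m <- matrix(0L, nrow(mask), ncol(mask))
  m[as.matrix(filled) > 0] <- 1L
  m
}

# fg pixels with at least one bg 8-neighbor (image border counts as bg)
boundary_pixels <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  p <- matrix(0L, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- mask
  core <- p[2:(nr + 1L), 2:(nc + 1L)]
  allfg <- core == 1L
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    allfg <- allfg & p[2:(nr + 1L) + dr, 2:(nc + 1L) + dc] == 1L
  }
  out <- matrix(0L, nr, nc)
  out[core == 1L & !allfg] <- 1L
  out
}
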