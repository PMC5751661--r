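# Freeman chain-code boundary tracing
#
# Direction numbering (counter-clockwise, image coordinates with row
# increasing downward; x = column, y = -row):
#   0 = east (0,+1)   1 = north-east (-1,+1)   2 = north (-1,0)
#   3 = north-west (-1,-1)   4 = west (0,-1)   5 = south-west (+1,-1)
#   6 = south (+1,0)  7 = south-east (+1,+1)

freeman_moves <- matrix(c(
   0L,  1L,   # 0 E
  -1L,  1L,   # 1 NE
  -1L,  0L,   # 2 N
  -1L, -1L,   # 3 NW
   0L, -1L,   # 4 W
   1L, -1L,   # 5 SW
   1L,  0L,   # 6 S
   1L,  1L    # 7 SE
), ncol = 2, byrow = TRUE)

#' Starting pixel for boundary tracing
#'
#' The foreground pixel minimal in row-major scan order: topmost row first,
#' then leftmost column within it.
#'
#' @param mask 0/1 matrix with at least one foreground pixel.
#' @return Integer `c(row, col)`.
#' @export
find_start_pixel <- function(mask) {
  assert_mask(mask)
  idx <- which(mask == 1)
  nr <- nrow(mask)
  r <- (idx - 1L) %% nr + 1L
  cc <- (idx - 1L) %/% nr + 1L
  rmin <- min(r)
  c(rmin, min(cc[r == rmin]))
}

#' Trace the lesion boundary as a Freeman chain code
#'
#' Moore-neighbor tracing with Jacob's stopping criterion, starting at
#' [find_start_pixel()]. Diagonal moves are augmented with their foreground
#' corner pixel so the traced point set equals the full boundary-pixel set
#' (foreground pixels with a background 8-neighbor); plain Moore tracing
#' skips pixels whose only background contact is diagonal.
#'
#' @param mask 0/1 matrix with one 8-connected foreground component of area
#'   at least 2. If several components are present, the one containing the
#'   start pixel is traced with a warning.
#' @return A `chain_contour`: list with `start` (row, col), `codes` (integers
#'   0-7) and `points` (closed (n+1) x 2 matrix, first row repeated last).
#' @export
trace_chain_code <- function(mask) {
  assert_mask(mask)
  lab <- label_components8(mask)
  start <- find_start_pixel(mask)
  if (max(lab) > 1L) {
    warning("mask has multiple foreground components; tracing the one ",
            "containing the start pixel")
    m <- matrix(0L, nrow(mask), ncol(mask))
    m[lab == lab[start[1], start[2]]] <- 1L
  } else m <- mask
  area <- sum(m)
  if (area < 2L) stop("degenerate contour: component has a single pixel")

  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(FALSE, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- m == 1L
  # clockwise neighbor ring in screen coordinates (row down)
  ring <- matrix(c(0L, 1L,  1L, 1L,  1L, 0L,  1L, -1L,
                   0L, -1L, -1L, -1L, -1L, 0L, -1L, 1L), ncol = 2, byrow = TRUE)
  s <- start + 1L                               # padded coords
  cur <- s
  back <- s + c(0L, -1L)                        # west neighbor, background
  pts <- matrix(0L, 4L * area + 8L, 2L)
  pts[1L, ] <- s
  np <- 1L
  first_next <- NULL
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > 8L * area + 16L) stop("boundary tracing failed to terminate")
    rel <- back - cur
    bi <- which(ring[, 1] == rel[1] & ring[, 2] == rel[2])
    nxt <- NULL
    prev <- back
    for (k in 1:8) {
      cand <- cur + ring[(bi + k - 1L) %% 8L + 1L, ]
      if (p[cand[1], cand[2]]) { nxt <- cand; break }
      prev <- cand
    }
    if (is.null(nxt)) stop("isolated pixel encountered during tracing")
    if (is.null(first_next)) {
      first_next <- nxt
    } else if (all(cur == s) && all(nxt == first_next)) break
    np <- np + 1L
    if (np > nrow(pts)) pts <- rbind(pts, pts)  # defensive growth
    pts[np, ] <- nxt
    back <- prev
    cur <- nxt
  }
  pts <- pts[seq_len(np), , drop = FALSE]

  # augment diagonal moves with foreground corner boundary pixels
  bp <- boundary_pixels(m)
  out <- matrix(0L, 2L * np, 2L)
  no <- 1L
  out[1L, ] <- pts[1L, ]
  for (i in seq_len(np - 1L)) {
    a <- pts[i, ]; b <- pts[i + 1L, ]
    d <- b - a
    if (all(abs(d) == 1L)) {
      for (corner in list(c(a[1], b[2]), c(b[1], a[2]))) {
        cr <- corner[1] - 1L; cc2 <- corner[2] - 1L
        if (cr >= 1L && cr <= nr && cc2 >= 1L && cc2 <= nc &&
            bp[cr, cc2] == 1L) {
          no <- no + 1L
          out[no, ] <- corner
          break
        }
      }
    }
    no <- no + 1L
    out[no, ] <- b
  }
  pts <- out[seq_len(no), , drop = FALSE] - 1L  # back to unpadded coords

  d <- diff(pts)
  codes <- integer(nrow(d))
  for (i in seq_len(nrow(d))) {
    k <- which(freeman_moves[, 1] == d[i, 1] & freeman_moves[, 2] == d[i, 2])
    if (length(k) != 1L) stop("internal error: non-adjacent contour step")
    codes[i] <- k - 1L
  }
  structure(list(start = start, codes = codes, points = pts),
            class = "chain_contour")
}

#' Rebuild boundary points from a Freeman chain code
#'
#' Inverse of the chain encoding: cumulative application of the eight
#' direction offsets from the start pixel.
#'
#' @param start integer `c(row, col)`.
#' @param codes integer vector with values in 0-7.
#' @return (length(codes)+1) x 2 integer matrix of (row, col) points.
#' @export
reconstruct_from_codes <- function(start, codes) {
  codes <- as.integer(codes)
  if (length(codes) && (any(codes < 0L) || any(codes > 7L)))
    stop("codes must be in 0..7")
  steps <- freeman_moves[codes + 1L, , drop = FALSE]
  cbind(cumsum(c(start[1], steps[, 1])), cumsum(c(start[2], steps[, 2])))
}

#' @export
print.chain_contour <- function(x, ...) {
  cat("Freeman chain contour: start (", x$start[1], ",", x$start[2],
      "), ", length(x$codes), " moves\n", sep = "")
  invisible(x)
}

#' Serialize a chain contour to JSON
#' @param chain a `chain_contour`.
#' @param path optional file; if `NULL`, the JSON string is returned.
#' @return JSON string or `path` invisibly.
#' @export
chain_to_json <- function(chain, path = NULL) {
  j <- jsonlite::toJSON(list(start = chain$start, codes = chain$codes),
                        auto_unbox = FALSE, digits = NA)
  if (is.null(path)) return(j)
  writeLines(as.character(j), path)
  invisible(path)
}

#' Read a chain contour from JSON
#' @param path file path or JSON string.
#' @return A `chain_contour` (points rebuilt from start and codes).
#' @export
chain_from_json <- function(path) {
  x <- jsonlite::fromJSON(path)
  pts <- reconstruct_from_codes(as.integer(x$start), as.integer(x$codes))
  structure(list(start = as.integer(x$start), codes = as.integer(x$codes),
                 points = pts), class = "chain_contour")
}
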