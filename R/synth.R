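# synthetic dermoscopy lesions with controllable border abruptness
#
# A star-convex blob is drawn from a radial Fourier perturbation of a disk,
# filled with correlated brown pigment texture and blended into a skin
# background. The border transition is either a hard step (abrupt: pigment
# and texture keep full contrast up to the border, the malignant-like
# phenotype) or a Gaussian-profile fade spanning `edge_width` pixels and
# completing about one edge width inside the border (gradual,
# benign-like): in the peripheral layer both the pigment contrast and the
# texture amplitude are attenuated, as in lesions whose pigment network
# dissolves toward the skin. The fade is wide enough that its per-pixel
# intensity ramp stays below one GLCM quantization bin, so the
# co-occurrence signal is carried by the texture amplitude, not by the
# ramp itself. The class signal is carried only by the edge profile:
# interior texture statistics are matched across classes so downstream
# classification validates specifically the peripheral features.

lesion_pigment <- c(115, 77, 51)      # brown pigment base, 0-255 per channel
lesion_skin <- c(235, 205, 185)       # background skin tone
pigment_channel_gain <- c(1.0, 0.8, 0.6)  # correlated texture per channel
max_feature_radius <- 15              # largest patch radius in the study

#' Specification of one synthetic lesion
#'
#' @param image_size `c(height, width)` in pixels.
#' @param base_radius mean lesion radius in pixels.
#' @param irregularity total amplitude of the radial Fourier perturbation as
#'   a fraction of the radius, in `[0, 0.4]`.
#' @param n_harmonics number of random harmonics (orders 2 ...).
#' @param edge_profile `"abrupt"` (sharp cutoff; labeled malignant) or
#'   `"gradual"` (smooth fade; labeled benign).
#' @param edge_width fade length in pixels for the gradual profile (the
#'   fade is centered half an edge width inside the border and completes
#'   about one edge width deep); the abrupt profile uses a hard step
#'   (width <= 1).
#' @param interior_texture_scale correlation length (Gaussian blur sigma) of
#'   the pigment texture, pixels.
#' @param texture_amplitude texture contrast in intensity units (0-255).
#' @param noise_sd per-pixel Gaussian noise, intensity units.
#' @param seed RNG seed.
#' @return A `lesion_spec` list.
#' @export
lesion_spec <- function(image_size = c(192, 192), base_radius = 72,
                        irregularity = 0.12, n_harmonics = 6,
                        edge_profile = c("abrupt", "gradual"),
                        edge_width = NULL, interior_texture_scale = 3,
                        texture_amplitude = 45, noise_sd = 4, seed = 1) {
  edge_profile <- match.arg(edge_profile)
  if (irregularity < 0 || irregularity > 0.4)
    stop("irregularity must be in [0, 0.4]")
  if (base_radius * (1 - irregularity) <= 4 * max_feature_radius)
    stop("infeasible spec: base_radius * (1 - irregularity) must exceed ",
         4 * max_feature_radius, " px so all patch radii are feasible")
  edge_width <- edge_width %||% if (edge_profile == "abrupt") 1 else 20
  structure(list(image_size = image_size, base_radius = base_radius,
                 irregularity = irregularity, n_harmonics = n_harmonics,
                 edge_profile = edge_profile, edge_width = edge_width,
                 interior_texture_scale = interior_texture_scale,
                 texture_amplitude = texture_amplitude,
                 noise_sd = noise_sd, seed = seed),
            class = "lesion_spec")
}

#' Generate one synthetic lesion image with its mask
#'
#' @param spec a `lesion_spec`.
#' @return List with `image` (h x w x 3 array in `[0, 1]`), `mask` (0/1
#'   matrix of the lesion support), `label` (`"malignant"` for abrupt,
#'   `"benign"` for gradual) and `spec`.
#' @export
generate_lesion <- function(spec) {
  stopifnot(inherits(spec, "lesion_spec"))
  h <- spec$image_size[1]; w <- spec$image_size[2]
  with_seed(spec$seed, {
    k <- 2:(spec$n_harmonics + 1)
    raw <- stats::runif(length(k), 0.2, 1)
    amp <- if (spec$irregularity > 0) raw / sum(raw) * spec$irregularity
           else numeric(length(k))
    phase <- stats::runif(length(k), 0, 2 * pi)
    cr <- (h + 1) / 2; cc <- (w + 1) / 2
    dr <- matrix(seq_len(h) - cr, h, w)
    dc <- matrix(seq_len(w) - cc, h, w, byrow = TRUE)
    theta <- atan2(dc, dr)
    rho <- spec$base_radius *
      (1 + Reduce(`+`, lapply(seq_along(k), function(i)
        amp[i] * cos(k[i] * theta + phase[i])), accumulate = FALSE))
    psi <- sqrt(dr^2 + dc^2) - rho            # radial signed distance
    mask <- matrix(0L, h, w)
    mask[psi <= 0] <- 1L

    tex <- matrix(stats::rnorm(h * w), h, w)
    if (spec$interior_texture_scale > 0)
      tex <- as.matrix(EBImage::gblur(tex, sigma = spec$interior_texture_scale))
    tex <- tex / max(stats::sd(tex), 1e-12)

    alpha <- if (spec$edge_profile == "abrupt") (psi <= 0) * 1
             else stats::pnorm(-(psi + spec$edge_width / 2) *
                               2 / spec$edge_width)
    img <- array(0, dim = c(h, w, 3))
    for (ch in 1:3) {
      lesion <- lesion_pigment[ch] +
        spec$texture_amplitude * pigment_channel_gain[ch] * tex
      plane <- alpha * lesion + (1 - alpha) * lesion_skin[ch]
      if (spec$noise_sd > 0)
        plane <- plane + stats::rnorm(h * w, sd = spec$noise_sd)
      img[, , ch] <- pmin(pmax(plane, 0), 255) / 255
    }
    list(image = img, mask = mask,
         label = if (spec$edge_profile == "abrupt") "malignant" else "benign",
         spec = spec)
  })
}

#' Generate a labeled synthetic cohort
#'
#' Per-lesion specs are jittered around `base_spec` (radius, irregularity,
#' texture scale, noise, edge width) with per-lesion seeds derived from the
#' master seed; the irregularity is clamped so every lesion keeps all patch
#' radii feasible.
#'
#' @param n_benign,n_malignant class counts (>= 1).
#' @param base_spec template `lesion_spec` (its `edge_profile` is
#'   overridden per class).
#' @param seed master seed.
#' @param out_dir optional directory; when given, writes `images/*.png`,
#'   `masks/*.png`, `labels.csv` and `specs.json`.
#' @return A `synthetic_cohort`: list with `ids`, `images`, `masks`,
#'   `labels`, `specs`.
#' @export
generate_cohort <- function(n_benign, n_malignant,
                            base_spec = lesion_spec(), seed = 1,
                            out_dir = NULL) {
  stopifnot(n_benign >= 1, n_malignant >= 1)
  n <- n_benign + n_malignant
  profiles <- c(rep("gradual", n_benign), rep("abrupt", n_malignant))
  jit <- with_seed(seed, list(
    seeds = sample.int(.Machine$integer.max - 1L, n),
    radius = stats::runif(n, 0.92, 1.08),
    irr = stats::runif(n, -0.03, 0.03),
    texscale = stats::runif(n, 0.8, 1.2),
    noise = stats::runif(n, 0.8, 1.2),
    edgew = stats::runif(n, 0.8, 1.2)))
  ids <- sprintf("lesion_%04d", seq_len(n))
  # gradual fade width: the template's value if it is a gradual spec,
  # otherwise the gradual default (an abrupt template's width is the step)
  gradual_ew <- if (base_spec$edge_profile == "gradual")
    base_spec$edge_width else 20
  lesions <- vector("list", n)
  for (i in seq_len(n)) {
    radius <- base_spec$base_radius * jit$radius[i]
    irr <- min(max(base_spec$irregularity + jit$irr[i], 0),
               1 - (4 * max_feature_radius + 2) / radius)
    sp <- lesion_spec(
      image_size = base_spec$image_size, base_radius = radius,
      irregularity = irr, n_harmonics = base_spec$n_harmonics,
      edge_profile = profiles[i],
      edge_width = if (profiles[i] == "abrupt") 1
                   else gradual_ew * jit$edgew[i],
      interior_texture_scale =
        base_spec$interior_texture_scale * jit$texscale[i],
      texture_amplitude = base_spec$texture_amplitude,
      noise_sd = base_spec$noise_sd * jit$noise[i],
      seed = jit$seeds[i])
    lesions[[i]] <- generate_lesion(sp)
  }
  cohort <- structure(list(
    ids = ids,
    images = lapply(lesions, `[[`, "image"),
    masks = lapply(lesions, `[[`, "mask"),
    labels = vapply(lesions, `[[`, character(1), "label"),
    specs = lapply(lesions, `[[`, "spec")), class = "synthetic_cohort")
  if (!is.null(out_dir)) write_cohort(cohort, out_dir)
  cohort
}

#' Write a cohort to the standard directory layout
#' @param cohort a `synthetic_cohort`.
#' @param out_dir output directory (`images/`, `masks/`, `labels.csv`,
#'   `specs.json`).
#' @return `out_dir`, invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  dir.create(file.path(out_dir, "images"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out_dir, "masks"), recursive = TRUE,
             showWarnings = FALSE)
  for (i in seq_along(cohort$ids)) {
    png::writePNG(cohort$images[[i]],
                  file.path(out_dir, "images", paste0(cohort$ids[i], ".png")))
    write_mask(cohort$masks[[i]],
               file.path(out_dir, "masks", paste0(cohort$ids[i], ".png")))
  }
  utils::write.csv(data.frame(id = cohort$ids, label = cohort$labels),
                   file.path(out_dir, "labels.csv"), row.names = FALSE)
  specs <- lapply(cohort$specs, function(s) unclass(s))
  names(specs) <- cohort$ids
  jsonlite::write_json(specs, file.path(out_dir, "specs.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Read a cohort from the standard directory layout
#' @param dir directory with `images/`, `masks/` and `labels.csv`.
#' @return A `synthetic_cohort`-shaped list (specs absent).
#' @export
read_cohort <- function(dir) {
  lab <- utils::read.csv(file.path(dir, "labels.csv"),
                         stringsAsFactors = FALSE)
  images <- lapply(lab$id, function(id) {
    img <- png::readPNG(file.path(dir, "images", paste0(id, ".png")))
    if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
    img[, , 1:3, drop = FALSE]
  })
  masks <- lapply(lab$id, function(id)
    read_mask(file.path(dir, "masks", paste0(id, ".png"))))
  structure(list(ids = lab$id, images = images, masks = masks,
                 labels = lab$label, specs = NULL),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic lesion cohort:", length(x$ids), "lesions (",
      sum(x$labels == "benign"), "benign,",
      sum(x$labels == "malignant"), "malignant )\n")
  invisible(x)
}
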