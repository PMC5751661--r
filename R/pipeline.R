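# end-to-end orchestration: mask -> chain code -> contraction -> features
# -> cross-validated classification

#' Pipeline configuration
#'
#' @param radii patch radii to extract (pixels).
#' @param color_spaces color spaces to extract.
#' @param glcm_levels,glcm_offset GLCM parameters.
#' @param spacing_factor patch spacing as a multiple of the radius.
#' @param contraction_method `"distance"` (default, exact constant-speed
#'   offset) or `"pde"` (time-stepped evolution).
#' @param dt level-set time step for the PDE method.
#' @param classifiers classifier kinds to evaluate.
#' @param n_runs,n_folds cross-validation protocol.
#' @param seed master seed; all randomness (cohort generation, fold splits,
#'   weight initialization) derives from it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(radii = c(5, 7, 10, 15),
                            color_spaces = c("RGB", "HSV", "RGB+HSV"),
                            glcm_levels = 32, glcm_offset = c(0L, 1L),
                            spacing_factor = 1,
                            contraction_method = c("distance", "pde"),
                            dt = 0.5,
                            classifiers = c("mlp_single", "mlp_multi", "svm"),
                            n_runs = 10, n_folds = 10, seed = 1) {
  structure(list(radii = radii, color_spaces = color_spaces,
                 glcm_levels = glcm_levels, glcm_offset = glcm_offset,
                 spacing_factor = spacing_factor,
                 contraction_method = match.arg(contraction_method),
                 dt = dt, classifiers = classifiers,
                 n_runs = n_runs, n_folds = n_folds, seed = seed),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#' @param path config file; keys as in [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is required to read YAML configs")
    yaml::read_yaml(path)
  } else jsonlite::fromJSON(path)
  do.call(pipeline_config, cfg)
}

#' Extract peripheral features for a whole cohort
#'
#' Runs mask preprocessing, border contraction (with `distance_L = 2 r`)
#' and feature extraction for every lesion, radius and color space.
#' Per-lesion failures (lesion too small for a radius, over-contraction)
#' are logged and skipped, never fatal.
#'
#' @param input a `synthetic_cohort` or a directory with `images/`,
#'   `masks/` and `labels.csv`.
#' @param config a `pipeline_config`.
#' @param out_csv optional path for the feature CSV.
#' @param manifest optional path for a JSON manifest (config, config hash,
#'   per-image status).
#' @return Feature data.frame (see [features_to_table()]), invisibly `NULL`
#'   rows for failed combinations.
#' @export
run_extract <- function(input, config = pipeline_config(), out_csv = NULL,
                        manifest = NULL) {
  cohort <- if (inherits(input, "synthetic_cohort")) input
            else read_cohort(input)
  fvs <- list(); ids <- character(0)
  status <- list()
  for (i in seq_along(cohort$ids)) {
    id <- cohort$ids[i]
    mask <- preprocess_mask(cohort$masks[[i]])
    img <- cohort$images[[i]]
    st <- character(0)
    for (r in config$radii) {
      res <- tryCatch(
        contract_border(mask, distance_L = 2 * r, dt = config$dt,
                        method = config$contraction_method),
        error = function(e) e)
      if (inherits(res, "error")) {
        message("[", id, "] radius ", r, " skipped: ", conditionMessage(res))
        st <- c(st, sprintf("radius %g skipped: %s", r,
                            conditionMessage(res)))
        next
      }
      for (cs in config$color_spaces) {
        fv <- tryCatch(
          extract_features(img, res, radius_r = r, color_space = cs,
                           glcm_levels = config$glcm_levels,
                           glcm_offset = config$glcm_offset,
                           spacing_factor = config$spacing_factor,
                           label = cohort$labels[i]),
          error = function(e) e)
        if (inherits(fv, "error")) {
          message("[", id, "] radius ", r, " ", cs, " skipped: ",
                  conditionMessage(fv))
          st <- c(st, sprintf("radius %g %s skipped: %s", r, cs,
                              conditionMessage(fv)))
          next
        }
        fvs[[length(fvs) + 1L]] <- fv
        ids <- c(ids, id)
      }
    }
    status[[id]] <- if (length(st)) st else "ok"
  }
  if (length(fvs) == 0) stop("no features could be extracted")
  tab <- features_to_table(fvs, ids)
  if (!is.null(out_csv)) utils::write.csv(tab, out_csv, row.names = FALSE)
  if (!is.null(manifest)) {
    jsonlite::write_json(
      list(config = unclass(config), config_hash = config_hash(config),
           status = status),
      manifest, auto_unbox = TRUE, digits = NA)
  }
  tab
}

#' Cross-validate classifiers over extracted features
#'
#' Runs [cross_validate()] for every requested (radius, color space,
#' classifier) combination present in the feature table and ranks the
#' combinations by mean f1.
#'
#' @param features feature data.frame from [run_extract()] or a CSV path.
#' @param labels optional data.frame `id, label` (or CSV path); defaults to
#'   the `label` column of `features`.
#' @param config a `pipeline_config`.
#' @param out_json optional path for the JSON report.
#' @return A `pipeline_report`: list with `results` (one row per
#'   combination with the five metrics), `best` (top-f1 combination) and
#'   `reports` (the underlying `eval_report`s).
#' @export
run_evaluate <- function(features, labels = NULL,
                         config = pipeline_config(), out_json = NULL) {
  if (is.character(features))
    features <- utils::read.csv(features, stringsAsFactors = FALSE,
                                check.names = FALSE)
  if (is.character(labels))
    labels <- utils::read.csv(labels, stringsAsFactors = FALSE)
  if (!is.null(labels)) {
    features$label <- labels$label[match(features$id, labels$id)]
    if (anyNA(features$label)) stop("label join failed for some ids")
  }
  combos <- unique(features[, c("radius", "color_space")])
  combos <- combos[combos$radius %in% config$radii &
                   combos$color_space %in% config$color_spaces, ,
                   drop = FALSE]
  if (nrow(combos) == 0) stop("no requested (radius, color space) present")
  seeds <- derive_seeds(config$seed,
                        nrow(combos) * length(config$classifiers))
  rows <- list(); reports <- list()
  k <- 0L
  for (ci in seq_len(nrow(combos))) {
    sub <- features[features$radius == combos$radius[ci] &
                    features$color_space == combos$color_space[ci], ,
                    drop = FALSE]
    x <- as.matrix(sub[, feature_names(combos$color_space[ci]), drop = FALSE])
    y <- sub$label
    if (length(unique(y)) < 2) stop("labels contain a single class")
    for (cl in config$classifiers) {
      k <- k + 1L
      cc <- classifier_config(kind = cl, n_runs = config$n_runs,
                              n_folds = config$n_folds, seed = seeds[k])
      rep_k <- cross_validate(x, y, cc)
      key <- sprintf("r%g_%s_%s", combos$radius[ci],
                     combos$color_space[ci], cl)
      reports[[key]] <- rep_k
      rows[[key]] <- data.frame(radius = combos$radius[ci],
                                color_space = combos$color_space[ci],
                                classifier = cl,
                                t(rep_k$metrics))
    }
  }
  results <- do.call(rbind, rows)
  results <- results[order(-results$f1), ]
  rownames(results) <- NULL
  report <- structure(list(results = results,
                           best = results[1, , drop = FALSE],
                           reports = reports,
                           config = unclass(config),
                           config_hash = config_hash(config)),
                      class = "pipeline_report")
  if (!is.null(out_json)) {
    jsonlite::write_json(list(config = unclass(config),
                              config_hash = report$config_hash,
                              results = results,
                              best = report$best),
                         out_json, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Classification of border abruptness features",
      "(combinations ranked by mean f1):\n")
  df <- x$results
  df[, c("precision", "recall", "sensitivity", "specificity", "f1")] <-
    round(df[, c("precision", "recall", "sensitivity", "specificity",
                 "f1")], 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Write an overlay PNG of the original and contracted borders
#'
#' Original traced boundary in green, contracted polyline(s) in red, over
#' the lesion image.
#'
#' @param image h x w x 3 array in `[0, 1]`.
#' @param result a `contraction_result`.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_overlay <- function(image, result, path) {
  img <- image
  paint <- function(img, pts, col) {
    pts <- round(pts)
    pts <- pts[pts[, 1] >= 1 & pts[, 1] <= dim(img)[1] &
               pts[, 2] >= 1 & pts[, 2] <= dim(img)[2], , drop = FALSE]
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[pts] <- col[ch]
      img[, , ch] <- plane
    }
    img
  }
  img <- paint(img, result$original$points, c(0, 1, 0))
  for (curve in result$contracted) {
    dense <- resample_polyline(curve, 0.5)
    img <- paint(img, dense, c(1, 0, 0))
  }
  png::writePNG(img, path)
  invisible(path)
}
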