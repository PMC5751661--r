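# benign/malignant classifiers and repeated stratified cross-validation
#
# Three classifiers: a single-hidden-layer perceptron (ReLU, sigmoid
# output), a fully connected multi-hidden-layer network (ReLU hidden
# layers, softmax output over one-hot targets), and a polynomial-kernel
# SVM. The networks are trained with full-batch plain gradient descent on
# the summed cross-entropy; training stops after `max_iterations` epochs or
# when the epoch-to-epoch loss improvement drops to `stop_tolerance`.

#' Classifier configuration
#'
#' Defaults mirror the reference protocol: learning rate 0.001, at most
#' 1000 epochs, stop tolerance 0.001, 4 hidden layers of 4 nodes for the
#' multi-layer network, hidden width equal to the input width for the
#' single-hidden-layer perceptron, polynomial kernel of order 3 with a very
#' large box constraint for the SVM, standardized inputs, stratified
#' 10-fold cross-validation repeated 10 times.
#'
#' @param kind `"mlp_single"`, `"mlp_multi"` or `"svm"`.
#' @param learning_rate gradient-descent step size.
#' @param max_iterations maximum training epochs.
#' @param hidden_layers hidden layer count for `mlp_multi`.
#' @param hidden_nodes nodes per hidden layer for `mlp_multi`; `NULL` for
#'   `mlp_single` means input width.
#' @param svm_degree polynomial kernel order.
#' @param svm_cost soft-margin box constraint (large = near-hard margin).
#' @param stop_tolerance minimal epoch-to-epoch loss improvement.
#' @param n_runs,n_folds cross-validation repetitions and folds.
#' @param standardize center/scale features on the training data.
#' @param seed master seed for fold splits and weight initialization.
#' @return A `classifier_config` list.
#' @export
classifier_config <- function(kind = c("mlp_multi", "mlp_single", "svm"),
                              learning_rate = 0.001, max_iterations = 1000,
                              hidden_layers = 4, hidden_nodes = 4,
                              svm_degree = 3, svm_cost = 1e6,
                              stop_tolerance = 0.001,
                              n_runs = 10, n_folds = 10,
                              standardize = TRUE, seed = 1) {
  structure(list(kind = match.arg(kind), learning_rate = learning_rate,
                 max_iterations = max_iterations,
                 hidden_layers = hidden_layers, hidden_nodes = hidden_nodes,
                 activation = "relu", svm_kernel = "polynomial",
                 svm_degree = svm_degree, svm_cost = svm_cost,
                 stop_tolerance = stop_tolerance, n_runs = n_runs,
                 n_folds = n_folds, standardize = standardize, seed = seed),
            class = "classifier_config")
}

as_binary_labels <- function(y) {
  if (is.factor(y)) y <- as.character(y)
  if (is.character(y)) {
    bad <- setdiff(unique(y), c("benign", "malignant"))
    if (length(bad)) stop("unknown labels: ", paste(bad, collapse = ", "))
    y <- as.integer(y == "malignant")        # benign -> 0, malignant -> 1
  }
  if (!all(y %in% c(0, 1))) stop("labels must be 0/1 or benign/malignant")
  as.integer(y)
}

standardize_fit <- function(x) {
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  sd[!is.finite(sd) | sd < 1e-12] <- 1
  list(center = mu, scale = sd)
}

standardize_apply <- function(x, sc) {
  sweep(sweep(x, 2, sc$center, "-"), 2, sc$scale, "/")
}

he_init <- function(nin, nout) {
  matrix(stats::rnorm(nin * nout, sd = sqrt(2 / nin)), nin, nout)
}

#' Train the single-hidden-layer perceptron
#'
#' Input -> hidden (ReLU, width = input width unless overridden) -> sigmoid
#' output; summed binary cross-entropy minimized by full-batch gradient
#' descent.
#'
#' @param x numeric feature matrix (rows = samples).
#' @param y labels: 0/1 or `"benign"`/`"malignant"`.
#' @param learning_rate,max_iterations,stop_tolerance training protocol.
#' @param hidden_nodes hidden width; `NULL` = `ncol(x)`.
#' @param standardize center/scale `x` (stored in the model).
#' @param seed RNG seed for weight initialization.
#' @return An `abrupt_mlp` scoring model.
#' @export
train_mlp_single <- function(x, y, learning_rate = 0.001,
                             max_iterations = 1000, stop_tolerance = 0.001,
                             hidden_nodes = NULL, standardize = TRUE,
                             seed = NULL) {
  x <- as.matrix(x)
  y <- as_binary_labels(y)
  if (length(unique(y)) < 2) stop("training set contains a single class")
  sc <- if (standardize) standardize_fit(x) else NULL
  if (!is.null(sc)) x <- standardize_apply(x, sc)
  d <- ncol(x)
  h <- hidden_nodes %||% d
  with_seed(seed, {
    W1 <- he_init(d, h); b1 <- rep(0.01, h)
    w2 <- he_init(h, 1L); b2 <- 0
    prev <- Inf
    for (epoch in seq_len(max_iterations)) {
      Z1 <- sweep(x %*% W1, 2, b1, "+")
      A1 <- pmax(Z1, 0)
      z2 <- drop(A1 %*% w2) + b2
      p <- 1 / (1 + exp(-z2))
      pc <- pmin(pmax(p, 1e-12), 1 - 1e-12)
      loss <- -sum(y * log(pc) + (1 - y) * log(1 - pc))
      if (abs(prev - loss) <= stop_tolerance) break
      prev <- loss
      dz2 <- p - y
      dW2 <- crossprod(A1, dz2)
      dA1 <- outer(dz2, drop(w2))
      dZ1 <- dA1 * (Z1 > 0)
      W1 <- W1 - learning_rate * crossprod(x, dZ1)
      b1 <- b1 - learning_rate * colSums(dZ1)
      w2 <- w2 - learning_rate * dW2
      b2 <- b2 - learning_rate * sum(dz2)
    }
    structure(list(kind = "mlp_single", W1 = W1, b1 = b1, w2 = w2, b2 = b2,
                   scaling = sc, epochs = epoch, loss = loss),
              class = "abrupt_mlp")
  })
}

#' Train the fully connected multi-hidden-layer network
#'
#' `hidden_layers` ReLU layers of `hidden_nodes` each, softmax output over
#' the two one-hot classes (benign = (1,0), malignant = (0,1)); summed
#' cross-entropy, full-batch gradient descent, same stopping rule as
#' [train_mlp_single()].
#'
#' @inheritParams train_mlp_single
#' @param hidden_layers,hidden_nodes architecture (default 4 x 4).
#' @return An `abrupt_mlp` class-probability model.
#' @export
train_mlp_multi <- function(x, y, learning_rate = 0.001,
                            max_iterations = 1000, stop_tolerance = 0.001,
                            hidden_layers = 4, hidden_nodes = 4,
                            standardize = TRUE, seed = NULL) {
  x <- as.matrix(x)
  y <- as_binary_labels(y)
  if (length(unique(y)) < 2) stop("training set contains a single class")
  sc <- if (standardize) standardize_fit(x) else NULL
  if (!is.null(sc)) x <- standardize_apply(x, sc)
  n <- nrow(x)
  Y <- cbind(1 - y, y)                       # one-hot: benign (1,0)
  widths <- c(ncol(x), rep(hidden_nodes, hidden_layers), 2L)
  L <- length(widths) - 1L
  with_seed(seed, {
    W <- lapply(seq_len(L), function(l) he_init(widths[l], widths[l + 1]))
    # small positive hidden biases reduce dead-ReLU units at initialization
    b <- lapply(seq_len(L), function(l)
      if (l < L) rep(0.01, widths[l + 1]) else numeric(widths[l + 1]))
    prev <- Inf
    for (epoch in seq_len(max_iterations)) {
      A <- vector("list", L + 1L); Z <- vector("list", L)
      A[[1]] <- x
      for (l in seq_len(L)) {
        Z[[l]] <- sweep(A[[l]] %*% W[[l]], 2, b[[l]], "+")
        A[[l + 1]] <- if (l < L) pmax(Z[[l]], 0) else {
          e <- exp(Z[[l]] - apply(Z[[l]], 1, max))
          e / rowSums(e)
        }
      }
      P <- pmin(pmax(A[[L + 1]], 1e-12), 1)
      loss <- -sum(Y * log(P))
      if (abs(prev - loss) <= stop_tolerance) break
      prev <- loss
      delta <- A[[L + 1]] - Y
      for (l in rev(seq_len(L))) {
        gW <- crossprod(A[[l]], delta)
        gb <- colSums(delta)
        if (l > 1) delta <- (delta %*% t(W[[l]])) * (Z[[l - 1]] > 0)
        W[[l]] <- W[[l]] - learning_rate * gW
        b[[l]] <- b[[l]] - learning_rate * gb
      }
    }
    structure(list(kind = "mlp_multi", W = W, b = b, scaling = sc,
                   epochs = epoch, loss = loss),
              class = "abrupt_mlp")
  })
}

#' Predict from a trained network
#'
#' @param object an `abrupt_mlp`.
#' @param newdata feature matrix.
#' @param type `"class"` (0/1) or `"prob"` (probability of the malignant
#'   class; for `mlp_multi` this is the softmax column for malignant).
#' @param ... unused.
#' @return Numeric vector.
#' @export
predict.abrupt_mlp <- function(object, newdata, type = c("class", "prob"),
                               ...) {
  type <- match.arg(type)
  x <- as.matrix(newdata)
  if (!is.null(object$scaling)) x <- standardize_apply(x, object$scaling)
  if (object$kind == "mlp_single") {
    A1 <- pmax(sweep(x %*% object$W1, 2, object$b1, "+"), 0)
    p <- 1 / (1 + exp(-(drop(A1 %*% object$w2) + object$b2)))
  } else {
    a <- x
    L <- length(object$W)
    for (l in seq_len(L)) {
      z <- sweep(a %*% object$W[[l]], 2, object$b[[l]], "+")
      a <- if (l < L) pmax(z, 0) else {
        e <- exp(z - apply(z, 1, max))
        e / rowSums(e)
      }
    }
    p <- a[, 2]
  }
  if (type == "prob") p else as.integer(p > 0.5)
}

#' Class probabilities of the multi-layer network
#'
#' Softmax output over (benign, malignant) for every sample.
#'
#' @param object an `abrupt_mlp` of kind `mlp_multi`.
#' @param newdata feature matrix.
#' @return n x 2 matrix with columns `benign`, `malignant`, rows summing
#'   to 1.
#' @export
predict_proba <- function(object, newdata) {
  stopifnot(inherits(object, "abrupt_mlp"))
  p <- predict(object, newdata, type = "prob")
  cbind(benign = 1 - p, malignant = p)
}

#' Polynomial kernel value
#'
#' `(gamma * <x, y> + coef0)^degree`, the kernel used by the SVM.
#'
#' @param x,y numeric vectors.
#' @param degree polynomial order.
#' @param gamma scale; default `1/length(x)`.
#' @param coef0 additive constant.
#' @return Scalar kernel value.
#' @export
poly_kernel <- function(x, y, degree = 3, gamma = 1 / length(x), coef0 = 0) {
  (gamma * sum(x * y) + coef0)^degree
}

#' Train the polynomial-kernel SVM
#'
#' Degree-3 polynomial kernel on standardized features with a very large
#' box constraint (near-hard margin), via [e1071::svm()].
#'
#' @inheritParams train_mlp_single
#' @param degree polynomial order.
#' @param cost box constraint.
#' @param gamma kernel scale; default `1/ncol(x)`.
#' @param coef0 kernel offset.
#' @return An `abrupt_svm` decision model.
#' @export
train_svm <- function(x, y, degree = 3, cost = 1e6, gamma = NULL, coef0 = 0,
                      standardize = TRUE) {
  x <- as.matrix(x)
  y <- as_binary_labels(y)
  if (length(unique(y)) < 2) stop("training set contains a single class")
  sc <- if (standardize) standardize_fit(x) else NULL
  if (!is.null(sc)) x <- standardize_apply(x, sc)
  fit <- e1071::svm(x, factor(y, levels = c(0, 1)), kernel = "polynomial",
                    degree = degree, gamma = gamma %||% (1 / ncol(x)),
                    coef0 = coef0, cost = cost, scale = FALSE)
  structure(list(kind = "svm", fit = fit, scaling = sc),
            class = "abrupt_svm")
}

#' @export
predict.abrupt_svm <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  if (!is.null(object$scaling)) x <- standardize_apply(x, object$scaling)
  as.integer(as.character(predict(object$fit, x)))
}

#' Evaluation metrics from a binary confusion matrix
#'
#' Malignant is the positive class. Precision and recall are
#' macro-averages over the two classes; sensitivity is the malignant-class
#' recall and specificity the benign-class recall; f1 is the harmonic mean
#' of the macro precision and recall. Undefined ratios (empty denominators)
#' yield `NA`.
#'
#' @param tp,fp,fn,tn confusion counts (malignant positive).
#' @return Named numeric: precision, recall, sensitivity, specificity, f1.
#' @export
metrics_from_confusion <- function(tp, fp, fn, tn) {
  div <- function(a, b) if (b > 0) a / b else NA_real_
  prec_m <- div(tp, tp + fp)
  prec_b <- div(tn, tn + fn)
  sens <- div(tp, tp + fn)
  spec <- div(tn, tn + fp)
  precision <- mean(c(prec_m, prec_b))
  recall <- mean(c(sens, spec))
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  c(precision = precision, recall = recall, sensitivity = sens,
    specificity = spec, f1 = f1)
}

train_by_config <- function(x, y, config, seed) {
  switch(config$kind,
    mlp_single = train_mlp_single(x, y,
      learning_rate = config$learning_rate,
      max_iterations = config$max_iterations,
      stop_tolerance = config$stop_tolerance,
      standardize = config$standardize, seed = seed),
    mlp_multi = train_mlp_multi(x, y,
      learning_rate = config$learning_rate,
      max_iterations = config$max_iterations,
      stop_tolerance = config$stop_tolerance,
      hidden_layers = config$hidden_layers,
      hidden_nodes = config$hidden_nodes,
      standardize = config$standardize, seed = seed),
    svm = train_svm(x, y, degree = config$svm_degree, cost = config$svm_cost,
                    standardize = config$standardize))
}

#' Repeated stratified k-fold cross-validation
#'
#' Stratified `n_folds`-fold cross-validation repeated `n_runs` times with
#' distinct derived seeds; per-fold confusion matrices are converted to
#' metrics and averaged over all runs and folds.
#'
#' @param x feature matrix.
#' @param y labels (0/1 or benign/malignant).
#' @param config a `classifier_config`.
#' @return An `eval_report`: list with `metrics` (mean precision, recall,
#'   sensitivity, specificity, f1), `per_fold` (data.frame of confusion
#'   counts and metrics per run x fold) and `config`.
#' @export
cross_validate <- function(x, y, config = classifier_config()) {
  x <- as.matrix(x)
  y <- as_binary_labels(y)
  n <- length(y)
  if (n < config$n_folds) stop("need at least n_folds samples")
  if (min(table(y)) < config$n_folds)
    stop("each class needs at least n_folds members for stratified folds")
  run_seeds <- derive_seeds(config$seed, config$n_runs * (config$n_folds + 1))
  rows <- list()
  si <- 0L
  for (run in seq_len(config$n_runs)) {
    si <- si + 1L
    folds <- integer(n)
    with_seed(run_seeds[si], {
      for (cl in c(0L, 1L)) {
        idx <- sample(which(y == cl))
        folds[idx] <- rep_len(seq_len(config$n_folds), length(idx))
      }
    })
    for (fold in seq_len(config$n_folds)) {
      si <- si + 1L
      test <- folds == fold
      model <- train_by_config(x[!test, , drop = FALSE], y[!test], config,
                               seed = run_seeds[si])
      pred <- predict(model, x[test, , drop = FALSE])
      tp <- sum(pred == 1 & y[test] == 1)
      fp <- sum(pred == 1 & y[test] == 0)
      fn <- sum(pred == 0 & y[test] == 1)
      tn <- sum(pred == 0 & y[test] == 0)
      rows[[length(rows) + 1L]] <- data.frame(run = run, fold = fold,
        tp = tp, fp = fp, fn = fn, tn = tn,
        t(metrics_from_confusion(tp, fp, fn, tn)))
    }
  }
  per_fold <- do.call(rbind, rows)
  metric_cols <- c("precision", "recall", "sensitivity", "specificity", "f1")
  metrics <- colMeans(per_fold[metric_cols], na.rm = TRUE)
  structure(list(metrics = metrics, per_fold = per_fold, config = config,
                 aggregation = "per-fold average"),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Cross-validated evaluation (", x$config$kind, ", ",
      x$config$n_runs, " x ", x$config$n_folds, "-fold):\n", sep = "")
  df <- as.data.frame(t(round(x$metrics, 4)))
  names(df) <- c("Precision", "Recall", "Sensitivity", "Specificity",
                 "F1-Score")
  print(df, row.names = FALSE)
  invisible(x)
}
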