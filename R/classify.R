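# Three-class SVM recording classifier.
#
# One-vs-rest RBF support vector machines over standardized wavelet-packet
# features. The binary machines come from e1071/libsvm; the one-vs-rest
# wrapper, feature standardization, inverse-frequency class weighting and the
# serializable model bundle are defined here. Classifier outputs are always
# one of crackle/wheeze/normal; `indeterminate` is a human-rater-only value.

MODEL_FORMAT <- "auscultr_model"
MODEL_VERSION <- 1L

# features: data.frame with recording_id + numeric columns, or a plain
# numeric matrix/df; returns list(x = matrix, ids)
as_feature_matrix <- function(features) {
  if (is.data.frame(features) && "recording_id" %in% names(features)) {
    ids <- features$recording_id
    x <- as.matrix(features[, setdiff(names(features), "recording_id"),
                            drop = FALSE])
  } else {
    x <- as.matrix(features)
    ids <- rownames(x)
  }
  storage.mode(x) <- "double"
  if (!is.null(ids)) rownames(x) <- ids
  list(x = x, ids = ids)
}

#' Train the three-class breath-sound SVM
#'
#' One-vs-rest SVMs with an RBF kernel on standardized features
#' (standardization statistics are stored in the bundle and reapplied at
#' prediction time). Class imbalance is handled with inverse-frequency class
#' weights.
#'
#' @param features data.frame with a `recording_id` column plus numeric
#'   feature columns (see [extract_features()]), or a numeric matrix with
#'   recording ids as row names.
#' @param labels named character vector or data.frame
#'   (`recording_id`,`label`) mapping every recording to
#'   `crackle`/`wheeze`/`normal`. `indeterminate` labels are an error.
#' @param cost SVM regularization parameter C (default 1).
#' @param gamma RBF kernel width (default `1/n_features`).
#' @param seed integer seed recorded in the bundle and applied during
#'   training for exact reproducibility.
#' @return a `breath_model` bundle: binary machines, feature names, class
#'   order, standardization statistics and training metadata (seed,
#'   hyperparameters, corpus fingerprint).
#' @export
train_classifier <- function(features, labels, cost = 1, gamma = NULL,
                             seed = 1L) {
  fm <- as_feature_matrix(features)
  if (is.data.frame(labels)) {
    lab <- stats::setNames(labels$label, labels$recording_id)
  } else lab <- labels
  if (!is.null(fm$ids)) {
    missing_ids <- setdiff(fm$ids, names(lab))
    if (length(missing_ids))
      stop("no label for: ", paste(head(missing_ids, 5), collapse = ", "))
    y <- unname(lab[fm$ids])
  } else {
    if (length(lab) != nrow(fm$x)) stop("labels do not match feature rows")
    y <- unname(lab)
  }
  if (any(y == "indeterminate"))
    stop("training labels may not contain 'indeterminate'")
  bad <- setdiff(unique(y), BREATH_CLASSES)
  if (length(bad)) stop("unknown labels: ", paste(bad, collapse = ", "))
  classes <- BREATH_CLASSES[BREATH_CLASSES %in% unique(y)]
  if (length(classes) < 2) stop("training needs at least two classes")

  x <- fm$x
  if (is.null(gamma)) gamma <- 1 / ncol(x)
  mu <- colMeans(x)
  sds <- apply(x, 2, sd)
  sds[sds == 0 | !is.finite(sds)] <- 1
  xs <- scale(x, center = mu, scale = sds)

  machines <- with_seed(seed, lapply(classes, function(cls) {
    yy <- factor(ifelse(y == cls, "pos", "neg"), levels = c("pos", "neg"))
    n_pos <- sum(yy == "pos")
    wts <- c(pos = length(yy) / (2 * n_pos),
             neg = length(yy) / (2 * (length(yy) - n_pos)))
    e1071::svm(xs, yy, kernel = "radial", cost = cost, gamma = gamma,
               scale = FALSE, class.weights = wts)
  }))
  names(machines) <- classes

  structure(list(machines = machines,
                 feature_names = colnames(x),
                 classes = classes,
                 center = mu, scale = sds,
                 metadata = list(seed = as.integer(seed), cost = cost,
                                 gamma = gamma, n_train = nrow(x),
                                 corpus_fingerprint = hash_object(
                                   if (is.null(fm$ids)) list(y) else
                                     list(sort(fm$ids), y[order(fm$ids)])))),
            class = "breath_model")
}

#' @export
print.breath_model <- function(x, ...) {
  cat(sprintf(
    "<breath_model: %d features, classes %s, n_train %d, C=%g gamma=%g>\n",
    length(x$feature_names), paste(x$classes, collapse = "/"),
    x$metadata$n_train, x$metadata$cost, x$metadata$gamma))
  invisible(x)
}

#' Predict recording labels
#'
#' Each one-vs-rest machine produces a decision value; the class with the
#' largest value wins. Feature names must match the training feature names
#' exactly (same set, any order).
#'
#' @param model a `breath_model`.
#' @param features as in [train_classifier()]: data.frame with
#'   `recording_id`, a named numeric vector for a single recording, or a
#'   matrix.
#' @return character vector of predicted labels (never `indeterminate`),
#'   named by recording id when ids are available.
#' @export
predict_labels <- function(model, features) {
  stopifnot(inherits(model, "breath_model"))
  if (is.numeric(features) && is.null(dim(features)))
    features <- matrix(features, nrow = 1,
                       dimnames = list(NULL, names(features)))
  fm <- as_feature_matrix(features)
  x <- fm$x
  if (nrow(x) == 0) return(character(0))
  if (is.null(colnames(x)) || !setequal(colnames(x), model$feature_names))
    stop("feature names do not match the training feature names")
  x <- x[, model$feature_names, drop = FALSE]
  xs <- scale(x, center = model$center, scale = model$scale)
  dec <- vapply(model$classes, function(cls) {
    p <- predict(model$machines[[cls]], xs, decision.values = TRUE)
    dv <- attr(p, "decision.values")[, 1]
    # orient so larger means more likely the target class
    if (grepl("^pos/", colnames(attr(p, "decision.values"))[1])) dv else -dv
  }, numeric(nrow(xs)))
  dec <- matrix(dec, nrow = nrow(xs),
                dimnames = list(fm$ids, model$classes))
  out <- model$classes[max.col(dec, ties.method = "first")]
  if (!is.null(fm$ids)) names(out) <- fm$ids
  out
}

#' Save / load a model bundle
#'
#' The bundle is written as a single versioned file; loading verifies the
#' format marker and version and fails loudly on mismatch or truncation.
#'
#' @param model a `breath_model`.
#' @param path file path.
#' @return `path` invisibly (save); the `breath_model` (load).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "breath_model"))
  saveRDS(list(format = MODEL_FORMAT, version = MODEL_VERSION,
               model = model), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- tryCatch(readRDS(path),
                  error = function(e) stop("cannot read model file: ",
                                           conditionMessage(e)))
  if (!is.list(obj) || !identical(obj$format, MODEL_FORMAT))
    stop("not an auscultr model bundle: ", path)
  if (!identical(obj$version, MODEL_VERSION))
    stop("model bundle version ", obj$version,
         " not supported (expected ", MODEL_VERSION, ")")
  obj$model
}

#' Stratified k-fold cross-validation
#'
#' @param features,labels as in [train_classifier()].
#' @param k number of folds (default 5).
#' @param seed seed controlling fold assignment and training.
#' @param ... passed to [train_classifier()].
#' @return list with `predictions` (named character vector over all
#'   recordings), `accuracy`, and `fold` assignments.
#' @export
cross_validate <- function(features, labels, k = 5, seed = 1L, ...) {
  fm <- as_feature_matrix(features)
  if (is.data.frame(labels)) {
    lab <- stats::setNames(labels$label, labels$recording_id)
  } else lab <- labels
  y <- unname(lab[fm$ids])
  n <- nrow(fm$x)
  fold <- integer(n)
  with_seed(seed, {
    for (cls in unique(y)) {
      i <- which(y == cls)
      fold[i] <- sample(rep_len(seq_len(k), length(i)))
    }
  })
  preds <- character(n)
  for (f in seq_len(k)) {
    tr <- fold != f
    if (all(tr)) next                    # fold received no test samples
    model <- train_classifier(fm$x[tr, , drop = FALSE],
                              stats::setNames(y[tr], fm$ids[tr]),
                              seed = seed, ...)
    m <- fm$x[!tr, , drop = FALSE]
    rownames(m) <- fm$ids[!tr]
    preds[!tr] <- predict_labels(model, m)
  }
  names(preds) <- fm$ids
  list(predictions = preds, accuracy = mean(preds == y), fold = fold)
}
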