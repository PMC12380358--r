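#' Feature table for classification
#'
#' Per-sample feature vectors (in this pipeline, the ATLD score matrix) with
#' class labels. All classifiers in the package operate on this container.
#'
#' @param ids Character vector of sample ids.
#' @param labels Class labels (character or factor), one per sample.
#' @param features Numeric matrix, rows aligned with `ids`.
#' @param scaling `"raw"` or `"autoscaled"`.
#' @return Object of class `feature_table`.
#' @export
feature_table <- function(ids, labels, features, scaling = "raw") {
  features <- as.matrix(features)
  if (length(ids) != nrow(features) || length(labels) != nrow(features))
    stop("feature_table: ids, labels and feature rows must align", call. = FALSE)
  if (any(!is.finite(features)))
    stop("feature_table: features contain missing or non-finite values",
         call. = FALSE)
  if (is.null(colnames(features)))
    colnames(features) <- paste0("component_", seq_len(ncol(features)))
  structure(list(ids = as.character(ids), labels = factor(labels),
                 features = features, scaling = scaling),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d samples x %d features (%s), %d classes\n",
              nrow(x$features), ncol(x$features), x$scaling,
              nlevels(x$labels)))
  invisible(x)
}

scaling_params <- function(X) {
  center <- colMeans(X)
  scale <- apply(X, 2, stats::sd)
  constant <- scale < .Machine$double.eps * 100
  scale[constant] <- 1
  list(center = center, scale = scale, constant = constant)
}

apply_scaling <- function(X, sp) {
  sweep(sweep(X, 2, sp$center, "-"), 2, sp$scale, "/")
}

#' Autoscale a feature table
#'
#' Centres each feature column to mean 0 and scales it to unit sample
#' variance. Constant columns are centred only, with a warning. Applying
#' autoscale twice equals applying it once.
#'
#' @param table A [feature_table()].
#' @return The autoscaled [feature_table()] with attributes `center` and
#'   `scale` recording the transformation.
#' @export
autoscale <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  if (nrow(table$features) < 2L)
    stop("autoscale: need at least two samples", call. = FALSE)
  sp <- scaling_params(table$features)
  if (any(sp$constant))
    warning(sprintf("autoscale: constant column(s) left centred: %s",
                    paste(colnames(table$features)[sp$constant], collapse = ", ")))
  out <- table
  out$features <- apply_scaling(table$features, sp)
  out$scaling <- "autoscaled"
  attr(out, "center") <- sp$center
  attr(out, "scale") <- sp$scale
  out
}

#' Principal component analysis of a feature table
#'
#' Eigendecomposition of the covariance of the feature matrix (via
#' [stats::prcomp()]); no additional scaling is applied, so autoscale first
#' if unit-variance features are wanted.
#'
#' @param table A [feature_table()].
#' @param n_pc Number of components to keep (default: all).
#' @return List with `scores`, `loadings`, and `var_fraction` (explained
#'   variance fractions, sorted decreasing).
#' @export
pca_features <- function(table, n_pc = NULL) {
  stopifnot(inherits(table, "feature_table"))
  pc <- stats::prcomp(table$features, center = TRUE, scale. = FALSE)
  rank <- sum(pc$sdev > pc$sdev[1] * 1e-12)
  if (is.null(n_pc)) n_pc <- rank
  if (n_pc > rank) {
    warning(sprintf("pca_features: n_pc=%d exceeds rank %d; truncated", n_pc, rank))
    n_pc <- rank
  }
  var_fraction <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x[, seq_len(n_pc), drop = FALSE],
       loadings = pc$rotation[, seq_len(n_pc), drop = FALSE],
       var_fraction = var_fraction[seq_len(n_pc)])
}

#' Hierarchical clustering of a feature table
#'
#' Agglomerative clustering on Euclidean distances between feature vectors.
#'
#' @param table A [feature_table()] (autoscale first for unitless distances).
#' @param linkage `"ward"` (Ward's D2) or `"average"`.
#' @param k Number of clusters to cut.
#' @return Integer cluster assignment named by sample id.
#' @export
hier_cluster <- function(table, linkage = c("ward", "average"), k) {
  linkage <- match.arg(linkage)
  stopifnot(inherits(table, "feature_table"), k >= 1,
            k <= nrow(table$features))
  hc <- stats::hclust(stats::dist(table$features),
                      method = if (linkage == "ward") "ward.D2" else "average")
  cl <- stats::cutree(hc, k = k)
  names(cl) <- table$ids
  cl
}

#' k-nearest-neighbour classification
#'
#' Majority vote over the `k` nearest training samples by Euclidean distance
#' in autoscaled feature space (scaling parameters are taken from the
#' training set and applied to the queries, so no information leaks from the
#' query set). Ties are broken by the class of the single nearest neighbour.
#' A neighbour report listing the `n_report` nearest training samples with
#' ids and distances accompanies the predictions.
#'
#' @param train,query [feature_table()] objects on the same feature space.
#' @param k Number of voting neighbours (default 3).
#' @param n_report Number of neighbours listed in the report (default 7).
#' @return List with `predictions` (factor, named by query id) and
#'   `neighbors` (data.frame: query id, rank, neighbour id, class, distance,
#'   distances in increasing order).
#' @export
knn_classify <- function(train, query, k = 3, n_report = 7) {
  stopifnot(inherits(train, "feature_table"), inherits(query, "feature_table"))
  if (k < 1) stop("knn_classify: k must be >= 1", call. = FALSE)
  if (k > nrow(train$features))
    stop("knn_classify: k exceeds the number of training samples", call. = FALSE)
  sp <- scaling_params(train$features)
  Xtr <- apply_scaling(train$features, sp)
  Xq <- apply_scaling(query$features, sp)
  n_report <- min(n_report, nrow(Xtr))
  preds <- character(nrow(Xq))
  nb <- vector("list", nrow(Xq))
  for (q in seq_len(nrow(Xq))) {
    d <- sqrt(colSums((t(Xtr) - Xq[q, ])^2))
    ord <- order(d)
    votes <- table(train$labels[ord[seq_len(k)]])
    top <- names(votes)[votes == max(votes)]
    preds[q] <- if (length(top) == 1L) top else
      as.character(train$labels[ord[1L]])
    nb[[q]] <- data.frame(query_id = query$ids[q], rank = seq_len(n_report),
                          neighbor_id = train$ids[ord[seq_len(n_report)]],
                          neighbor_class = as.character(train$labels[ord[seq_len(n_report)]]),
                          distance = d[ord[seq_len(n_report)]])
  }
  predictions <- factor(preds, levels = levels(train$labels))
  names(predictions) <- query$ids
  list(predictions = predictions, neighbors = do.call(rbind, nb))
}

#' Random-forest classifier on a feature table
#'
#' Bootstrap-aggregated decision trees with Gini-impurity splits of the form
#' `feature <= threshold` (via the randomForest package). Feature importances
#' are mean impurity decreases normalized to sum to 1. Deterministic for a
#' fixed seed.
#'
#' @param train A [feature_table()].
#' @param n_trees Number of trees (default 500).
#' @param seed Integer seed (required).
#' @param mtry Features tried per split; default `ceiling(sqrt(p))`.
#' @return Object of class `rf_model` with elements `forest`
#'   (the randomForest fit), `importance` (named, sums to 1), `scaling`,
#'   `seed`.
#' @export
rf_fit <- function(train, n_trees = 500, seed, mtry = NULL) {
  stopifnot(inherits(train, "feature_table"))
  if (missing(seed)) stop("rf_fit: seed is required", call. = FALSE)
  if (nlevels(droplevels(train$labels)) < 2L)
    stop("rf_fit: need at least two classes", call. = FALSE)
  sp <- scaling_params(train$features)
  X <- apply_scaling(train$features, sp)
  if (is.null(mtry)) mtry <- ceiling(sqrt(ncol(X)))
  set.seed(seed)
  forest <- randomForest::randomForest(x = X, y = droplevels(train$labels),
                                       ntree = n_trees, mtry = mtry,
                                       importance = FALSE)
  imp <- forest$importance[, "MeanDecreaseGini"]
  imp <- if (sum(imp) > 0) imp / sum(imp) else imp
  structure(list(forest = forest, importance = imp, scaling = sp, seed = seed),
            class = "rf_model")
}

#' @export
predict.rf_model <- function(object, newdata, ...) {
  X <- apply_scaling(as.matrix(newdata), object$scaling)
  stats::predict(object$forest, X)
}

#' Partial least squares discriminant analysis
#'
#' PLS2 regression (NIPALS) of the autoscaled feature matrix against the
#' one-vs-all class indicator matrix. Prediction assigns the class with the
#' largest fitted indicator; when `threshold` is set, queries whose largest
#' fitted indicator falls below it are returned as `"unassigned"`.
#'
#' @param train A [feature_table()].
#' @param n_latent Number of latent variables (>= 1, at most the feature
#'   rank).
#' @return Object of class `plsda_model` with weights `x_weights` (W),
#'   loadings `x_loadings` (P), `y_loadings` (Q), the regression matrix
#'   `coefficients`, class levels, and the training scaling.
#' @export
plsda_fit <- function(train, n_latent) {
  stopifnot(inherits(train, "feature_table"))
  if (n_latent < 1) stop("plsda_fit: n_latent must be >= 1", call. = FALSE)
  labels <- droplevels(train$labels)
  classes <- levels(labels)
  if (length(classes) < 2L)
    stop("plsda_fit: need at least two classes", call. = FALSE)
  Y <- outer(as.character(labels), classes, `==`) * 1
  if (any(colSums(Y) == 0) || any(colSums(Y) == nrow(Y)))
    stop("plsda_fit: degenerate (constant) indicator column", call. = FALSE)
  sp <- scaling_params(train$features)
  X <- apply_scaling(train$features, sp)
  ymean <- colMeans(Y)
  Yc <- sweep(Y, 2, ymean)
  p <- ncol(X)
  W <- matrix(0, p, n_latent)
  P <- matrix(0, p, n_latent)
  Q <- matrix(0, ncol(Y), n_latent)
  Xr <- X; Yr <- Yc
  for (a in seq_len(n_latent)) {
    u <- Yr[, which.max(colSums(Yr^2))]
    t_old <- rep(Inf, nrow(X))
    for (iter in 1:500) {
      w <- crossprod(Xr, u)
      nw <- sqrt(sum(w^2))
      if (nw < 1e-14) break
      w <- w / nw
      tt <- Xr %*% w
      q <- crossprod(Yr, tt) / sum(tt^2)
      u <- Yr %*% q / sum(q^2)
      if (sum((tt - t_old)^2) < 1e-12 * sum(tt^2)) break
      t_old <- tt
    }
    if (nw < 1e-14) {
      n_latent <- a - 1L
      W <- W[, seq_len(n_latent), drop = FALSE]
      P <- P[, seq_len(n_latent), drop = FALSE]
      Q <- Q[, seq_len(n_latent), drop = FALSE]
      break
    }
    pv <- crossprod(Xr, tt) / sum(tt^2)
    W[, a] <- w; P[, a] <- pv; Q[, a] <- q
    Xr <- Xr - tt %*% t(pv)
    Yr <- Yr - tt %*% t(q)
  }
  if (n_latent < 1)
    stop("plsda_fit: no usable latent variable (degenerate features)",
         call. = FALSE)
  B <- W %*% solve(t(P) %*% W, t(Q))
  structure(list(n_latent = n_latent, x_weights = W, x_loadings = P,
                 y_loadings = Q, coefficients = B, ymean = ymean,
                 classes = classes, scaling = sp),
            class = "plsda_model")
}

#' @param object A `plsda_model`.
#' @param newdata Feature matrix (raw scale; the training autoscaling is
#'   applied internally).
#' @param threshold Optional rejection threshold on the largest fitted
#'   indicator; below it the prediction is `"unassigned"`.
#' @param ... Unused.
#' @rdname plsda_fit
#' @export
predict.plsda_model <- function(object, newdata, threshold = NULL, ...) {
  X <- apply_scaling(as.matrix(newdata), object$scaling)
  Yhat <- X %*% object$coefficients
  Yhat <- sweep(Yhat, 2, object$ymean, "+")
  colnames(Yhat) <- object$classes
  idx <- max.col(Yhat, ties.method = "first")
  preds <- object$classes[idx]
  if (!is.null(threshold)) {
    best <- Yhat[cbind(seq_len(nrow(Yhat)), idx)]
    preds[best < threshold] <- "unassigned"
  }
  out <- factor(preds, levels = c(object$classes,
                                  if (!is.null(threshold)) "unassigned"))
  attr(out, "indicators") <- Yhat
  out
}

#' Select the number of PLS-DA latent variables by cross-validation
#'
#' Evaluates cross-validated classification accuracy for each candidate
#' latent-variable count and returns the smallest count whose accuracy lies
#' within one standard error of the best (the usual parsimony tie-break).
#'
#' @param train A [feature_table()].
#' @param lv_range Candidate LV counts (default 1 to the feature count).
#' @param scheme `"loo"` or `"stratified"` k-fold.
#' @param k_folds Folds for the stratified scheme.
#' @param seed Seed for fold assignment.
#' @return List with `selected`, and `cv_curve` (data.frame: `n_latent`,
#'   `accuracy` percent, `se` percent).
#' @export
select_lv <- function(train, lv_range = NULL, scheme = c("loo", "stratified"),
                      k_folds = 6, seed = 1) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(train, "feature_table"))
  if (is.null(lv_range)) lv_range <- seq_len(ncol(train$features))
  lv_range <- sort(unique(as.integer(lv_range)))
  if (length(lv_range) == 0L)
    stop("select_lv: empty candidate range", call. = FALSE)
  n <- nrow(train$features)
  curve <- lapply(lv_range, function(a) {
    rep_ <- cross_validate(train, model_spec = list(method = "plsda",
                                                    n_latent = a),
                           scheme = scheme, k_folds = k_folds, seed = seed)
    p <- rep_$accuracy / 100
    data.frame(n_latent = a, accuracy = rep_$accuracy,
               se = 100 * sqrt(p * (1 - p) / n))
  })
  curve <- do.call(rbind, curve)
  best <- max(curve$accuracy)
  se_best <- curve$se[which.max(curve$accuracy)]
  selected <- min(curve$n_latent[curve$accuracy >= best - se_best])
  list(selected = selected, cv_curve = curve)
}

fit_classifier <- function(spec, train) {
  method <- spec$method
  if (method == "knn") {
    list(method = "knn", train = train,
         k = if (is.null(spec$k)) 3 else spec$k)
  } else if (method == "rf") {
    list(method = "rf",
         model = rf_fit(train,
                        n_trees = if (is.null(spec$n_trees)) 500 else spec$n_trees,
                        seed = if (is.null(spec$seed)) 1 else spec$seed))
  } else if (method == "plsda") {
    list(method = "plsda",
         model = plsda_fit(train, n_latent = if (is.null(spec$n_latent)) 4
                           else spec$n_latent),
         threshold = spec$threshold)
  } else stop(sprintf("unknown classifier method '%s'", method), call. = FALSE)
}

predict_classifier <- function(fit, query) {
  if (fit$method == "knn") {
    knn_classify(fit$train, query, k = fit$k)$predictions
  } else if (fit$method == "rf") {
    stats::predict(fit$model, query$features)
  } else {
    stats::predict(fit$model, query$features, threshold = fit$threshold)
  }
}

#' Build a classification report from truth and predictions
#'
#' Confusion matrix (rows = true class, columns = predicted class plus an
#' `"unassigned"` column when rejections occur) with the per-class quality
#' metrics used for origin authentication: sensitivity `TP/(TP+FN)*100`,
#' specificity `TN/(TN+FP)*100` (one-vs-rest), reject rate (percent of the
#' class left unassigned), and false-recognition rate (percent of the class
#' assigned to a wrong class). The `total` row aggregates over all samples.
#'
#' @param truth True class labels.
#' @param predicted Predicted labels (may include `"unassigned"`).
#' @param classes Class vocabulary; defaults to the union of levels.
#' @return Object of class `classification_report`: `confusion`, `metrics`
#'   (data.frame, one row per class plus `total`), and `accuracy` (percent).
#' @export
classification_report <- function(truth, predicted, classes = NULL) {
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  stopifnot(length(truth) == length(predicted))
  if (is.null(classes)) classes <- sort(unique(truth))
  has_reject <- any(predicted == "unassigned")
  pred_levels <- c(classes, if (has_reject) "unassigned")
  confusion <- table(factor(truth, levels = classes),
                     factor(predicted, levels = pred_levels))
  confusion <- unclass(confusion)
  names(dimnames(confusion)) <- c("truth", "predicted")
  rows <- lapply(classes, function(g) {
    n_g <- sum(truth == g)
    tp <- sum(truth == g & predicted == g)
    fp <- sum(truth != g & predicted == g)
    tn <- sum(truth != g & predicted != g)
    rej <- sum(truth == g & predicted == "unassigned")
    fr <- sum(truth == g & predicted != g & predicted != "unassigned")
    data.frame(class = g, n = n_g,
               reject_rate = if (n_g) 100 * rej / n_g else NA_real_,
               false_recognition_rate = if (n_g) 100 * fr / n_g else NA_real_,
               sensitivity = if (n_g) 100 * tp / n_g else NA_real_,
               specificity = if (tn + fp) 100 * tn / (tn + fp) else NA_real_)
  })
  metrics <- do.call(rbind, rows)
  n_tot <- length(truth)
  tp_tot <- sum(truth == predicted)
  total <- data.frame(class = "total", n = n_tot,
                      reject_rate = 100 * sum(predicted == "unassigned") / n_tot,
                      false_recognition_rate =
                        100 * sum(truth != predicted &
                                  predicted != "unassigned") / n_tot,
                      sensitivity = 100 * tp_tot / n_tot,
                      specificity = stats::weighted.mean(metrics$specificity,
                                                         metrics$n))
  metrics <- rbind(metrics, total)
  structure(list(confusion = confusion, metrics = metrics,
                 accuracy = 100 * tp_tot / n_tot),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat("confusion matrix (rows = truth):\n")
  print(x$confusion)
  cat("\n")
  print(x$metrics, row.names = FALSE, digits = 4)
  cat(sprintf("\noverall accuracy: %.3f%%\n", x$accuracy))
  invisible(x)
}

#' Cross-validated classification
#'
#' Refits the full pipeline (including autoscaling) inside every fold, so no
#' scaling information leaks from held-out samples, and aggregates the
#' held-out predictions into one [classification_report()].
#'
#' @param table A [feature_table()] with raw (unscaled) features.
#' @param model_spec List: `method` (`"knn"`, `"rf"`, `"plsda"`) plus
#'   method parameters (`k`, `n_trees`, `n_latent`, `threshold`, `seed`).
#' @param scheme `"loo"` (leave-one-out, default) or `"stratified"` k-fold.
#' @param k_folds Folds for the stratified scheme (default 6).
#' @param seed Seed for fold assignment and stochastic classifiers.
#' @return A [classification_report()] with attribute `predictions`.
#' @export
cross_validate <- function(table, model_spec, scheme = c("loo", "stratified"),
                           k_folds = 6, seed = 1) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(table, "feature_table"))
  labels <- droplevels(table$labels)
  if (nlevels(labels) < 2L)
    stop("cross_validate: need at least two classes", call. = FALSE)
  n <- nrow(table$features)
  if (scheme == "stratified") {
    if (min(table(labels)) < k_folds) {
      if (min(table(labels)) < 2L) {
        warning("cross_validate: class with a single member; falling back to LOO")
        scheme <- "loo"
      } else k_folds <- min(table(labels))
    }
  }
  if (scheme == "loo") {
    folds <- as.list(seq_len(n))
  } else {
    set.seed(seed)
    fold_id <- integer(n)
    for (g in levels(labels)) {
      idx <- sample(which(labels == g))
      fold_id[idx] <- rep_len(seq_len(k_folds), length(idx))
    }
    folds <- split(seq_len(n), fold_id)
  }
  if (!is.null(model_spec$method) && model_spec$method == "rf" &&
      is.null(model_spec$seed)) model_spec$seed <- seed
  preds <- character(n)
  for (fold in folds) {
    tr <- feature_table(table$ids[-fold], labels[-fold],
                        table$features[-fold, , drop = FALSE])
    qu <- feature_table(table$ids[fold], labels[fold],
                        table$features[fold, , drop = FALSE])
    fit <- fit_classifier(model_spec, tr)
    preds[fold] <- as.character(predict_classifier(fit, qu))
  }
  rep_ <- classification_report(labels, preds, classes = levels(labels))
  attr(rep_, "predictions") <- stats::setNames(preds, table$ids)
  rep_
}

#' External-set validation
#'
#' Fits the classifier on the full training table and evaluates it on a
#' disjoint holdout table.
#'
#' @param train,holdout [feature_table()] objects with raw features;
#'   passing the training table itself yields resubstitution accuracy.
#' @param model_spec As in [cross_validate()].
#' @return A [classification_report()] for the holdout with attribute
#'   `predictions`.
#' @export
external_validate <- function(train, holdout, model_spec) {
  stopifnot(inherits(train, "feature_table"), inherits(holdout, "feature_table"))
  if (nrow(holdout$features) == 0L)
    stop("external_validate: empty holdout", call. = FALSE)
  fit <- fit_classifier(model_spec, train)
  preds <- predict_classifier(fit, holdout)
  rep_ <- classification_report(droplevels(holdout$labels), preds,
                                classes = levels(droplevels(train$labels)))
  attr(rep_, "predictions") <- stats::setNames(as.character(preds), holdout$ids)
  rep_
}
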