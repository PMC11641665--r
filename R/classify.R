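#' KNN / nested cross-validation configuration
#'
#' @param k number of neighbours when `fix_k = TRUE` (default 5, the value
#'   used for the final model); a warning is issued for even k because vote
#'   ties become possible.
#' @param k_grid candidate k values the inner CV chooses from (odd only by
#'   default).
#' @param fix_k skip inner selection and use `k` everywhere.
#' @param n_outer,n_inner numbers of outer and inner stratified folds
#'   (default 10 and 10).
#' @param seed integer seed controlling fold assignment.
#' @return a `knn_config` list.
#' @export
knn_config <- function(k = 5L, k_grid = c(1L, 3L, 5L, 7L, 9L),
                       fix_k = FALSE, n_outer = 10L, n_inner = 10L,
                       seed = 1L) {
  if (n_outer < 2L || n_inner < 2L)
    snm_error("snm_invalid_config", "n_outer and n_inner must be at least 2")
  if (k %% 2L == 0L)
    warning("even k allows vote ties; ties are broken toward tumor")
  structure(list(k = as.integer(k), k_grid = as.integer(k_grid),
                 fix_k = isTRUE(fix_k), n_outer = as.integer(n_outer),
                 n_inner = as.integer(n_inner), seed = as.integer(seed)),
            class = "knn_config")
}

#' City-block (Manhattan) distance
#'
#' @param u,v numeric vectors of equal length.
#' @return `sum(|u - v|)`.
#' @export
city_block_distance <- function(u, v) {
  if (length(u) != length(v))
    snm_error("snm_invalid_input", "vectors differ in length")
  sum(abs(u - v))
}

#' K-nearest-neighbour prediction with city-block distance
#'
#' Each test sample's k nearest training samples (by city-block distance)
#' vote; the score is the tumor vote fraction and the label is tumor when
#' the score is at least 0.5 (a tied vote goes to the positive class).
#' Neighbours are ordered deterministically by (distance, training sample
#' id), so predictions do not depend on training-row order.
#'
#' @param train_features numeric matrix, training samples in rows
#'   (rownames used for tie-breaking; row indices otherwise).
#' @param train_labels character vector (`"tumor"`/`"normal"`).
#' @param test_features numeric matrix, test samples in rows.
#' @param k number of neighbours (default 5).
#' @return list with `labels` (character) and `scores` (tumor vote
#'   fraction in \[0, 1\]).
#' @export
knn_predict <- function(train_features, train_labels, test_features, k = 5L) {
  train_features <- as.matrix(train_features)
  test_features <- as.matrix(test_features)
  if (k > nrow(train_features))
    snm_error("snm_invalid_input", "k exceeds the number of training samples")
  if (length(unique(train_labels)) < 2L)
    snm_error("snm_invalid_input", "training data must contain both classes")
  ids <- rownames(train_features)
  if (is.null(ids)) ids <- sprintf("s%06d", seq_len(nrow(train_features)))
  scores <- numeric(nrow(test_features))
  for (i in seq_len(nrow(test_features))) {
    d <- rowSums(abs(train_features -
                       matrix(test_features[i, ], nrow(train_features),
                              ncol(train_features), byrow = TRUE)))
    ord <- order(d, ids)
    nb <- ord[seq_len(k)]
    scores[i] <- mean(train_labels[nb] == "tumor")
  }
  list(labels = ifelse(scores >= 0.5, "tumor", "normal"), scores = scores)
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' `P(score_tumor > score_normal) + 0.5 P(equal)` over all tumor/normal
#' pairs, computed from average ranks; invariant under strictly monotone
#' transforms of the scores.
#'
#' @param scores numeric ranking scores (higher = more tumor-like).
#' @param labels character classes (`"tumor"` positive).
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  pos <- labels == "tumor"
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L)
    snm_error("snm_invalid_input", "both classes required for AUC")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# deterministic stratified fold assignment: within each class, samples are
# shuffled (seeded) and folds dealt cyclically
stratified_folds <- function(labels, n_folds, seed) {
  folds <- integer(length(labels))
  with_seed(seed, {
    for (cl in sort(unique(labels))) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  folds
}

confusion_metrics <- function(true, predicted) {
  tp <- sum(true == "tumor" & predicted == "tumor")
  tn <- sum(true == "normal" & predicted == "normal")
  fp <- sum(true == "normal" & predicted == "tumor")
  fn <- sum(true == "tumor" & predicted == "normal")
  list(confusion = list(TP = tp, FP = fp, FN = fn, TN = tn),
       accuracy = (tp + tn) / length(true),
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}

#' Two-level nested cross-validation for the KNN classifier
#'
#' Stratified outer folds estimate generalization; within each outer
#' training portion, stratified inner folds pick k from `k_grid` by inner
#' accuracy (ties to the smallest k), the model is refit on the full outer
#' training portion, and outer-test predictions are pooled into one
#' report. Anything data-dependent about the features (gene selection,
#' direction estimation) can be recomputed per outer fold by supplying
#' `feature_fun`, so no test sample ever influences its own prediction.
#'
#' @param labels character class labels for all samples.
#' @param features numeric matrix (samples x features); ignored when
#'   `feature_fun` is given.
#' @param feature_fun optional `function(train_idx, test_idx)` returning
#'   `list(train = matrix, test = matrix)` built from the training subset
#'   only.
#' @param config a [knn_config()].
#' @param sample_ids optional sample ids (defaults to feature rownames).
#' @return a `classification_report` list: `accuracy`, `sensitivity`,
#'   `specificity`, `auc`, `confusion`, `per_fold`, `predictions`,
#'   `positive_class`.
#' @export
nested_cv <- function(labels, features = NULL, feature_fun = NULL,
                      config = knn_config(), sample_ids = NULL) {
  n <- length(labels)
  if (is.null(feature_fun)) {
    stopifnot(!is.null(features), nrow(features) == n)
    feature_fun <- function(train_idx, test_idx) {
      list(train = features[train_idx, , drop = FALSE],
           test = features[test_idx, , drop = FALSE])
    }
  }
  if (is.null(sample_ids))
    sample_ids <- rownames(features) %||% sprintf("s%04d", seq_len(n))
  if (min(table(labels)) < config$n_outer)
    warning("a class has fewer samples than outer folds; folds are stratified but uneven")
  outer <- stratified_folds(labels, config$n_outer, config$seed)
  pred <- character(n); score <- numeric(n)
  per_fold <- list()
  for (f in sort(unique(outer))) {
    test_idx <- which(outer == f)
    train_idx <- which(outer != f)
    if (length(unique(labels[train_idx])) < 2L)
      snm_error("snm_invalid_input",
                sprintf("outer training fold %d lacks a class", f))
    feats <- feature_fun(train_idx, test_idx)
    rownames(feats$train) <- sample_ids[train_idx]
    k_sel <- config$k
    if (!config$fix_k) {
      grid <- config$k_grid
      inner <- stratified_folds(labels[train_idx], config$n_inner,
                                derive_seed(config$seed, paste0("inner", f)))
      acc <- vapply(grid, function(k) {
        hits <- 0L; tot <- 0L
        for (g in sort(unique(inner))) {
          it <- which(inner == g)
          tr <- which(inner != g)
          if (length(unique(labels[train_idx][tr])) < 2L) next
          if (k > length(tr)) next
          p <- knn_predict(feats$train[tr, , drop = FALSE],
                           labels[train_idx][tr],
                           feats$train[it, , drop = FALSE], k)
          hits <- hits + sum(p$labels == labels[train_idx][it])
          tot <- tot + length(it)
        }
        if (tot == 0L) return(NA_real_)
        hits / tot
      }, numeric(1))
      if (all(is.na(acc)))
        snm_error("snm_invalid_input", "inner CV produced no usable folds")
      k_sel <- grid[which(acc == max(acc, na.rm = TRUE))[1L]]
    }
    k_use <- min(k_sel, length(train_idx))
    p <- knn_predict(feats$train, labels[train_idx], feats$test, k_use)
    pred[test_idx] <- p$labels
    score[test_idx] <- p$scores
    per_fold[[length(per_fold) + 1L]] <- list(
      fold = f, test_ids = sample_ids[test_idx], k_selected = k_use)
  }
  m <- confusion_metrics(labels, pred)
  structure(c(m, list(
    auc = roc_auc(score, labels),
    per_fold = per_fold,
    predictions = data.frame(sample_id = sample_ids, true = labels,
                             predicted = pred, score = score,
                             fold = outer, stringsAsFactors = FALSE),
    positive_class = "tumor")), class = "classification_report")
}

#' Train/test evaluation of the KNN classifier
#'
#' Fits nothing beyond storing the training features; predicts the test
#' set with city-block KNN and reports pooled metrics.
#'
#' @param train_features,train_labels training data.
#' @param test_features,test_labels held-out data.
#' @param k number of neighbours (default 5).
#' @return a `classification_report` list (no `per_fold`).
#' @export
evaluate_classifier <- function(train_features, train_labels,
                                test_features, test_labels, k = 5L) {
  p <- knn_predict(train_features, train_labels, test_features, k)
  m <- confusion_metrics(test_labels, p$labels)
  structure(c(m, list(
    auc = roc_auc(p$scores, test_labels),
    predictions = data.frame(
      sample_id = rownames(test_features) %||% seq_along(test_labels),
      true = test_labels, predicted = p$labels, score = p$scores,
      stringsAsFactors = FALSE),
    positive_class = "tumor")), class = "classification_report")
}

#' Principal-component projection of activity features
#'
#' Centered (not scaled) PCA of the samples x features matrix. Sign
#' convention: each component's largest-magnitude loading is positive.
#'
#' @param features numeric matrix, samples in rows.
#' @param n_components number of components returned (truncated to the
#'   matrix rank with a warning if larger).
#' @return list with `coordinates` (samples x components),
#'   `explained_variance` (fractions) and `loadings`.
#' @export
pca_project <- function(features, n_components = 2L) {
  features <- as.matrix(features)
  if (nrow(features) < 2L)
    snm_error("snm_invalid_input", "need more than one sample")
  pc <- stats::prcomp(features, center = TRUE, scale. = FALSE)
  rank <- sum(pc$sdev > pc$sdev[1L] * 1e-12)
  if (n_components > rank) {
    warning(sprintf("n_components truncated from %d to rank %d",
                    n_components, rank))
    n_components <- rank
  }
  keep <- seq_len(n_components)
  rot <- pc$rotation[, keep, drop = FALSE]
  coords <- pc$x[, keep, drop = FALSE]
  for (j in keep) {
    m <- which.max(abs(rot[, j]))
    if (rot[m, j] < 0) {
      rot[, j] <- -rot[, j]
      coords[, j] <- -coords[, j]
    }
  }
  list(coordinates = coords,
       explained_variance = (pc$sdev^2 / sum(pc$sdev^2))[keep],
       loadings = rot)
}
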