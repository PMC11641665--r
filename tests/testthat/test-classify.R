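test_that("city-block distance is the absolute coordinate sum", {
  expect_equal(city_block_distance(c(0, 0), c(1, 2)), 3)
  expect_equal(city_block_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  set.seed(1)
  for (i in 1:10) {
    u <- rnorm(10); v <- rnorm(10)
    expect_equal(city_block_distance(u, v), sum(abs(u - v)), tolerance = 1e-12)
  }
  expect_error(city_block_distance(1:2, 1:3), class = "snm_invalid_input")
})

test_that("KNN voting follows the documented tie and neighbour rules", {
  train <- matrix(c(0, 0, 1, 1, 2, 2), 3, byrow = TRUE,
                  dimnames = list(c("s1", "s2", "s3"), NULL))
  labels <- c("tumor", "normal", "tumor")
  p <- knn_predict(train, labels, train["s2", , drop = FALSE], k = 1)
  expect_equal(p$labels, "normal")
  expect_true(p$scores %in% c(0, 1))

  # all training points at city-block distance 1 from the origin:
  # 3 tumor / 2 normal at k = 5 forces score 0.6
  tr <- matrix(c(1, 0, -1, 0, 0, 1, 0, -1, 0.5, 0.5), 5, 2, byrow = TRUE)
  labs <- c("tumor", "tumor", "tumor", "normal", "normal")
  p2 <- knn_predict(tr, labs, matrix(0, 1, 2), k = 5)
  expect_equal(p2$scores, 0.6)
  expect_equal(p2$labels, "tumor")

  expect_error(knn_predict(tr, labs, matrix(0, 1, 2), k = 6),
               class = "snm_invalid_input")
  expect_error(knn_predict(tr, rep("tumor", 5), matrix(0, 1, 2), k = 3),
               class = "snm_invalid_input")
})

test_that("KNN matches the brute-force oracle and ignores training order", {
  set.seed(23)
  for (i in 1:10) {
    n <- 30
    train <- matrix(rnorm(n * 4), n,
                    dimnames = list(sprintf("s%02d", 1:n), NULL))
    labels <- sample(c("tumor", "normal"), n, replace = TRUE,
                     prob = c(0.6, 0.4))
    if (length(unique(labels)) < 2) next
    test <- matrix(rnorm(8 * 4), 8)
    k <- sample(c(1, 3, 5), 1)
    got <- knn_predict(train, labels, test, k)
    want <- oracle_knn(train, labels, test, k)
    expect_equal(got$scores, unname(want[, "score"]), tolerance = 1e-12)
    expect_equal(got$labels == "tumor", want[, "tumor"] == 1,
                 ignore_attr = TRUE)
    # permutation invariance of training rows
    perm <- sample(n)
    got2 <- knn_predict(train[perm, ], labels[perm], test, k)
    expect_equal(got2$scores, got$scores, tolerance = 1e-12)
  }
})

test_that("AUC equals exhaustive pair enumeration and is rank-invariant", {
  expect_equal(roc_auc(c(1, 2, 3, 4), c("normal", "normal", "tumor", "tumor")), 1)
  expect_equal(roc_auc(rep(0.5, 6), rep(c("tumor", "normal"), 3)), 0.5)
  set.seed(4)
  scores <- c(rnorm(6, 1), rnorm(4))
  labels <- c(rep("tumor", 6), rep("normal", 4))
  expect_equal(roc_auc(scores, labels), oracle_auc(scores, labels),
               tolerance = 1e-12)
  # ties handled as 1/2
  s2 <- c(1, 1, 2, 2, 3); l2 <- c("tumor", "normal", "tumor", "normal", "tumor")
  expect_equal(roc_auc(s2, l2), oracle_auc(s2, l2), tolerance = 1e-12)
  # strictly monotone transform leaves AUC unchanged
  expect_equal(roc_auc(exp(scores), labels), roc_auc(scores, labels),
               tolerance = 1e-12)
  expect_error(roc_auc(1:3, rep("tumor", 3)), class = "snm_invalid_input")
})

test_that("nested CV is perfect on separable blobs and pools a valid confusion", {
  set.seed(6)
  n <- 40
  labels <- rep(c("tumor", "normal"), c(25, 15))
  feats <- rbind(matrix(rnorm(25 * 3, 5, 0.3), 25),
                 matrix(rnorm(15 * 3, 0, 0.3), 15))
  rownames(feats) <- sprintf("s%02d", 1:n)
  rep1 <- nested_cv(labels, feats, config = knn_config(seed = 2))
  expect_equal(rep1$accuracy, 1)
  expect_equal(rep1$sensitivity, 1)
  expect_equal(rep1$specificity, 1)
  expect_equal(rep1$auc, 1)
  cm <- rep1$confusion
  expect_equal(cm$TP + cm$TN + cm$FP + cm$FN, n)
  expect_equal(rep1$accuracy, (cm$TP + cm$TN) / n)

  # pooled confusion equals an independent per-fold recomputation
  pred2 <- character(n)
  for (pf in rep1$per_fold) {
    test_idx <- match(pf$test_ids, rownames(feats))
    train_idx <- setdiff(seq_len(n), test_idx)
    o <- oracle_knn(feats[train_idx, , drop = FALSE], labels[train_idx],
                    feats[test_idx, , drop = FALSE], pf$k_selected)
    pred2[test_idx] <- ifelse(o[, "tumor"] == 1, "tumor", "normal")
  }
  expect_equal(pred2, rep1$predictions$predicted)
})

test_that("no sample influences its own prediction (leakage canary)", {
  set.seed(8)
  # canary: extreme point labelled normal sitting beyond the tumor blob;
  # trained without itself its 1-NN is a tumor point, trained with itself
  # it would predict its own label
  labels <- c(rep("tumor", 14), rep("normal", 14), "normal")
  feats <- rbind(matrix(rnorm(14 * 2, 10, 0.3), 14),
                 matrix(rnorm(14 * 2, 0, 0.3), 14),
                 c(1000, 1000))
  rownames(feats) <- sprintf("s%02d", 1:29)
  rep1 <- nested_cv(labels, feats,
                    config = knn_config(k = 1, fix_k = TRUE, seed = 3))
  canary <- rep1$predictions[rep1$predictions$sample_id == "s29", ]
  expect_equal(canary$predicted, "tumor")
  # every sample appears in exactly one outer test fold
  all_ids <- unlist(lapply(rep1$per_fold, `[[`, "test_ids"))
  expect_setequal(all_ids, rownames(feats))
  expect_equal(anyDuplicated(all_ids), 0)
})

test_that("train/test evaluation reports coherent pooled metrics", {
  set.seed(12)
  tr <- rbind(matrix(rnorm(20 * 2, 3, 0.5), 20), matrix(rnorm(10 * 2, 0, 0.5), 10))
  rownames(tr) <- sprintf("a%02d", 1:30)
  te <- rbind(matrix(rnorm(30 * 2, 3, 0.5), 30), matrix(rnorm(20 * 2, 0, 0.5), 20))
  rownames(te) <- sprintf("b%02d", 1:50)
  rep1 <- evaluate_classifier(tr, rep(c("tumor", "normal"), c(20, 10)),
                              te, rep(c("tumor", "normal"), c(30, 20)), k = 5)
  expect_gte(rep1$accuracy, 0.9)
  cm <- rep1$confusion
  expect_equal(rep1$sensitivity, cm$TP / (cm$TP + cm$FN))
  expect_equal(rep1$specificity, cm$TN / (cm$TN + cm$FP))
})

test_that("PCA projection reconstructs the centered matrix and fixes signs", {
  set.seed(19)
  x <- matrix(rnorm(40), 10, 4)
  p <- pca_project(x, 4)
  centered <- scale(x, scale = FALSE)
  expect_equal(p$coordinates %*% t(p$loadings), unclass(centered),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_true(all(vapply(1:4, function(j) {
    l <- p$loadings[, j]; l[which.max(abs(l))] > 0
  }, logical(1))))
  # two distinct samples: one component carries all variance
  p2 <- pca_project(matrix(c(0, 0, 1, 2), 2, byrow = TRUE), 1)
  expect_equal(p2$explained_variance, 1)
  # duplicated samples project identically
  xd <- x[rep(1:10, each = 2), ]
  pd <- pca_project(xd, 2)
  expect_equal(pd$coordinates[seq(1, 19, 2), ], pd$coordinates[seq(2, 20, 2), ],
               tolerance = 1e-10)
  expect_warning(pca_project(matrix(rnorm(6), 3, 2), 5), "truncated")
})
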