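test_that("IQR-Welch statistic matches its defining formula", {
  expect_equal(iqr_welch_t(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5)), 0)
  # frozen direct-formula value: medians 1.5 and 11.5, each IQR 1.5,
  # t = -10 / ((1.5/1.349) * sqrt(1/2)) = -12.71849397...
  expect_equal(iqr_welch_t(c(0, 1, 2, 3), c(10, 11, 12, 13)),
               -12.7184939709, tolerance = 1e-9)
  # strictly decreasing in a location shift of the second group
  a <- c(1, 2, 3, 4)
  ts <- vapply(c(0, 1, 2, 5), function(c) iqr_welch_t(a, a + c), numeric(1))
  expect_true(all(diff(ts) < 0))
  expect_error(iqr_welch_t(1, c(1, 2)), class = "snm_invalid_input")
  # both scales zero -> undefined
  expect_true(is.na(iqr_welch_t(c(1, 1, 1), c(2, 2, 2))))
})

test_that("IQR-Welch is antisymmetric, shift-invariant and scale-invariant", {
  set.seed(10)
  for (i in 1:20) {
    a <- rnorm(sample(4:12, 1)); b <- rnorm(sample(4:12, 1), mean = 1)
    t0 <- iqr_welch_t(a, b)
    expect_equal(iqr_welch_t(b, a), -t0, tolerance = 1e-12)
    expect_equal(iqr_welch_t(a + 5, b + 5), t0, tolerance = 1e-9)
    c <- runif(1, 0.5, 3)
    expect_equal(iqr_welch_t(a * c, b * c), t0, tolerance = 1e-9)
  }
})

test_that("representative selection takes top-5 by |t| with id tie-break", {
  ds <- tiny_dataset(n_genes = 3)
  reps <- select_representatives(rownames(ds$values), ds)
  expect_equal(nrow(reps), 3)  # fewer than 5 genes: all returned
  expect_true(all(diff(abs(reps$t_iqr)) <= 1e-12))
  expect_equal(reps$direction, ifelse(reps$t_iqr > 0, "up", "down"))

  # engineered tie for rank 5: two identical moderate genes compete
  set.seed(2)
  vals <- matrix(rnorm(6 * 10, 7, 0.5), 6,
                 dimnames = list(c("A", "B", "C", "D", "E", "Ez"),
                                 sprintf("s%d", 1:10)))
  classes <- rep(c("tumor", "normal"), each = 5)
  vals[1:4, classes == "tumor"] <- vals[1:4, classes == "tumor"] + 20
  vals["E", classes == "tumor"] <- vals["E", classes == "tumor"] + 2
  vals["Ez", ] <- vals["E", ]  # |t| ties exactly; "E" < "Ez" wins
  ds2 <- expression_dataset(vals, classes)
  reps2 <- select_representatives(rownames(vals), ds2)
  expect_equal(nrow(reps2), 5)
  expect_true("E" %in% reps2$gene_id)
  expect_false("Ez" %in% reps2$gene_id)
})

test_that("planted genes dominate representatives at large effect size", {
  ok <- vapply(1:20, function(seed) {
    cfg <- simulation_config(n_genes = 100, n_planted_modules = 1,
                             module_size = 10, effect_size_delta = 3,
                             noise_sd = 1, seed = seed)
    st <- simulate_study(cfg)
    mod <- st$truth$planted_gene_sets[[1]]
    reps <- select_representatives(
      c(mod, setdiff(rownames(st$dataset$values), mod)[1:20]), st$dataset)
    all(reps$gene_id %in% mod)
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("sample clustering finds well-separated blobs and handles degeneracy", {
  set.seed(5)
  blob <- rbind(matrix(rnorm(6 * 3, 0, 0.1), 6),
                matrix(rnorm(6 * 3, 5, 0.1), 6))
  rownames(blob) <- sprintf("s%02d", 1:12)
  assign <- cluster_samples(blob, 2)
  expect_equal(length(unique(assign[1:6])), 1)
  expect_equal(length(unique(assign[7:12])), 1)
  expect_false(assign[1] == assign[7])
  # matches the brute-force best 2-partition by within-cluster SS
  # direct exhaustive search over all 2-partitions of the 12 points
  xs <- scale(blob)
  best_ss <- Inf
  ss_of <- function(part) {
    sum(vapply(unique(part), function(k) {
      m <- xs[part == k, , drop = FALSE]
      sum(sweep(m, 2, colMeans(m))^2)
    }, numeric(1)))
  }
  for (mask in 1:(2^12 - 2)) {
    part <- as.integer(intToBits(mask))[1:12]
    ss <- ss_of(part)
    if (ss < best_ss) { best_ss <- ss; best <- part }
  }
  expect_equal(ss_of(as.integer(assign == assign[1])), best_ss, tolerance = 1e-8)

  # duplicates co-cluster
  dup <- blob[c(1:12, 1), ]
  a2 <- cluster_samples(dup, 2)
  expect_equal(a2[13], a2[1])

  # identical samples: everything in cluster 1, flagged degenerate
  same <- matrix(1, 5, 3, dimnames = list(sprintf("s%d", 1:5), NULL))
  a3 <- cluster_samples(same, 2)
  expect_true(all(a3 == 1))
  expect_true(attr(a3, "degenerate"))
  expect_error(cluster_samples(same[1, , drop = FALSE], 2),
               class = "snm_invalid_input")
})

test_that("entropy score matches direct summation and its closed forms", {
  expect_equal(entropy_score(c(1, 1, 2, 2), c("t", "t", "n", "n")), 0)
  expect_equal(entropy_score(rep(1, 8), rep(c("t", "n"), 4)), 1)
  # two clusters of 4 with class counts (3,1) and (1,3)
  expect_equal(
    entropy_score(rep(1:2, each = 4),
                  c("t", "t", "t", "n", "t", "n", "n", "n")),
    0.8112781245, tolerance = 1e-9)
  expect_error(entropy_score(1:3, c("a", "b")), class = "snm_invalid_input")
})

test_that("entropy score is invariant under cluster and class relabeling", {
  set.seed(30)
  for (i in 1:50) {
    n <- sample(6:30, 1)
    assign <- sample(1:3, n, replace = TRUE)
    classes <- sample(c("tumor", "normal"), n, replace = TRUE)
    h <- entropy_score(assign, classes)
    expect_equal(h, oracle_entropy(assign, classes), tolerance = 1e-12)
    relab <- c(2, 3, 1)[assign]
    expect_equal(entropy_score(relab, classes), h, tolerance = 1e-12)
    flip <- ifelse(classes == "tumor", "normal", "tumor")
    expect_equal(entropy_score(assign, flip), h, tolerance = 1e-12)
    # zero iff every cluster pure
    pure <- all(vapply(unique(assign), function(k)
      length(unique(classes[assign == k])) == 1, logical(1)))
    expect_equal(h == 0, pure)
  }
})

test_that("overlap merging follows the Jaccard threshold and terminates", {
  ds <- tiny_dataset(n_genes = 12, seed = 77)
  genes <- rownames(ds$values)
  mk <- function(id, gs) score_subnetwork(list(id = id, genes = gs), ds)

  # identical sets merge to one
  s <- list(mk("A", genes[1:6]), mk("B", genes[1:6]))
  merged <- merge_overlapping(s, ds)
  expect_length(merged, 1)
  expect_equal(merged[[1]]$id, "A+B")

  # disjoint sets unchanged
  s2 <- list(mk("A", genes[1:5]), mk("B", genes[6:10]))
  expect_length(merge_overlapping(s2, ds), 2)

  # Jaccard 3/9 = 1/3 below default 0.5: unchanged
  s3 <- list(mk("A", genes[1:6]), mk("B", genes[4:9]))
  expect_length(merge_overlapping(s3, ds), 2)
  expect_length(merge_overlapping(s3, ds, jaccard_threshold = 1 / 3), 1)

  # idempotent at fixpoint
  m3 <- merge_overlapping(s3, ds, jaccard_threshold = 1 / 3)
  expect_equal(length(merge_overlapping(m3, ds, jaccard_threshold = 1 / 3)),
               length(m3))
})

test_that("ranking sorts by entropy then conductance then id", {
  mk <- function(id, e, c) structure(
    list(id = id, genes = "x", entropy = e, conductance = c),
    class = "scored_subnetwork")
  r <- rank_subnetworks(list(mk("a", 0.9, 0.1), mk("b", 0.1, 0.5),
                             mk("c", 0.5, 0.2)))
  expect_equal(vapply(r, `[[`, character(1), "id"), c("b", "c", "a"))
  r2 <- rank_subnetworks(list(mk("a", 0.5, 0.9), mk("b", 0.5, 0.2)))
  expect_equal(vapply(r2, `[[`, character(1), "id"), c("b", "a"))
  expect_equal(vapply(r2, `[[`, integer(1), "rank"), 1:2)
})
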