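#' IQR-modified Welch statistic
#'
#' A robust two-group location statistic: medians replace means and the
#' Gaussian-consistent robust scale IQR/1.349 replaces the standard
#' deviation in the Welch formula,
#' `t = (median(a) - median(b)) / sqrt(s_a^2/n_a + s_b^2/n_b)`.
#' Quartiles use linear-interpolation quantiles (type 7). When both IQRs
#' are zero the statistic is undefined and `NA` is returned.
#'
#' @param values_a,values_b numeric vectors with at least 2 values each.
#' @return signed real, or `NA` when both robust scales are zero.
#' @export
iqr_welch_t <- function(values_a, values_b) {
  if (length(values_a) < 2L || length(values_b) < 2L)
    snm_error("snm_invalid_input", "each group needs at least 2 values")
  s_a <- stats::IQR(values_a, type = 7) / 1.349
  s_b <- stats::IQR(values_b, type = 7) / 1.349
  if (s_a == 0 && s_b == 0) return(NA_real_)
  (stats::median(values_a) - stats::median(values_b)) /
    sqrt(s_a^2 / length(values_a) + s_b^2 / length(values_b))
}

# classical Welch t statistic (behind the `statistic = "welch"` switch)
plain_welch_t <- function(values_a, values_b) {
  if (length(values_a) < 2L || length(values_b) < 2L)
    snm_error("snm_invalid_input", "each group needs at least 2 values")
  va <- stats::var(values_a); vb <- stats::var(values_b)
  if (va == 0 && vb == 0) return(NA_real_)
  (mean(values_a) - mean(values_b)) /
    sqrt(va / length(values_a) + vb / length(values_b))
}

# per-gene statistics (tumor minus normal) for a set of genes
gene_statistics <- function(dataset, genes, statistic = c("iqr_welch", "welch")) {
  statistic <- match.arg(statistic)
  fn <- if (statistic == "iqr_welch") iqr_welch_t else plain_welch_t
  tumor <- dataset$class_labels == "tumor"
  vapply(genes, function(g) {
    fn(dataset$values[g, tumor], dataset$values[g, !tumor])
  }, numeric(1))
}

#' Select representative genes for a subnetwork
#'
#' The (up to) five most differentially expressed genes by absolute
#' IQR-modified Welch statistic, ties broken by gene id ascending. Genes
#' with an undefined statistic (zero robust scale in both groups) are
#' excluded.
#'
#' @param genes character vector of the subnetwork's gene ids (present in
#'   the dataset).
#' @param dataset an [expression_dataset] with both classes.
#' @param n_representatives maximum number selected (default 5).
#' @param statistic `"iqr_welch"` (default) or plain `"welch"`.
#' @return data.frame with columns `gene_id`, `t_iqr`, `direction`
#'   (`"up"` iff the statistic is positive, i.e. higher in tumor), ordered
#'   by `|t_iqr|` descending.
#' @export
select_representatives <- function(genes, dataset, n_representatives = 5L,
                                   statistic = c("iqr_welch", "welch")) {
  t_vals <- gene_statistics(dataset, genes, match.arg(statistic))
  ok <- is.finite(t_vals)
  if (!any(ok))
    snm_error("snm_unusable_subnetwork",
              "no gene with a finite statistic in this subnetwork")
  df <- data.frame(gene_id = genes[ok], t_iqr = unname(t_vals[ok]),
                   stringsAsFactors = FALSE)
  df <- df[order(-abs(df$t_iqr), df$gene_id), , drop = FALSE]
  df <- utils::head(df, n_representatives)
  df$direction <- ifelse(df$t_iqr > 0, "up", "down")
  rownames(df) <- NULL
  df
}

#' Cluster samples on representative-gene expression
#'
#' K-means (Lloyd iterations, squared-Euclidean assignment) on the samples
#' by representative-genes matrix, each gene standardized to zero mean and
#' unit variance across samples. Initialization is deterministic: the two
#' samples at maximum pairwise city-block distance seed the first two
#' centroids (further centroids, if requested, by the farthest-point rule).
#' Converges when centroids move less than `1e-8` or after 300 iterations.
#' If all samples are identical every sample is assigned to cluster 1 and
#' the result is flagged degenerate.
#'
#' @param rep_matrix numeric matrix, samples in rows, representative genes
#'   in columns (raw expression; standardization happens internally).
#' @param n_clusters number of clusters (default 2).
#' @return integer vector of cluster assignments (1-based) with attribute
#'   `degenerate`.
#' @export
cluster_samples <- function(rep_matrix, n_clusters = 2L) {
  n <- nrow(rep_matrix)
  if (n < n_clusters)
    snm_error("snm_invalid_input", "fewer samples than clusters")
  x <- apply(rep_matrix, 2L, function(col) {
    s <- stats::sd(col)
    if (s == 0) rep(0, length(col)) else (col - mean(col)) / s
  })
  x <- matrix(x, nrow = n, dimnames = dimnames(rep_matrix))
  d <- as.matrix(stats::dist(x, method = "manhattan"))
  if (max(d) == 0) {
    out <- rep(1L, n)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  ij <- which(d == max(d), arr.ind = TRUE)
  ij <- ij[order(ij[, 1L], ij[, 2L]), , drop = FALSE][1L, ]
  centers <- x[c(min(ij), max(ij)), , drop = FALSE]
  while (nrow(centers) < n_clusters) {
    dmin <- apply(x, 1L, function(p) {
      min(colSums((t(centers) - p)^2))
    })
    centers <- rbind(centers, x[which.max(dmin), , drop = FALSE])
  }
  assign <- integer(n)
  for (iter in seq_len(300L)) {
    d2 <- vapply(seq_len(nrow(centers)), function(k) {
      rowSums((x - matrix(centers[k, ], n, ncol(x), byrow = TRUE))^2)
    }, numeric(n))
    d2 <- matrix(d2, nrow = n)
    assign <- max.col(-d2, ties.method = "first")
    new_centers <- centers
    for (k in seq_len(nrow(centers))) {
      if (any(assign == k))
        new_centers[k, ] <- colMeans(x[assign == k, , drop = FALSE])
    }
    if (max(abs(new_centers - centers)) < 1e-8) {
      centers <- new_centers
      break
    }
    centers <- new_centers
  }
  out <- assign
  attr(out, "degenerate") <- FALSE
  out
}

#' Entropy score of a sample clustering against class labels
#'
#' Weighted mean class entropy over clusters:
#' `H = sum_c (n_c/N) * H_c` with `H_c = -sum_k p_ck log2 p_ck` over class
#' proportions within cluster c (`0 log 0 = 0`). Zero means every cluster
#' is class-pure; for two classes the ceiling is 1 bit. Lower scores mark
#' better subnetwork markers.
#'
#' @param assignments per-sample cluster labels.
#' @param class_labels per-sample classes.
#' @return entropy in bits.
#' @export
entropy_score <- function(assignments, class_labels) {
  if (length(assignments) != length(class_labels))
    snm_error("snm_invalid_input", "assignments and class_labels differ in length")
  n <- length(assignments)
  h <- 0
  for (cl in unique(assignments)) {
    in_c <- assignments == cl
    p <- table(class_labels[in_c]) / sum(in_c)
    p <- p[p > 0]
    h <- h + (sum(in_c) / n) * (-sum(p * log2(p)))
  }
  unname(h)
}

#' Score one candidate subnetwork
#'
#' Computes per-gene differential statistics, selects representatives,
#' clusters samples on them and attaches the entropy score and
#' conductance.
#'
#' @param candidate list with `id` and `genes` (see [partition_network()]).
#' @param dataset an [expression_dataset] with both classes.
#' @param network igraph used for conductance (optional; `NA` when absent).
#' @param n_clusters clusters for the entropy step (default 2 = classes).
#' @param statistic differential statistic variant.
#' @return a `scored_subnetwork` list: `id`, `genes`, `representatives`,
#'   `gene_directions` (named up/down over all finite-statistic genes),
#'   `entropy`, `conductance`, `degenerate`.
#' @export
score_subnetwork <- function(candidate, dataset, network = NULL,
                             n_clusters = 2L,
                             statistic = c("iqr_welch", "welch")) {
  statistic <- match.arg(statistic)
  genes <- intersect(candidate$genes, rownames(dataset$values))
  if (!length(genes))
    snm_error("snm_unusable_subnetwork", "no subnetwork gene present in dataset")
  t_vals <- gene_statistics(dataset, genes, statistic)
  ok <- is.finite(t_vals)
  if (!any(ok))
    snm_error("snm_unusable_subnetwork",
              "no gene with a finite statistic in this subnetwork")
  reps <- select_representatives(genes, dataset, statistic = statistic)
  rm_mat <- t(dataset$values[reps$gene_id, , drop = FALSE])
  assign <- cluster_samples(rm_mat, n_clusters)
  cond <- NA_real_
  if (!is.null(network)) {
    present <- intersect(genes, igraph::V(network)$name)
    if (length(present) && length(present) < igraph::vcount(network))
      cond <- conductance(network, present)
  }
  structure(list(
    id = candidate$id,
    genes = sort(genes),
    representatives = reps,
    gene_directions = stats::setNames(
      ifelse(t_vals[ok] > 0, "up", "down"), genes[ok]),
    entropy = entropy_score(assign, dataset$class_labels),
    conductance = cond,
    degenerate = isTRUE(attr(assign, "degenerate"))
  ), class = "scored_subnetwork")
}

#' Merge significantly overlapping subnetworks
#'
#' Repeatedly merges the pair with the highest Jaccard overlap of gene
#' sets at or above `jaccard_threshold` (union of gene sets;
#' representatives, entropy and conductance recomputed) until no pair
#' qualifies. The max-overlap rule with id tie-breaking makes the result
#' order-independent.
#'
#' @param scored list of `scored_subnetwork` objects.
#' @param dataset dataset used for rescoring merged candidates.
#' @param network igraph for conductance of merged candidates.
#' @param jaccard_threshold overlap needed to merge, in (0, 1]; default 0.5.
#' @param ... passed to [score_subnetwork()] for rescoring.
#' @return list of `scored_subnetwork`, merges applied.
#' @export
merge_overlapping <- function(scored, dataset, network = NULL,
                              jaccard_threshold = 0.5, ...) {
  if (jaccard_threshold <= 0 || jaccard_threshold > 1)
    snm_error("snm_invalid_config", "jaccard_threshold must lie in (0, 1]")
  repeat {
    n <- length(scored)
    if (n < 2L) break
    best <- NULL
    best_j <- -1
    for (i in seq_len(n - 1L)) {
      for (j in seq((i + 1L), n)) {
        gi <- scored[[i]]$genes; gj <- scored[[j]]$genes
        jac <- length(intersect(gi, gj)) / length(union(gi, gj))
        ids <- sort(c(scored[[i]]$id, scored[[j]]$id))
        if (jac > best_j ||
            (jac == best_j && !is.null(best) &&
             paste(ids, collapse = "|") < paste(best$ids, collapse = "|"))) {
          best_j <- jac
          best <- list(i = i, j = j, ids = ids)
        }
      }
    }
    if (best_j < jaccard_threshold) break
    merged_candidate <- list(
      id = paste(best$ids, collapse = "+"),
      genes = sort(union(scored[[best$i]]$genes, scored[[best$j]]$genes)))
    merged <- score_subnetwork(merged_candidate, dataset, network, ...)
    scored <- c(scored[-c(best$i, best$j)], list(merged))
  }
  scored
}

#' Rank scored subnetworks
#'
#' Ascending entropy score (lower = better marker); ties broken by
#' conductance ascending, then id.
#'
#' @param scored list of `scored_subnetwork`.
#' @return the list reordered, each element gaining a `rank` field.
#' @export
rank_subnetworks <- function(scored) {
  ent <- vapply(scored, `[[`, numeric(1), "entropy")
  cond <- vapply(scored, function(s) {
    if (is.na(s$conductance)) Inf else s$conductance
  }, numeric(1))
  ids <- vapply(scored, `[[`, character(1), "id")
  ord <- order(ent, cond, ids)
  scored <- scored[ord]
  for (k in seq_along(scored)) scored[[k]]$rank <- k
  scored
}

#' Discover and rank subnetworks
#'
#' Scores every candidate (skipping unusable ones with a message), merges
#' overlapping candidates and ranks by entropy.
#'
#' @param dataset an [expression_dataset] with both classes.
#' @param candidates list from [partition_network()].
#' @param network igraph for conductance.
#' @param jaccard_threshold merge threshold (default 0.5).
#' @param n_clusters clusters in the entropy step.
#' @param statistic differential statistic variant.
#' @return ranked list of `scored_subnetwork`.
#' @export
discover_subnetworks <- function(dataset, candidates, network = NULL,
                                 jaccard_threshold = 0.5, n_clusters = 2L,
                                 statistic = c("iqr_welch", "welch")) {
  statistic <- match.arg(statistic)
  scored <- list()
  for (cand in candidates) {
    s <- tryCatch(
      score_subnetwork(cand, dataset, network, n_clusters, statistic),
      subnetmark_error = function(e) {
        message(sprintf("discover: skipping %s (%s)", cand$id, conditionMessage(e)))
        NULL
      })
    if (!is.null(s)) scored[[length(scored) + 1L]] <- s
  }
  if (!length(scored))
    snm_error("snm_unusable_subnetwork", "no usable candidate subnetwork")
  scored <- merge_overlapping(scored, dataset, network,
                              jaccard_threshold = jaccard_threshold,
                              n_clusters = n_clusters, statistic = statistic)
  rank_subnetworks(scored)
}

#' Summarise discovery results as a data frame
#'
#' @param scored ranked list from [discover_subnetworks()].
#' @return data.frame with one row per subnetwork.
#' @export
discovery_table <- function(scored) {
  data.frame(
    rank = vapply(scored, function(s) s$rank %||% NA_integer_, integer(1)),
    subnetwork_id = vapply(scored, `[[`, character(1), "id"),
    n_genes = vapply(scored, function(s) length(s$genes), integer(1)),
    entropy = vapply(scored, `[[`, numeric(1), "entropy"),
    conductance = vapply(scored, `[[`, numeric(1), "conductance"),
    representatives = vapply(scored, function(s)
      paste(s$representatives$gene_id, collapse = ","), character(1)),
    stringsAsFactors = FALSE)
}
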