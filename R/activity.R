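#' Per-sample activity score of a subnetwork
#'
#' The metagene activity of a subnetwork in sample j is the mean expression
#' of its up-regulated genes minus the mean expression of its down-regulated
#' genes: `a_j = mean(x[Up, j]) - mean(x[Down, j])`. With one side empty the
#' other side's (possibly negated) mean is used. Directions come from the
#' subnetwork's training-set statistics (frozen at discovery time), so
#' scoring a held-out dataset never re-estimates them.
#'
#' @param subnetwork a `scored_subnetwork` (see [score_subnetwork()]).
#' @param dataset an [expression_dataset]; may be held-out data.
#' @param gene_scope `"all_genes"` (default) uses every subnetwork gene with
#'   a finite training statistic, directions by its sign; `"representatives"`
#'   restricts to the (up to 5) representative genes.
#' @return named numeric vector, one score per sample.
#' @export
activity_score <- function(subnetwork, dataset,
                           gene_scope = c("all_genes", "representatives")) {
  gene_scope <- match.arg(gene_scope)
  dirs <- if (gene_scope == "all_genes") {
    subnetwork$gene_directions
  } else {
    stats::setNames(subnetwork$representatives$direction,
                    subnetwork$representatives$gene_id)
  }
  dirs <- dirs[names(dirs) %in% rownames(dataset$values)]
  up <- names(dirs)[dirs == "up"]
  down <- names(dirs)[dirs == "down"]
  if (!length(up) && !length(down))
    snm_error("snm_invalid_input", "both direction sets are empty")
  a <- if (length(up)) colMeans(dataset$values[up, , drop = FALSE]) else
    stats::setNames(rep(0, ncol(dataset$values)), colnames(dataset$values))
  d <- if (length(down)) colMeans(dataset$values[down, , drop = FALSE]) else
    stats::setNames(rep(0, ncol(dataset$values)), colnames(dataset$values))
  a - d
}

#' Activity matrix for a set of subnetworks
#'
#' @param subnetworks list of `scored_subnetwork`.
#' @param dataset an [expression_dataset].
#' @param gene_scope see [activity_score()].
#' @return numeric matrix, subnetworks in rows (ids as rownames), samples
#'   in columns.
#' @export
activity_matrix <- function(subnetworks, dataset,
                            gene_scope = c("all_genes", "representatives")) {
  gene_scope <- match.arg(gene_scope)
  scores <- t(vapply(subnetworks, activity_score, dataset = dataset,
                     gene_scope = gene_scope,
                     FUN.VALUE = numeric(ncol(dataset$values))))
  rownames(scores) <- vapply(subnetworks, `[[`, character(1), "id")
  colnames(scores) <- colnames(dataset$values)
  scores
}

#' Welch's two-sample t-test
#'
#' Classical Welch statistic with Satterthwaite degrees of freedom and a
#' two-sided p-value. Degenerate input (zero variance in both groups)
#' yields a flagged record with `p = 1` by convention.
#'
#' @param scores_a,scores_b numeric vectors, each with at least 2 values.
#' @return list with `t`, `df`, `p`, `degenerate`.
#' @export
welch_test <- function(scores_a, scores_b) {
  if (length(scores_a) < 2L || length(scores_b) < 2L)
    snm_error("snm_invalid_input", "each group needs at least 2 values")
  res <- tryCatch(stats::t.test(scores_a, scores_b, var.equal = FALSE),
                  error = function(e) NULL)
  if (is.null(res)) {
    return(list(t = 0, df = NA_real_, p = 1, degenerate = TRUE))
  }
  list(t = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value, degenerate = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment (sort ascending, `q_i = min_{j >= i} m p_j / j`
#' clipped at 1, returned in the original order).
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values in the original order.
#' @export
bh_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    snm_error("snm_invalid_input", "p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Test subnetwork activity for tumor/normal differences
#'
#' Welch tests on each subnetwork's activity scores between tumor and
#' normal samples, Benjamini-Hochberg correction across subnetworks, and
#' selection at adjusted p strictly below `alpha`.
#'
#' @param activity activity matrix from [activity_matrix()].
#' @param class_labels per-sample classes aligned to the matrix columns.
#' @param alpha selection threshold on the adjusted p-value (default 1e-5).
#' @return data.frame with columns `subnetwork_id`, `welch_t`, `df`,
#'   `p_raw`, `p_adjusted`, `degenerate`, `selected`.
#' @export
significance_records <- function(activity, class_labels, alpha = 1e-5) {
  tumor <- class_labels == "tumor"
  tests <- lapply(seq_len(nrow(activity)), function(i) {
    welch_test(activity[i, tumor], activity[i, !tumor])
  })
  rec <- data.frame(
    subnetwork_id = rownames(activity),
    welch_t = vapply(tests, `[[`, numeric(1), "t"),
    df = vapply(tests, `[[`, numeric(1), "df"),
    p_raw = vapply(tests, `[[`, numeric(1), "p"),
    degenerate = vapply(tests, `[[`, logical(1), "degenerate"),
    stringsAsFactors = FALSE)
  rec$p_adjusted <- bh_adjust(rec$p_raw)
  rec$selected <- rec$p_adjusted < alpha
  rec
}

#' Select significant subnetworks
#'
#' @param records data.frame from [significance_records()].
#' @param alpha strict threshold on `p_adjusted` (default 1e-5).
#' @return the subset of records with `p_adjusted < alpha`, `selected`
#'   set to `TRUE`.
#' @export
select_significant <- function(records, alpha = 1e-5) {
  out <- records[records$p_adjusted < alpha, , drop = FALSE]
  out$selected <- rep(TRUE, nrow(out))
  rownames(out) <- NULL
  out
}
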