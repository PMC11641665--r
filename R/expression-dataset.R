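#' Construct an expression dataset
#'
#' Bundles a genes-by-samples log2 expression matrix with per-sample class
#' labels (tumor/normal) and optional clinical covariates (survival time in
#' months, event indicator, estrogen-receptor status). All downstream
#' statistics operate on this container.
#'
#' @param values numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids). Missing values are not
#'   allowed.
#' @param class_labels optional character vector, one of `"tumor"` or
#'   `"normal"` per sample. When present both classes must occur.
#' @param clinical optional data.frame with columns `sample_id`,
#'   `survival_time` (non-negative, months), `event` (0/1) and optionally
#'   `er_status` (`"positive"`, `"negative"`, `"unknown"`). `survival_time`
#'   and `event` must be supplied together.
#' @return an object of class `expression_dataset` with fields `values`,
#'   `class_labels`, `clinical`.
#' @export
expression_dataset <- function(values, class_labels = NULL, clinical = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    snm_error("snm_non_numeric", "expression values must be a numeric matrix")
  gene_ids <- rownames(values)
  sample_ids <- colnames(values)
  if (is.null(gene_ids) || is.null(sample_ids))
    snm_error("snm_invalid_dataset", "values must have gene rownames and sample colnames")
  if (anyDuplicated(gene_ids))
    snm_error("snm_duplicate_gene_ids", sprintf(
      "duplicate gene ids: %s", paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", ")))
  if (anyDuplicated(sample_ids))
    snm_error("snm_duplicate_sample_ids", "duplicate sample ids")
  if (anyNA(values))
    snm_error("snm_missing_values", "missing expression values are not allowed")
  if (!is.null(class_labels)) {
    if (length(class_labels) != ncol(values))
      snm_error("snm_invalid_dataset", "class_labels length must equal number of samples")
    bad <- setdiff(unique(class_labels), c("tumor", "normal"))
    if (length(bad))
      snm_error("snm_invalid_dataset", sprintf("unknown class label(s): %s", paste(bad, collapse = ", ")))
    if (length(unique(class_labels)) < 2L)
      snm_error("snm_invalid_dataset", "need at least one sample of each class")
    names(class_labels) <- sample_ids
  }
  if (!is.null(clinical)) {
    clinical <- as.data.frame(clinical)
    if (!"sample_id" %in% names(clinical))
      snm_error("snm_invalid_dataset", "clinical table needs a sample_id column")
    has_t <- "survival_time" %in% names(clinical)
    has_e <- "event" %in% names(clinical)
    if (has_t != has_e)
      snm_error("snm_invalid_dataset", "survival_time and event must be supplied together")
    if (has_t) {
      if (any(clinical$survival_time < 0, na.rm = TRUE))
        snm_error("snm_invalid_dataset", "survival_time must be non-negative")
      if (!all(clinical$event %in% c(0L, 1L, NA)))
        snm_error("snm_invalid_dataset", "event must be 0/1")
    }
    if (!all(clinical$sample_id %in% sample_ids))
      snm_error("snm_invalid_dataset", "clinical sample_id not found among samples")
  }
  structure(
    list(values = values, class_labels = class_labels, clinical = clinical),
    class = "expression_dataset"
  )
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("expression_dataset: %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  if (!is.null(x$class_labels)) {
    tab <- table(x$class_labels)
    cat("  classes:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  if (!is.null(x$clinical))
    cat(sprintf("  clinical records: %d\n", nrow(x$clinical)))
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$values)

# subset a dataset by sample index/ids, keeping labels and clinical aligned
subset_samples <- function(dataset, idx) {
  ids <- colnames(dataset$values)[idx]
  clin <- dataset$clinical
  if (!is.null(clin)) {
    clin <- clin[clin$sample_id %in% ids, , drop = FALSE]
    if (nrow(clin) == 0L) clin <- NULL
  }
  labels <- dataset$class_labels[idx]
  if (!is.null(labels) && length(unique(labels)) < 2L) {
    # bypass the two-class invariant for internal fold slices
    out <- dataset
    out$values <- dataset$values[, idx, drop = FALSE]
    out$class_labels <- labels
    out$clinical <- clin
    return(out)
  }
  expression_dataset(dataset$values[, idx, drop = FALSE], labels, clin)
}
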