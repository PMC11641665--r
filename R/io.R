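#' Read a gene-expression matrix with sample annotation
#'
#' The expression file is TSV or CSV (by file extension) with a header row of
#' sample ids and gene identifiers in the first column. Class labels and
#' clinical covariates come from a companion annotation table with columns
#' `sample_id`, a label column (default `class`), and optionally
#' `survival_time`, `event`, `er_status`.
#'
#' @param path expression matrix file.
#' @param annotation_path optional annotation file (TSV/CSV).
#' @param label_column name of the class column in the annotation table.
#' @return an [expression_dataset].
#' @export
read_expression <- function(path, annotation_path = NULL, label_column = "class") {
  if (!file.exists(path))
    snm_error("snm_missing_file", sprintf("file not found: %s", path))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           colClasses = "character", quote = "")
  gene_ids <- raw[[1L]]
  if (anyDuplicated(gene_ids))
    snm_error("snm_duplicate_gene_ids", sprintf(
      "duplicate gene ids in %s: %s", path,
      paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", ")))
  num <- suppressWarnings(vapply(raw[-1L], as.numeric, numeric(nrow(raw))))
  num <- matrix(num, nrow = nrow(raw),
                dimnames = list(gene_ids, names(raw)[-1L]))
  if (anyNA(num))
    snm_error("snm_non_numeric", sprintf("non-numeric expression cell(s) in %s", path))

  class_labels <- NULL
  clinical <- NULL
  if (!is.null(annotation_path)) {
    if (!file.exists(annotation_path))
      snm_error("snm_missing_file", sprintf("file not found: %s", annotation_path))
    asep <- if (grepl("\\.csv$", annotation_path, ignore.case = TRUE)) "," else "\t"
    ann <- utils::read.table(annotation_path, header = TRUE, sep = asep,
                             check.names = FALSE, stringsAsFactors = FALSE, quote = "")
    if (!label_column %in% names(ann))
      snm_error("snm_missing_label_column", sprintf(
        "label column '%s' absent from %s", label_column, annotation_path))
    if (!"sample_id" %in% names(ann))
      snm_error("snm_missing_label_column", "annotation needs a sample_id column")
    rownames(ann) <- ann$sample_id
    missing <- setdiff(colnames(num), ann$sample_id)
    if (length(missing))
      snm_error("snm_invalid_dataset", sprintf(
        "samples without annotation: %s", paste(missing, collapse = ", ")))
    ann <- ann[colnames(num), , drop = FALSE]
    class_labels <- ann[[label_column]]
    clin_cols <- intersect(c("survival_time", "event", "er_status"), names(ann))
    if (length(clin_cols)) {
      clinical <- ann[, c("sample_id", clin_cols), drop = FALSE]
      if ("survival_time" %in% clin_cols)
        clinical <- clinical[!is.na(clinical$survival_time), , drop = FALSE]
      rownames(clinical) <- NULL
      if (nrow(clinical) == 0L) clinical <- NULL
    }
  }
  expression_dataset(num, class_labels, clinical)
}

#' Write an expression dataset (matrix + annotation)
#'
#' Deterministic TSV serialization; numbers carry 10 significant digits so
#' that identical datasets give byte-identical files.
#'
#' @param dataset an [expression_dataset].
#' @param path expression TSV path.
#' @param annotation_path optional annotation TSV path.
#' @export
write_expression <- function(dataset, path, annotation_path = NULL) {
  vals <- dataset$values
  lines <- c(
    paste(c("gene_id", colnames(vals)), collapse = "\t"),
    vapply(seq_len(nrow(vals)), function(i) {
      paste(c(rownames(vals)[i], snm_num(vals[i, ])), collapse = "\t")
    }, character(1))
  )
  writeLines(lines, path)
  if (!is.null(annotation_path)) {
    ann <- data.frame(sample_id = colnames(vals), stringsAsFactors = FALSE)
    if (!is.null(dataset$class_labels)) ann$class <- unname(dataset$class_labels)
    if (!is.null(dataset$clinical)) {
      clin <- dataset$clinical
      for (col in setdiff(names(clin), "sample_id")) {
        v <- clin[[col]][match(ann$sample_id, clin$sample_id)]
        ann[[col]] <- if (is.numeric(v)) snm_num(v) else ifelse(is.na(v), "NA", v)
      }
    }
    header <- paste(names(ann), collapse = "\t")
    rows <- apply(ann, 1L, function(r) paste(r, collapse = "\t"))
    writeLines(c(header, rows), annotation_path)
  }
  invisible(path)
}

#' Read a STRING-style interaction edge list
#'
#' Expects whitespace- or tab-separated columns `protein1 protein2
#' combined_score` (a header line is detected and skipped). Self-loops are
#' dropped, duplicate undirected edges keep the maximum score, and only
#' edges with `combined_score >= min_confidence` are retained. An optional
#' two-column mapping table translates protein ids to gene symbols; edges
#' with unmapped endpoints are dropped with a message.
#'
#' @param path edge-list file.
#' @param min_confidence minimum combined score kept (STRING 0-1000 scale;
#'   default 700, the usual "high confidence" cutoff).
#' @param id_map optional data.frame whose first two columns map protein id
#'   to gene id.
#' @return an [igraph][igraph::graph] with vertex names and an edge
#'   attribute `confidence`.
#' @export
read_network <- function(path, min_confidence = 700, id_map = NULL) {
  if (!file.exists(path))
    snm_error("snm_missing_file", sprintf("file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    snm_error("snm_parse_error", sprintf("empty edge list: %s", path))
  fields <- strsplit(trimws(lines), "[ \t]+")
  start <- 1L
  if (length(fields[[1L]]) >= 3L &&
      is.na(suppressWarnings(as.numeric(fields[[1L]][3L])))) {
    start <- 2L  # header line
  }
  n1 <- character(0); n2 <- character(0); sc <- numeric(0)
  for (i in seq(start, length(fields))) {
    f <- fields[[i]]
    if (length(f) != 3L)
      snm_error("snm_parse_error", sprintf(
        "malformed line %d in %s: expected 3 columns, got %d", i, path, length(f)))
    s <- suppressWarnings(as.numeric(f[3L]))
    if (is.na(s))
      snm_error("snm_parse_error", sprintf(
        "malformed line %d in %s: non-numeric score '%s'", i, path, f[3L]))
    n1 <- c(n1, f[1L]); n2 <- c(n2, f[2L]); sc <- c(sc, s)
  }
  if (!is.null(id_map)) {
    id_map <- as.data.frame(id_map)
    map <- stats::setNames(as.character(id_map[[2L]]), as.character(id_map[[1L]]))
    m1 <- unname(map[n1]); m2 <- unname(map[n2])
    unmapped <- is.na(m1) | is.na(m2)
    if (any(unmapped))
      message(sprintf("read_network: dropped %d edge(s) with unmapped ids", sum(unmapped)))
    n1 <- m1[!unmapped]; n2 <- m2[!unmapped]; sc <- sc[!unmapped]
  }
  keep <- n1 != n2
  n1 <- n1[keep]; n2 <- n2[keep]; sc <- sc[keep]
  # undirected dedup keeping the maximum score
  a <- pmin(n1, n2); b <- pmax(n1, n2)
  key <- paste(a, b, sep = "\r")
  if (length(key)) {
    sc <- vapply(split(sc, key), max, numeric(1))
    ab <- strsplit(names(sc), "\r", fixed = TRUE)
    a <- vapply(ab, `[`, character(1), 1L)
    b <- vapply(ab, `[`, character(1), 2L)
  }
  keep <- sc >= min_confidence
  a <- a[keep]; b <- b[keep]; sc <- sc[keep]
  ord <- order(a, b)
  g <- igraph::graph_from_data_frame(
    data.frame(from = a[ord], to = b[ord], confidence = sc[ord],
               stringsAsFactors = FALSE),
    directed = FALSE)
  g
}

#' Restrict a dataset and network to their common genes
#'
#' @param dataset an [expression_dataset].
#' @param network an igraph interaction network.
#' @return list with elements `dataset` and `network`, both restricted to
#'   the gene intersection; the dataset's gene order is preserved.
#' @export
restrict_to_common_genes <- function(dataset, network) {
  common <- intersect(rownames(dataset$values), igraph::V(network)$name)
  if (!length(common))
    snm_error("snm_empty_intersection",
              "dataset and network share no genes")
  common <- rownames(dataset$values)[rownames(dataset$values) %in% common]
  ds <- dataset
  ds$values <- dataset$values[common, , drop = FALSE]
  net <- igraph::induced_subgraph(network, common)
  list(dataset = ds, network = net)
}

#' Serialize a report deterministically
#'
#' Structured reports (lists) are written as JSON with stable key order and
#' 10-significant-digit floats; matrices (e.g. an activity matrix,
#' subnetworks in rows and samples in columns) are written as TSV. Writing
#' the same report twice yields byte-identical files.
#'
#' @param report a named list (JSON) or numeric matrix (TSV).
#' @param path output file.
#' @export
write_report <- function(report, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  if (is.matrix(report)) {
    lines <- c(
      paste(c("id", colnames(report)), collapse = "\t"),
      vapply(seq_len(nrow(report)), function(i) {
        paste(c(rownames(report)[i], snm_num(report[i, ])), collapse = "\t")
      }, character(1))
    )
    writeLines(lines, path)
  } else {
    json <- jsonlite::toJSON(report, auto_unbox = TRUE, digits = I(10),
                             null = "null", na = "null", pretty = TRUE)
    writeLines(json, path)
  }
  invisible(path)
}

#' Read back a serialized report
#'
#' @param path file written by [write_report()].
#' @return a list (JSON reports) or numeric matrix (TSV reports).
#' @export
read_report <- function(path) {
  if (!file.exists(path))
    snm_error("snm_missing_file", sprintf("file not found: %s", path))
  first <- readLines(path, n = 1L)
  if (grepl("^\\s*[{\\[]", first)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             check.names = FALSE, quote = "")
    m <- as.matrix(tab[-1L])
    rownames(m) <- tab[[1L]]
    m
  }
}
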