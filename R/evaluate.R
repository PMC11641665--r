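#' Evaluate planted-module recovery of a discovery result
#'
#' Matches each planted module to the discovered subnetwork containing the
#' largest share of its genes (a hit requires at least half of the module)
#' and summarises whether the planted modules occupy the top entropy ranks
#' and clear the significance threshold.
#'
#' @param scored ranked list from [discover_subnetworks()].
#' @param records data.frame from [significance_records()] (optional; the
#'   significance summary is `NA` without it).
#' @param truth truth list with `planted_gene_sets`.
#' @param alpha adjusted-p threshold used for `all_significant`.
#' @return list with `hits` (per-module data.frame: subnetwork id, rank,
#'   overlap, p_adjusted), `top_ranked` (all modules matched, distinct, and
#'   occupying ranks 1..n_modules) and `all_significant`.
#' @export
evaluate_recovery <- function(scored, records = NULL, truth, alpha = 1e-5) {
  mods <- truth$planted_gene_sets
  if (!length(mods))
    return(list(hits = NULL, top_ranked = NA, all_significant = NA))
  ids <- vapply(scored, `[[`, character(1), "id")
  ranks <- vapply(scored, function(s) s$rank %||% NA_integer_, integer(1))
  hits <- do.call(rbind, lapply(seq_along(mods), function(m) {
    mod <- mods[[m]]
    ov <- vapply(scored, function(s) length(intersect(s$genes, mod)),
                 integer(1))
    best <- which.max(ov)
    hit <- ov[best] >= length(mod) / 2
    data.frame(
      module = names(mods)[m] %||% as.character(m),
      subnetwork_id = if (hit) ids[best] else NA_character_,
      rank = if (hit) ranks[best] else NA_integer_,
      overlap = ov[best], module_size = length(mod),
      p_adjusted = if (hit && !is.null(records))
        records$p_adjusted[match(ids[best], records$subnetwork_id)]
      else NA_real_,
      stringsAsFactors = FALSE)
  }))
  matched <- !is.na(hits$rank)
  top_ranked <- all(matched) &&
    anyDuplicated(hits$subnetwork_id) == 0L &&
    setequal(hits$rank, seq_len(nrow(hits)))
  all_significant <- if (is.null(records)) NA else
    all(matched) && all(hits$p_adjusted < alpha)
  list(hits = hits, top_ranked = top_ranked, all_significant = all_significant)
}

#' Run discovery and significance on a simulated study
#'
#' Convenience wrapper used by the acceptance surface: partitions the
#' study's network, discovers and ranks subnetworks, computes the activity
#' matrix and significance records.
#'
#' @param study list from [simulate_study()].
#' @param partition a [partition_config()].
#' @param alpha selection threshold.
#' @param gene_scope activity gene scope.
#' @param jaccard_threshold merge threshold.
#' @return list with `scored`, `activity`, `records`, `dataset`, `network`.
#' @export
discover_study <- function(study, partition = partition_config(),
                           alpha = 1e-5, gene_scope = "all_genes",
                           jaccard_threshold = 0.5) {
  both <- restrict_to_common_genes(study$dataset, study$network)
  cand <- partition_network(both$network, partition)
  scored <- discover_subnetworks(both$dataset, cand, both$network,
                                 jaccard_threshold = jaccard_threshold)
  act <- activity_matrix(scored, both$dataset, gene_scope)
  rec <- significance_records(act, both$dataset$class_labels, alpha)
  list(scored = scored, activity = act, records = rec,
       dataset = both$dataset, network = both$network)
}
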