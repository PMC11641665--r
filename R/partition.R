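#' Partition configuration
#'
#' @param min_size smallest cluster emitted (smaller clusters are absorbed
#'   into the neighbouring cluster sharing the most edges).
#' @param max_size largest cluster allowed before a spectral split.
#' @param boundary_expansion add 1-hop neighbour nodes with strictly more
#'   than half their edges inside the cluster (lets candidates overlap).
#' @return a `partition_config` list.
#' @export
partition_config <- function(min_size = 8L, max_size = 50L,
                             boundary_expansion = TRUE) {
  if (min_size > max_size)
    snm_error("snm_invalid_config", "min_size must not exceed max_size")
  structure(list(min_size = as.integer(min_size),
                 max_size = as.integer(max_size),
                 boundary_expansion = isTRUE(boundary_expansion)),
            class = "partition_config")
}

# Fiedler bipartition of the node set `nodes` (names) of graph g.
# Confidence-weighted Laplacian, weights scaled to [0,1]; eigenvector sign
# fixed by making its first nonzero entry (sorted-name order) positive;
# exact zeros go to the positive side.
fiedler_split <- function(g, nodes) {
  nodes <- sort(nodes)
  sub <- igraph::induced_subgraph(g, nodes)
  attr_name <- if ("confidence" %in% igraph::edge_attr_names(sub)) "confidence" else NULL
  W <- as.matrix(igraph::as_adjacency_matrix(sub, attr = attr_name, sparse = TRUE))
  W <- W[nodes, nodes, drop = FALSE]
  if (!is.null(attr_name)) W <- W / 1000
  L <- diag(rowSums(W)) - W
  ev <- eigen(L, symmetric = TRUE)
  v <- ev$vectors[, ncol(ev$vectors) - 1L]
  v[abs(v) < 1e-12] <- 0
  nz <- which(v != 0)
  if (length(nz) && v[nz[1L]] < 0) v <- -v
  pos <- nodes[v >= 0]
  neg <- nodes[v < 0]
  if (!length(neg) || !length(pos)) {
    # numerically degenerate: fall back to a balanced ordered split
    half <- floor(length(nodes) / 2)
    ord <- order(v, nodes)
    neg <- nodes[ord[seq_len(half)]]
    pos <- setdiff(nodes, neg)
  }
  list(pos = pos, neg = neg)
}

# connected components of a node subset, each sorted
node_components <- function(g, nodes) {
  sub <- igraph::induced_subgraph(g, nodes)
  comp <- igraph::components(sub)
  lapply(seq_len(comp$no), function(k) {
    sort(igraph::V(sub)$name[comp$membership == k])
  })
}

#' Partition an interaction network into candidate subnetworks
#'
#' Recursive spectral bisection: any connected component larger than
#' `max_size` is split by the sign of its Fiedler vector (second-smallest
#' eigenvector of the confidence-weighted Laplacian), recursing until every
#' cluster has at most `max_size` nodes. Clusters smaller than `min_size`
#' are absorbed into the neighbouring cluster sharing the most edges
#' (preferring merges that keep the result within `max_size`). With
#' `boundary_expansion`, each cluster finally adds 1-hop neighbours that
#' have strictly more than half of their edges inside it, which may create
#' overlaps between candidates. Output order is deterministic: clusters
#' sorted by their lexicographically smallest member.
#'
#' @param network igraph interaction network.
#' @param config a [partition_config()].
#' @return list of candidates, each a list with `id`, `genes` (sorted,
#'   after any expansion), `core_genes` (the disjoint partition cell) and
#'   an `undersized` flag (set when an isolated component smaller than
#'   `min_size` could not be absorbed).
#' @export
partition_network <- function(network, config = partition_config()) {
  if (igraph::vcount(network) == 0L)
    snm_error("snm_invalid_config", "network is empty")
  clusters <- list()
  recurse <- function(nodes) {
    if (length(nodes) <= config$max_size) {
      clusters[[length(clusters) + 1L]] <<- sort(nodes)
      return(invisible(NULL))
    }
    sp <- fiedler_split(network, nodes)
    for (side in list(sp$pos, sp$neg)) {
      for (comp in node_components(network, side)) recurse(comp)
    }
  }
  for (comp in node_components(network, igraph::V(network)$name)) recurse(comp)

  edge_list <- igraph::as_edgelist(network, names = TRUE)
  count_between <- function(a, b) {
    sum((edge_list[, 1L] %in% a & edge_list[, 2L] %in% b) |
        (edge_list[, 1L] %in% b & edge_list[, 2L] %in% a))
  }

  # absorb undersized clusters; isolated ones stay flagged
  undersized_flag <- rep(FALSE, length(clusters))
  repeat {
    sizes <- lengths(clusters)
    small <- which(sizes < config$min_size & !undersized_flag)
    if (!length(small)) break
    small <- small[order(sizes[small],
                         vapply(clusters[small], `[`, character(1), 1L))]
    i <- small[1L]
    nb <- vapply(seq_along(clusters), function(j) {
      if (j == i) 0L else count_between(clusters[[i]], clusters[[j]])
    }, integer(1))
    if (all(nb == 0L)) {
      undersized_flag[i] <- TRUE
      next
    }
    fits <- nb > 0L & (sizes + sizes[i]) <= config$max_size
    pool <- if (any(fits)) which(fits) else which(nb > 0L)
    best <- pool[order(-nb[pool],
                       vapply(clusters[pool], `[`, character(1), 1L))][1L]
    merged <- sort(c(clusters[[i]], clusters[[best]]))
    clusters <- c(clusters[-c(i, best)], list(merged))
    undersized_flag <- c(undersized_flag[-c(i, best)], FALSE)
  }

  ord <- order(vapply(clusters, `[`, character(1), 1L))
  clusters <- clusters[ord]
  undersized_flag <- undersized_flag[ord]

  deg <- igraph::degree(network)
  vnames <- igraph::V(network)$name
  out <- vector("list", length(clusters))
  for (k in seq_along(clusters)) {
    core <- clusters[[k]]
    genes <- core
    if (config$boundary_expansion) {
      nbr_idx <- setdiff(unique(unlist(igraph::adjacent_vertices(network, core))),
                         match(core, vnames))
      nbr_names <- vnames[nbr_idx]
      if (length(nbr_names)) {
        inside <- vapply(nbr_names, function(v) count_between(v, core), integer(1))
        qualify <- nbr_names[inside > deg[nbr_names] / 2]
        if (length(qualify) > length(core)) {
          # guard: expansion adds at most |cluster| extra nodes
          qs <- qualify[order(-inside[match(qualify, nbr_names)], qualify)]
          qualify <- qs[seq_len(length(core))]
          message(sprintf("partition: boundary expansion capped for cluster %d", k))
        }
        genes <- sort(c(core, qualify))
      }
    }
    out[[k]] <- list(id = sprintf("SN%03d", k), genes = genes,
                     core_genes = core, undersized = undersized_flag[k])
  }
  out
}

#' Conductance of a node set
#'
#' Number of cut edges divided by the smaller of the two sides' total
#' degree (edge counts; a low value means a closely connected cluster).
#'
#' @param network igraph interaction network.
#' @param gene_set character vector of node names; must be a non-empty
#'   proper subset of the nodes.
#' @return real in \[0, 1\].
#' @export
conductance <- function(network, gene_set) {
  all_nodes <- igraph::V(network)$name
  gene_set <- intersect(all_nodes, gene_set)
  if (!length(gene_set) || length(setdiff(all_nodes, gene_set)) == 0L)
    snm_error("snm_invalid_config",
              "gene_set must be a non-empty proper subset of the nodes")
  el <- igraph::as_edgelist(network, names = TRUE)
  in1 <- el[, 1L] %in% gene_set
  in2 <- el[, 2L] %in% gene_set
  cut <- sum(xor(in1, in2))
  deg <- igraph::degree(network)
  vol_in <- sum(deg[gene_set])
  vol_out <- sum(deg) - vol_in
  denom <- min(vol_in, vol_out)
  if (denom == 0) return(0)
  cut / denom
}

#' Candidate membership as a data frame
#'
#' @param candidates list from [partition_network()].
#' @return data.frame with columns `subnetwork_id`, `gene_id`.
#' @export
membership_table <- function(candidates) {
  data.frame(
    subnetwork_id = rep(vapply(candidates, `[[`, character(1), "id"),
                        lengths(lapply(candidates, `[[`, "genes"))),
    gene_id = unlist(lapply(candidates, `[[`, "genes")),
    stringsAsFactors = FALSE, row.names = NULL)
}
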