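# programmatic fixtures shared across test files

tiny_dataset <- function(n_genes = 6, n_tumor = 5, n_normal = 4, seed = 42,
                         shift_genes = character(0), delta = 0) {
  set.seed(seed)
  genes <- sprintf("g%02d", seq_len(n_genes))
  samples <- c(sprintf("T%02d", seq_len(n_tumor)),
               sprintf("N%02d", seq_len(n_normal)))
  classes <- c(rep("tumor", n_tumor), rep("normal", n_normal))
  vals <- matrix(rnorm(n_genes * length(samples), 7, 1), n_genes,
                 dimnames = list(genes, samples))
  vals[shift_genes, classes == "tumor"] <-
    vals[shift_genes, classes == "tumor"] + delta
  expression_dataset(vals, classes)
}

write_expression_fixture <- function(lines, ext = "tsv") {
  path <- tempfile(fileext = paste0(".", ext))
  writeLines(lines, path)
  path
}

# two 10-cliques (igraph, confidence 999)
two_cliques <- function(size = 10) {
  g1 <- igraph::make_full_graph(size)
  igraph::V(g1)$name <- sprintf("a%02d", seq_len(size))
  g2 <- igraph::make_full_graph(size)
  igraph::V(g2)$name <- sprintf("b%02d", seq_len(size))
  g <- igraph::disjoint_union(g1, g2)
  igraph::E(g)$confidence <- 999
  g
}

barbell_graph <- function(size = 12) {
  g <- two_cliques(size)
  g <- igraph::add_edges(g, c("a01", "b01"))
  igraph::E(g)$confidence <- 999
  g
}

path_graph <- function(n = 30) {
  g <- igraph::make_ring(n, circular = FALSE)
  igraph::V(g)$name <- sprintf("p%02d", seq_len(n))
  igraph::E(g)$confidence <- 999
  g
}

random_clinical <- function(n = 20, seed = 1) {
  set.seed(seed)
  data.frame(
    sample_id = sprintf("T%03d", seq_len(n)),
    survival_time = round(rexp(n, 0.02), 2),
    event = rbinom(n, 1, 0.7),
    er_status = sample(c("positive", "negative"), n, replace = TRUE),
    stringsAsFactors = FALSE)
}
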