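#' Pipeline configuration
#'
#' One object holding every stage's parameters and the fixed analysis
#' constants: up-to-5 representative genes, k = 5 city-block KNN with 10
#' outer and 10 inner stratified folds, adjusted-p selection threshold
#' 1e-5, survival significance threshold 0.05. Exactly one input mode must
#' be used: simulation (default) or expression/annotation/network paths.
#'
#' @param simulation a [simulation_config()], or `NULL` when reading files.
#' @param expression_path,annotation_path,network_path input files (file
#'   mode).
#' @param min_confidence STRING score cutoff in file mode (default 700).
#' @param partition a [partition_config()].
#' @param jaccard_threshold overlap merge threshold (default 0.5).
#' @param statistic `"iqr_welch"` (default) or `"welch"`.
#' @param alpha adjusted-p selection threshold (default 1e-5).
#' @param gene_scope activity gene scope (default `"all_genes"`).
#' @param knn a [knn_config()].
#' @param quantile_cut risk-group split quantile (default median).
#' @param survival_alpha log-rank significance threshold (default 0.05).
#' @param seed global seed; stages derive child seeds from it via
#'   [derive_seed()].
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(simulation = simulation_config(),
                            expression_path = NULL, annotation_path = NULL,
                            network_path = NULL, min_confidence = 700,
                            partition = partition_config(),
                            jaccard_threshold = 0.5,
                            statistic = c("iqr_welch", "welch"),
                            alpha = 1e-5,
                            gene_scope = c("all_genes", "representatives"),
                            knn = knn_config(),
                            quantile_cut = 0.5, survival_alpha = 0.05,
                            seed = 1L) {
  file_mode <- !is.null(expression_path)
  if (file_mode && !is.null(simulation))
    simulation <- NULL
  if (!file_mode && is.null(simulation))
    snm_error("snm_invalid_config",
              "provide either a simulation config or input paths")
  if (alpha <= 0 || alpha >= 1)
    snm_error("snm_invalid_config", "alpha must lie in (0, 1)")
  structure(list(simulation = simulation,
                 expression_path = expression_path,
                 annotation_path = annotation_path,
                 network_path = network_path,
                 min_confidence = min_confidence,
                 partition = partition,
                 jaccard_threshold = jaccard_threshold,
                 statistic = match.arg(statistic),
                 alpha = alpha,
                 gene_scope = match.arg(gene_scope),
                 knn = knn,
                 quantile_cut = quantile_cut,
                 survival_alpha = survival_alpha,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

# rediscovers subnetworks on a training subset of samples and returns
# activity features for train and test; used by nested CV so that gene
# selection and directions never see the held-out fold
fold_feature_builder <- function(dataset, candidates, network, config) {
  function(train_idx, test_idx) {
    train <- subset_samples(dataset, train_idx)
    test <- subset_samples(dataset, test_idx)
    scored <- discover_subnetworks(
      train, candidates, network,
      jaccard_threshold = config$jaccard_threshold,
      statistic = config$statistic)
    act_train <- activity_matrix(scored, train, config$gene_scope)
    rec <- significance_records(act_train, train$class_labels, config$alpha)
    sel <- rec$subnetwork_id[rec$selected]
    if (!length(sel)) {
      sel <- vapply(scored[seq_len(min(4L, length(scored)))], `[[`,
                    character(1), "id")
    }
    act_test <- activity_matrix(scored, test, config$gene_scope)
    list(train = t(act_train[sel, , drop = FALSE]),
         test = t(act_test[sel, , drop = FALSE]))
  }
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
}

km_to_list <- function(km) {
  list(event_times = km$event_times, survival_prob = km$survival_prob,
       at_risk = km$at_risk, n_events = km$n_events, n = km$n)
}

#' Run the end-to-end subnetwork-biomarker pipeline
#'
#' Executes simulate/read, gene-universe restriction, partitioning,
#' discovery, activity scoring, significance testing, nested-CV
#' classification, PCA projection and survival stratification, writing
#' every intermediate plus a manifest with input hashes. Rerunning with
#' the same config and seed reproduces byte-identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory (created if needed).
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config, outdir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  inputs <- list()

  if (!is.null(config$simulation)) {
    sim_cfg <- config$simulation
    sim_cfg$seed <- derive_seed(config$seed, "simulate")
    study <- run_stage("simulate", simulate_study(sim_cfg))
    dataset <- study$dataset
    network <- study$network
    expr_path <- file.path(outdir, "expression.tsv")
    ann_path <- file.path(outdir, "annotation.tsv")
    net_path <- file.path(outdir, "network.tsv")
    run_stage("simulate", {
      write_expression(dataset, expr_path, ann_path)
      el <- igraph::as_edgelist(network, names = TRUE)
      writeLines(c("protein1\tprotein2\tcombined_score",
                   sprintf("%s\t%s\t%s", el[, 1L], el[, 2L],
                           snm_num(igraph::E(network)$confidence))),
                 net_path)
      write_report(list(
        planted_gene_sets = study$truth$planted_gene_sets,
        directions = as.list(study$truth$directions %||% list()),
        composite_activity = as.list(study$truth$composite_activity %||% list())),
        file.path(outdir, "truth.json"))
    })
    inputs <- list(expression = expr_path, annotation = ann_path,
                   network = net_path)
  } else {
    dataset <- run_stage("read", read_expression(
      config$expression_path, config$annotation_path))
    network <- run_stage("read", read_network(
      config$network_path, config$min_confidence))
    inputs <- list(expression = config$expression_path,
                   annotation = config$annotation_path,
                   network = config$network_path)
  }

  both <- run_stage("restrict", restrict_to_common_genes(dataset, network))
  dataset <- both$dataset; network <- both$network

  candidates <- run_stage("partition",
                          partition_network(network, config$partition))
  mem <- membership_table(candidates)
  mem_path <- file.path(outdir, "membership.tsv")
  writeLines(c("subnetwork_id\tgene_id",
               sprintf("%s\t%s", mem$subnetwork_id, mem$gene_id)), mem_path)

  scored <- run_stage("discover", discover_subnetworks(
    dataset, candidates, network,
    jaccard_threshold = config$jaccard_threshold,
    statistic = config$statistic))
  disc_path <- file.path(outdir, "discovery.json")
  write_report(lapply(scored, function(s) list(
    rank = s$rank, id = s$id, genes = s$genes,
    representatives = s$representatives,
    entropy = s$entropy, conductance = s$conductance,
    degenerate = s$degenerate)), disc_path)

  activity <- run_stage("score", activity_matrix(scored, dataset,
                                                 config$gene_scope))
  act_path <- file.path(outdir, "activity.tsv")
  write_report(activity, act_path)

  records <- run_stage("score", significance_records(
    activity, dataset$class_labels, config$alpha))
  sig_path <- file.path(outdir, "significance.json")
  write_report(list(alpha = config$alpha, records = records), sig_path)

  selected <- records$subnetwork_id[records$selected]
  fallback <- !length(selected)
  if (fallback)
    selected <- vapply(scored[seq_len(min(4L, length(scored)))], `[[`,
                       character(1), "id")

  knn_cfg <- config$knn
  knn_cfg$seed <- derive_seed(config$seed, "classify")
  report <- run_stage("classify", nested_cv(
    labels = unname(dataset$class_labels),
    feature_fun = fold_feature_builder(dataset, candidates, network, config),
    config = knn_cfg,
    sample_ids = colnames(dataset$values)))
  cls_path <- file.path(outdir, "classification.json")
  write_report(list(
    accuracy = report$accuracy, sensitivity = report$sensitivity,
    specificity = report$specificity, auc = report$auc,
    confusion = report$confusion, positive_class = report$positive_class,
    selected_subnetworks = selected, selection_fallback = fallback,
    per_fold = report$per_fold, predictions = report$predictions), cls_path)

  pca <- run_stage("classify", pca_project(
    t(activity[selected, , drop = FALSE]),
    n_components = min(2L, length(selected))))
  pca_path <- file.path(outdir, "pca.tsv")
  pc_names <- colnames(pca$coordinates)
  writeLines(c(
    paste(c("sample_id", "class", pc_names), collapse = "\t"),
    vapply(seq_len(nrow(pca$coordinates)), function(i) {
      paste(c(colnames(dataset$values)[i],
              unname(dataset$class_labels[i]),
              snm_num(pca$coordinates[i, ])), collapse = "\t")
    }, character(1))), pca_path)

  surv_path <- file.path(outdir, "survival.json")
  if (!is.null(dataset$clinical) &&
      "survival_time" %in% names(dataset$clinical)) {
    orientation <- stats::setNames(records$welch_t, records$subnetwork_id)
    comp <- run_stage("survive", composite_score(activity, selected,
                                                 orientation))
    surv <- run_stage("survive", stratified_analysis(
      dataset$clinical, comp, strata = c("all", "er"),
      alpha = config$survival_alpha, quantile_cut = config$quantile_cut))
    write_report(lapply(unclass(surv), function(s) {
      s$km_high <- km_to_list(s$km_high)
      s$km_low <- km_to_list(s$km_low)
      s
    }), surv_path)
  } else {
    write_report(list(skipped = "no clinical data"), surv_path)
  }

  artifacts <- c(membership = mem_path, discovery = disc_path,
                 activity = act_path, significance = sig_path,
                 classification = cls_path, pca = pca_path,
                 survival = surv_path)
  manifest <- list(
    seed = config$seed,
    input_hashes = lapply(inputs, function(p) unname(tools::md5sum(p))),
    artifacts = lapply(as.list(artifacts), basename),
    artifact_hashes = lapply(as.list(artifacts),
                             function(p) unname(tools::md5sum(p))),
    config = list(
      mode = if (is.null(config$simulation)) "files" else "simulation",
      statistic = config$statistic, alpha = config$alpha,
      gene_scope = config$gene_scope,
      jaccard_threshold = config$jaccard_threshold,
      partition = unclass(config$partition),
      knn = unclass(knn_cfg),
      quantile_cut = config$quantile_cut,
      survival_alpha = config$survival_alpha,
      simulation = if (is.null(config$simulation)) NULL else
        unclass(config$simulation)))
  write_report(manifest, file.path(outdir, "manifest.json"))
  invisible(manifest)
}
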