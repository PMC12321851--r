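# End-to-end per-subtype workflow: simulate (or load) -> match -> filter ->
# co-abundance networks -> CAG clustering -> differential abundance ->
# pathway association -> random-forest screening with Shapley attribution.
# Every run writes a manifest echoing all parameters and interpretation
# switches so outputs are reproducible from the manifest alone.

#' Build a run configuration
#'
#' Either `simulate` (a [sim_config()]) or `paths` (named list with at least
#' `genus` and `metadata`; optionally `pathways` and `category_map`) must be
#' given. Thresholds and protocol parameters default to the study protocol:
#' genus filter 20% prevalence / 0.05% mean abundance, co-abundance edge rule
#' q < 0.05 and rho > 0.4 (positive only), k = 8 CAGs with size bounds 2-10,
#' genus-pathway edge rule |rho| > 0.2, random forest with 500 trees on a
#' stratified 70/30 split with 10-fold cross-validation, and Shapley
#' attribution of 100 test samples with 50 Monte-Carlo permutations each.
#'
#' @param simulate optional [sim_config()].
#' @param paths optional named list of input file paths.
#' @param match_algorithm `"optimal"` or `"greedy"`.
#' @param match_covariates optional character vector of matching covariates.
#' @param genus_min_prevalence,genus_min_mean_abundance genus filter.
#' @param network_threshold,network_positive_only,network_q_max co-abundance
#'   edge rule.
#' @param k number of CAGs.
#' @param cag_size_bounds reported per-CAG size range.
#' @param pathway_threshold genus-pathway edge rule on `|rho|`.
#' @param n_trees,train_fraction,cv_folds random-forest protocol.
#' @param shap_n_explained,shap_mc_samples Shapley protocol.
#' @param stages character vector of stages to run; subset of
#'   `c("match", "cags", "classify", "pathways")`.
#' @param seed global seed feeding per-stage substreams.
#' @return object of class `run_config` (a list).
#' @export
run_config <- function(simulate = NULL, paths = NULL,
                       match_algorithm = "optimal",
                       match_covariates = NULL,
                       genus_min_prevalence = 0.20,
                       genus_min_mean_abundance = 0.0005,
                       network_threshold = 0.4,
                       network_positive_only = TRUE,
                       network_q_max = 0.05,
                       k = 8, cag_size_bounds = c(2, 10),
                       pathway_threshold = 0.2,
                       n_trees = 500, train_fraction = 0.7, cv_folds = 10,
                       shap_n_explained = 100, shap_mc_samples = 50,
                       stages = c("match", "cags", "classify", "pathways"),
                       seed = 1L) {
  if (is.null(simulate) && is.null(paths)) {
    stop("either 'simulate' or 'paths' must be provided")
  }
  if (!is.null(simulate)) stopifnot(inherits(simulate, "sim_config"))
  stopifnot(network_threshold > 0, pathway_threshold > 0, k >= 1)
  structure(as.list(environment()), class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Reads a YAML file whose keys mirror the [run_config()] arguments; a
#' `simulate:` block is passed to [sim_config()].
#'
#' @param path YAML file path.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$simulate)) {
    y$simulate <- do.call(sim_config, y$simulate)
  }
  do.call(run_config, y)
}

#' Run the full matched-cohort CAG workflow
#'
#' Executes, in order: input simulation or loading; one-to-one cohort
#' matching on standardized covariates with a balance report; genus
#' filtering; per-group co-abundance networks; Ward clustering of the pooled
#' Spearman matrix into CAGs; per-CAG Wilcoxon contrasts; random-forest
#' screening of CAG-summed abundances with Gini importance, ROC/AUC and
#' Monte-Carlo Shapley attribution; and genus-pathway association with
#' per-(CAG, category) contrasts and focal-group paired tests. When no
#' pathway table is available the pathway stages are skipped and noted in
#' the manifest. Any stage error aborts with the stage name; files already
#' written are preserved.
#'
#' @param config a [run_config()] (or path to a YAML file).
#' @param outdir output directory; NULL runs fully in memory.
#' @return invisibly, a result bundle (list) with elements per stage plus
#'   `manifest`.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  if (!is.null(outdir)) dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  emit <- function(df, name) {
    if (!is.null(outdir)) write_report(df, file.path(outdir, name))
  }
  stage <- "input"
  res <- list()
  tryCatch({
    if (!is.null(config$simulate)) {
      sim <- simulate_study(config$simulate)
      abundance <- sim$abundance
      metadata <- sim$metadata
      pathways <- sim$pathways
      category_map <- sim$category_map
      focal_groups <- sim$focal_groups
      res$truth <- sim$truth
      if (!is.null(outdir)) write_simulation(sim, file.path(outdir, "inputs"))
    } else {
      abundance <- read_abundance(config$paths$genus)
      metadata <- read_metadata(config$paths$metadata)
      pathways <- if (!is.null(config$paths$pathways)) {
        read_abundance(config$paths$pathways)
      }
      category_map <- if (!is.null(config$paths$category_map)) {
        utils::read.delim(config$paths$category_map, sep = "\t",
                          stringsAsFactors = FALSE)
      }
      focal_groups <- if (!is.null(config$paths$focal_groups)) {
        yaml::read_yaml(config$paths$focal_groups)
      }
    }
    if (!"group" %in% names(metadata)) stop("metadata needs a 'group' column")
    group <- stats::setNames(metadata$group, metadata$sample_id)[rownames(abundance)]
    is_case <- group == "case"
    res$abundance <- abundance
    res$metadata <- metadata

    if ("match" %in% config$stages) {
      stage <- "match"
      cm <- standardize_covariates(metadata, covariates = config$match_covariates)
      z <- cm$values
      case_ids <- intersect(rownames(z), rownames(abundance)[is_case])
      ctrl_ids <- intersect(rownames(z), rownames(abundance)[!is_case])
      dmat <- pairwise_distances(z[case_ids, , drop = FALSE],
                                 z[ctrl_ids, , drop = FALSE])
      set.seed(substream_seed(config$seed, "match"))
      cohort <- match_cohort(dmat, algorithm = config$match_algorithm)
      balance <- balance_report(cohort, metadata, covariates = config$match_covariates,
                                subtype_col = "subtype")
      res$cohort <- cohort
      res$balance <- balance
      emit(cohort$pairs, "pairs.tsv")
      emit(balance$paired, "balance.tsv")
      # downstream stages analyze the matched cohort only: surplus controls
      # (and any unmatched cases) are set aside after matching
      keep <- c(cohort$pairs$case_id, cohort$pairs$control_id)
      abundance <- abundance[keep, , drop = FALSE]
      if (!is.null(pathways)) pathways <- pathways[keep, , drop = FALSE]
      group <- group[keep]
      is_case <- group == "case"
    }

    stage <- "filter"
    filtered <- filter_genera(abundance,
                              min_prevalence = config$genus_min_prevalence,
                              min_mean_abundance = config$genus_min_mean_abundance)
    res$filtered <- filtered

    if ("cags" %in% config$stages) {
      stage <- "networks"
      net_case <- build_network(filtered[is_case, , drop = FALSE],
                                threshold = config$network_threshold,
                                positive_only = config$network_positive_only,
                                q_max = config$network_q_max, group = "case")
      net_control <- build_network(filtered[!is_case, , drop = FALSE],
                                   threshold = config$network_threshold,
                                   positive_only = config$network_positive_only,
                                   q_max = config$network_q_max,
                                   group = "control")
      res$net_case <- net_case
      res$net_control <- net_control

      stage <- "cags"
      pooled <- spearman_matrix(filtered)
      partition <- cluster_cags(pooled$rho, k = config$k,
                                size_bounds = config$cag_size_bounds)
      res$partition <- partition
      cag_mean <- cag_abundance(filtered, partition, "mean")
      res$cag_mean <- cag_mean
      stage <- "differential"
      res$cag_tests <- cag_differential(cag_mean, group)
      if (!is.null(outdir)) {
        export_network(net_case, file.path(outdir, "network_case.tsv"),
                       file.path(outdir, "network_case.graphml"), partition)
        export_network(net_control, file.path(outdir, "network_control.tsv"),
                       file.path(outdir, "network_control.graphml"), partition)
        emit(data.frame(genus = names(partition$assignment),
                        cag = sprintf("CAG%d", partition$assignment)),
             "partition.tsv")
        emit(res$cag_tests, "cag_tests.tsv")
      }
    }

    if ("classify" %in% config$stages && !is.null(res$partition)) {
      stage <- "classify"
      cag_sum <- cag_abundance(filtered, res$partition, "sum")
      rf <- rf_fit_evaluate(cag_sum, group,
                            n_trees = config$n_trees,
                            train_fraction = config$train_fraction,
                            cv_folds = config$cv_folds,
                            seed = substream_seed(config$seed, "rf"))
      res$rf <- rf
      shap <- shapley_mc(rf,
                         instances = cag_sum[rf$split$test, , drop = FALSE],
                         background = cag_sum[rf$split$train, , drop = FALSE],
                         mc_samples = config$shap_mc_samples,
                         n_explained = min(config$shap_n_explained,
                                           length(rf$split$test)),
                         seed = substream_seed(config$seed, "shap"))
      res$shap <- shap
      shap_labels <- group[match(shap$instance_ids, rownames(cag_sum))]
      res$shap_summary <- shap_group_summary(shap, shap_labels)
      if (!is.null(outdir)) {
        jsonlite::write_json(rf$metrics, file.path(outdir, "rf_metrics.json"),
                             auto_unbox = TRUE, digits = NA)
        emit(data.frame(feature = names(rf$importance),
                        mean_decrease_gini = unname(rf$importance)),
             "importance.tsv")
        emit(rf$roc, "roc.tsv")
        emit(data.frame(instance = rep(shap$instance_ids, ncol(shap$phi)),
                        feature = rep(colnames(shap$phi), each = nrow(shap$phi)),
                        phi = as.vector(shap$phi),
                        se = as.vector(shap$se)),
             "shap.tsv")
        emit(res$shap_summary, "shap_summary.tsv")
      }
    }

    pathway_skipped <- is.null(pathways)
    if ("pathways" %in% config$stages && !pathway_skipped &&
        !is.null(res$partition)) {
      stage <- "pathways"
      bp_case <- genus_pathway_network(filtered[is_case, , drop = FALSE],
                                       pathways[is_case, , drop = FALSE],
                                       threshold = config$pathway_threshold,
                                       group = "case")
      bp_control <- genus_pathway_network(filtered[!is_case, , drop = FALSE],
                                          pathways[!is_case, , drop = FALSE],
                                          threshold = config$pathway_threshold,
                                          group = "control")
      res$bp_case <- bp_case
      res$bp_control <- bp_control
      if (!is.null(category_map)) {
        res$cell_tests <- cell_tests(bp_case, bp_control, res$partition,
                                     category_map)
        emit(res$cell_tests, "cell_tests.tsv")
      }
      if (!is.null(focal_groups) && !is.null(res$cohort)) {
        res$focal_tests <- focal_pathway_paired_test(pathways, res$cohort,
                                                     focal_groups)
        emit(res$focal_tests, "focal_tests.tsv")
      }
      if (!is.null(outdir)) {
        export_network(bp_case, file.path(outdir, "bipartite_case.tsv"),
                       file.path(outdir, "bipartite_case.graphml"))
        export_network(bp_control, file.path(outdir, "bipartite_control.tsv"),
                       file.path(outdir, "bipartite_control.graphml"))
      }
    }

    stage <- "manifest"
    manifest <- list(
      package = "cagnet",
      version = as.character(utils::packageVersion("cagnet")),
      seed = config$seed,
      parameters = config[setdiff(names(config), c("simulate", "paths"))],
      simulate = if (!is.null(config$simulate)) unclass(config$simulate),
      paths = config$paths,
      interpretation = list(
        low_count_exclusion = "feature removed only when it fails both presence and read thresholds",
        network_edges = "q < q_max AND rho > threshold (positive only by default)",
        clustering_input = "pooled case+control unthresholded Spearman matrix, Ward.D2 on 1 - rho",
        cell_values = "unthresholded genus x pathway correlations within each (CAG, category) cell",
        focal_aggregation = "sum of member pathway abundances",
        shap_background = "training-set marginal sampling; 50 MC permutations per instance"
      ),
      pathway_stage_skipped = pathway_skipped,
      warnings = list(
        cag_size_violations = if (!is.null(res$partition)) res$partition$violations,
        unmatched_cases = if (!is.null(res$cohort)) res$cohort$unmatched_cases
      )
    )
    res$manifest <- manifest
    if (!is.null(outdir)) {
      jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA, null = "null")
    }
    invisible(res)
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
}
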