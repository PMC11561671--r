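#' Union of numeric- and categorical-mode hit sets
#'
#' @param nva,cva `boruta_ensemble` objects over the same feature universe
#'   (numeric-age and categorical-age analyses).
#' @return List with `genes`, `origin` (gene -> `"NVA"`/`"CVA"`/`"both"`),
#'   `n_nva`, `n_cva`, `n_union` and `overlap`
#'   (`= n_nva + n_cva - n_union`).
#' @export
union_hits <- function(nva, cva) {
  stopifnot(inherits(nva, "boruta_ensemble"), inherits(cva, "boruta_ensemble"))
  if (!identical(sort(nva$features$feature), sort(cva$features$feature))) {
    stop("the two ensembles cover different feature universes", call. = FALSE)
  }
  a <- nva$hit_set
  b <- cva$hit_set
  genes <- sort(union(a, b))
  origin <- stats::setNames(ifelse(genes %in% a & genes %in% b, "both",
                            ifelse(genes %in% a, "NVA", "CVA")), genes)
  list(genes = genes, origin = origin,
       n_nva = length(a), n_cva = length(b), n_union = length(genes),
       overlap = length(a) + length(b) - length(genes))
}

#' Pipeline configuration
#'
#' Bundles the stage parameters of the end-to-end analysis. All defaults
#' match the individual stage defaults; the sizes here are desk-scale.
#'
#' @param design a [cohort_design()].
#' @param structure a [planted_structure()]; default
#'   [default_planted_structure()] sized to the design.
#' @param n_genes gene count for the default structure.
#' @param covariates nuisance covariates to correct.
#' @param methods correction methods considered in the order search.
#' @param boruta a [boruta_config()] template for the age selection (mode is
#'   set per analysis).
#' @param run_cva also run the categorical-age analysis.
#' @param crossboruta_config optional [boruta_config()] for the network stage
#'   (defaults to `boruta` with fewer iterations).
#' @param min_module_size,power_threshold module-stage parameters.
#' @param eval_folds cross-validation folds for the accuracy report.
#' @param seed master seed.
#' @param out_dir optional output directory for stage TSV/JSON artifacts.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(design = cohort_design(),
                            structure = NULL, n_genes = 300,
                            covariates = c("organ", "strain", "sex"),
                            methods = c("combat", "zscore"),
                            boruta = boruta_config(),
                            run_cva = TRUE,
                            crossboruta_config = NULL,
                            min_module_size = 10,
                            power_threshold = 0.94,
                            eval_folds = 5,
                            seed = 1L,
                            out_dir = NULL) {
  if (is.null(structure)) structure <- default_planted_structure(n_genes)
  if (is.null(crossboruta_config)) {
    crossboruta_config <- boruta
    crossboruta_config$n_iterations <- min(boruta$n_iterations, 3L)
    crossboruta_config$mode <- "numeric"
  }
  structure(list(design = design, structure = structure, covariates = covariates,
                 methods = methods, boruta = boruta, run_cva = isTRUE(run_cva),
                 crossboruta_config = crossboruta_config,
                 min_module_size = min_module_size,
                 power_threshold = power_threshold,
                 eval_folds = eval_folds,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Stages, in order: simulate the cohort; search the covariate correction
#' order by PVCA and apply the best plan; select age-associated transcripts
#' in numeric-age (NVA) and, optionally, categorical-age (CVA) mode; take
#' the union hit set; build co-expression modules over the hits; run
#' CrossBoruta with every hit as a target; restrict the edge table to the
#' hits and compute node metrics. Returns a report whose every number is
#' recomputable from the stage outputs.
#'
#' @param config a [pipeline_config()].
#' @return Object of class `pipeline_report` (a nested list; see fields).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  design <- config$design
  design$seed <- derive_seed(config$seed, "cohort")
  cohort <- generate_cohort(design, config$structure)
  ages <- cohort$samples$age

  pvca_factors <- unique(c(config$covariates, "age"))
  pvca_raw <- suppressWarnings(pvca(cohort$expression, cohort$samples, pvca_factors))
  search <- search_order(cohort$expression, cohort$samples, config$covariates,
                         methods = config$methods)
  best_plan <- search$plans[[1]]
  corrected <- apply_plan(cohort$expression, cohort$samples, best_plan)
  pvca_corrected <- search$pvca[[1]]

  Xs <- t(corrected)  # samples x genes
  cfg_nva <- config$boruta
  cfg_nva$mode <- "numeric"
  cfg_nva$seed <- derive_seed(config$seed, "nva")
  nva <- boruta_ensemble(Xs, ages, cfg_nva)
  if (config$run_cva) {
    cfg_cva <- config$boruta
    cfg_cva$mode <- "categorical"
    cfg_cva$seed <- derive_seed(config$seed, "cva")
    cva <- boruta_ensemble(Xs, factor(ages), cfg_cva)
    hits <- union_hits(nva, cva)
  } else {
    cva <- NULL
    hits <- list(genes = nva$hit_set,
                 origin = stats::setNames(rep("NVA", length(nva$hit_set)), nva$hit_set),
                 n_nva = length(nva$hit_set), n_cva = 0L,
                 n_union = length(nva$hit_set), overlap = 0L)
  }

  eval_all <- evaluate_prediction(Xs, ages, colnames(Xs), mode = "numeric",
                                  folds = config$eval_folds,
                                  seed = derive_seed(config$seed, "eval_all"),
                                  n_trees = config$boruta$n_trees)
  eval_hits <- if (length(hits$genes) >= 1) {
    evaluate_prediction(Xs, ages, hits$genes, mode = "numeric",
                        folds = config$eval_folds,
                        seed = derive_seed(config$seed, "eval_hits"),
                        n_trees = config$boruta$n_trees)
  } else NULL

  modules <- NULL; power_scan <- NULL; splits <- list()
  if (length(hits$genes) >= max(4, config$min_module_size)) {
    Xh <- corrected[hits$genes, , drop = FALSE]
    # low candidate powers: on desk-scale hit sets a high power erases the
    # weak-but-real correlations and leaves nothing categorizable
    power_scan <- suppressWarnings(pick_power(Xh, powers = 1:6,
                                              threshold = config$power_threshold))
    modules <- detect_modules(Xh, power_scan$chosen_power,
                              min_module_size = config$min_module_size)
    for (mname in setdiff(names(modules$sizes), "grey")) {
      members <- names(modules$membership)[modules$membership == mname]
      if (length(members) >= 4) {
        splits[[mname]] <- split_antiparallel(corrected[members, , drop = FALSE], ages)
      }
    }
  }

  network <- NULL; edge_tab <- NULL
  if (length(hits$genes) >= 2) {
    cb_cfg <- config$crossboruta_config
    cb_cfg$seed <- derive_seed(config$seed, "crossboruta")
    edge_tab <- crossboruta(corrected, targets = hits$genes, config = cb_cfg)
    network <- restrict_to_hits(edge_tab, hits$genes, origin = hits$origin,
                                modules = if (!is.null(modules)) modules$membership)
  }

  report <- structure(list(
    seed = config$seed,
    n_genes = nrow(cohort$expression),
    n_samples = ncol(cohort$expression),
    pvca_raw = pvca_raw$fractions,
    pvca_corrected = pvca_corrected$fractions,
    best_plan = plan_string(best_plan),
    plans_evaluated = nrow(search$ranking),
    n_hits_nva = hits$n_nva,
    n_hits_cva = hits$n_cva,
    n_hits_union = hits$n_union,
    hit_overlap = hits$overlap,
    accuracy_all = eval_all$accuracy, kappa_all = eval_all$kappa,
    accuracy_hits = if (!is.null(eval_hits)) eval_hits$accuracy else NA_real_,
    kappa_hits = if (!is.null(eval_hits)) eval_hits$kappa else NA_real_,
    chosen_power = if (!is.null(power_scan)) power_scan$chosen_power else NA_integer_,
    n_modules = if (!is.null(modules)) length(setdiff(names(modules$sizes), "grey")) else 0L,
    n_antiparallel_modules = sum(vapply(splits, function(s) isTRUE(s$antiparallel), logical(1))),
    n_edges_total = if (!is.null(edge_tab)) nrow(edge_tab$edges) else 0L,
    n_edges_network = if (!is.null(network)) nrow(network$edges) else 0L,
    stages = list(cohort = cohort, corrected = corrected, search = search,
                  nva = nva, cva = cva, hits = hits,
                  eval_all = eval_all, eval_hits = eval_hits,
                  power_scan = power_scan, modules = modules, splits = splits,
                  edge_table = edge_tab, network = network)
  ), class = "pipeline_report")

  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("pipeline_report (seed %d): %d genes x %d samples\n", x$seed, x$n_genes, x$n_samples))
  cat(sprintf("  best plan: %s (of %d evaluated); PVCA age fraction %.4f -> %.4f\n",
              x$best_plan, x$plans_evaluated,
              x$pvca_raw[["age"]], x$pvca_corrected[["age"]]))
  cat(sprintf("  hits: NVA %d, CVA %d, union %d (overlap %d)\n",
              x$n_hits_nva, x$n_hits_cva, x$n_hits_union, x$hit_overlap))
  cat(sprintf("  age prediction accuracy: all features %.3f (kappa %.3f), hit set %.3f (kappa %.3f)\n",
              x$accuracy_all, x$kappa_all, x$accuracy_hits, x$kappa_hits))
  cat(sprintf("  modules: %d (power %s, %d antiparallel); network: %d edges among hits\n",
              x$n_modules, format(x$chosen_power), x$n_antiparallel_modules, x$n_edges_network))
  invisible(x)
}

write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  st <- report$stages
  write_cohort(st$cohort, file.path(dir, "cohort"))
  write_expression_tsv(st$corrected, file.path(dir, "corrected.tsv"))
  utils::write.table(st$nva$features, file.path(dir, "nva_features.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(st$cva)) {
    utils::write.table(st$cva$features, file.path(dir, "cva_features.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(st$edge_table)) {
    utils::write.table(st$edge_table$edges, file.path(dir, "edges.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(st$network)) {
    export_network(st$network, file.path(dir, "aging_network.graphml"), "graphml")
    utils::write.table(st$network$nodes, file.path(dir, "node_metrics.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(st$modules)) {
    utils::write.table(
      data.frame(gene = names(st$modules$membership), module = st$modules$membership),
      file.path(dir, "modules.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  }
  summary <- report[setdiff(names(report), "stages")]
  summary$pvca_raw <- as.list(summary$pvca_raw)
  summary$pvca_corrected <- as.list(summary$pvca_corrected)
  jsonlite::write_json(summary, file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
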