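# End-to-end orchestration: mutual-information filter -> binary PSO over
# the kept pool -> leave-one-out evaluation, repeated over deterministically
# derived per-run seeds to yield a best/average/worst accuracy summary.

#' Configuration of a full two-stage selection run
#'
#' @param filter A [filter_config()].
#' @param pso A [pso_config()] (its `seed` field is overridden per run).
#' @param fitness A [fitness_config()].
#' @param classifier A [classifier_config()] used for final leave-one-out
#'   evaluation (the fitness carries its own classifier config; by default
#'   they are the same).
#' @param n_runs Number of repeated PSO runs (default 5).
#' @param base_seed Base seed; run r uses child seed `base_seed + r - 1`.
#' @param verbose Log stage-by-stage gene counts and seeds via `message()`.
#' @return An object of class `RunConfig`.
#' @export
run_config <- function(filter = filter_config(), pso = pso_config(),
                       fitness = fitness_config(),
                       classifier = fitness$classifier,
                       n_runs = 5L, base_seed = 42L, verbose = FALSE) {
  n_runs <- as.integer(n_runs)
  if (n_runs < 1L) stop("n_runs must be >= 1")
  structure(list(filter = filter, pso = pso, fitness = fitness,
                 classifier = classifier, n_runs = n_runs,
                 base_seed = as.integer(base_seed),
                 verbose = isTRUE(verbose)),
            class = "RunConfig")
}

#' Run the two-stage gene selection pipeline
#'
#' Stage 1 ranks and filters genes by mutual information once. Stage 2
#' repeats the particle-swarm search `n_runs` times with child seed
#' `base_seed + run - 1`, evaluating each run's selected subset by
#' leave-one-out cross-validation. The best run (highest leave-one-out
#' accuracy; ties broken toward the smaller subset, then the earlier run)
#' supplies the reported subset, confusion matrix, metrics and ROC/PR
#' curves; all runs feed the best/average/worst accuracy summary.
#'
#' @param dataset An [expression_dataset()].
#' @param cfg A [run_config()].
#' @return List with `subset` (best run's `GeneSubset`), `report` (an
#'   [evaluation_report()]), `ranking` (the stage-1 `MIRanking`), `trace`
#'   (best run's global-best fitness trace) and `runs` (data frame with
#'   per-run seed, subset size, fitness and leave-one-out accuracy).
#' @export
run_mipsa <- function(dataset, cfg = run_config()) {
  stopifnot(inherits(dataset, "ExpressionDataset"), inherits(cfg, "RunConfig"))
  log_info <- function(...) if (cfg$verbose) message("INFO: ", ...)

  log_info("dataset: ", n_samples(dataset), " samples x ", n_genes(dataset),
           " genes")
  ranking <- rank_and_filter(dataset, cfg$filter)
  pool <- ranking$kept
  log_info("filter: kept ", length(pool$gene_ids), " of ", n_genes(dataset),
           " genes (", nrow(ranking$dropped_redundant), " dropped as redundant)")

  runs <- vector("list", cfg$n_runs)
  for (r in seq_len(cfg$n_runs)) {
    pso_cfg <- cfg$pso
    pso_cfg$seed <- cfg$base_seed + r - 1L
    log_info("run ", r, "/", cfg$n_runs, ": swarm seed ", pso_cfg$seed)
    sel <- optimize_subset(pool, dataset, pso_cfg, cfg$fitness)
    loo <- loocv_accuracy(dataset, sel$subset, cfg$classifier)
    log_info("run ", r, ": ", length(sel$subset$gene_ids), " genes, LOOCV ",
             sprintf("%.4f", loo$accuracy))
    runs[[r]] <- list(seed = pso_cfg$seed, selection = sel, loocv = loo)
  }

  acc <- vapply(runs, function(x) x$loocv$accuracy, numeric(1))
  size <- vapply(runs, function(x) length(x$selection$subset$gene_ids),
                 integer(1))
  best_run <- order(-acc, size, seq_along(runs))[1L]
  best <- runs[[best_run]]

  cv <- curves(dataset$labels, best$loocv$scores)
  report <- evaluation_report(best$loocv$confusion, cv$roc_points,
                              cv$pr_points, cv$auc_roc, acc)
  log_info("best run ", best_run, ": ", size[best_run], " genes, LOOCV ",
           sprintf("%.4f", acc[best_run]))

  list(subset = best$selection$subset, report = report, ranking = ranking,
       trace = best$selection$trace,
       runs = data.frame(run = seq_len(cfg$n_runs),
                         seed = vapply(runs, `[[`, integer(1), "seed"),
                         n_genes = size,
                         fitness = vapply(runs, function(x) x$selection$fitness,
                                          numeric(1)),
                         loocv_accuracy = acc))
}
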