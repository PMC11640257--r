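# Seeded generator of labeled expression matrices with a known planted set
# of class-informative genes, used as the ground-truth surface for testing
# the filter, the swarm search and the full pipeline.

#' Specification for a synthetic expression dataset
#'
#' Describes a Gaussian class-conditional expression matrix emulating the
#' microarray regime: few samples, many genes, two classes, a small planted
#' set of informative genes among overwhelmingly uninformative ones, plus an
#' optional block of near-duplicate genes to exercise redundancy removal.
#'
#' @param n_samples Number of samples (rows).
#' @param n_genes Number of genes (columns).
#' @param n_informative Number of planted class-informative genes
#'   (`<= n_genes`).
#' @param effect_size Between-class mean shift of informative genes, in
#'   units of `noise_sd`; 0 makes planted genes indistinguishable from
#'   noise.
#' @param class_balance Proportion of class-1 ("Cancer") samples, in (0,1).
#' @param noise_sd Within-class standard deviation of expression.
#' @param correlated_block_size Number of genes generated as noisy copies
#'   (expected correlation > 0.95) of planted informative genes;
#'   `n_informative + correlated_block_size <= n_genes`.
#' @param seed Integer seed; identical specs produce bit-identical data.
#' @return An object of class `SyntheticSpec`.
#' @export
synthetic_spec <- function(n_samples = 60L, n_genes = 200L,
                           n_informative = 10L, effect_size = 2,
                           class_balance = 0.5, noise_sd = 1,
                           correlated_block_size = 0L, seed = 1L) {
  spec <- list(n_samples = as.integer(n_samples),
               n_genes = as.integer(n_genes),
               n_informative = as.integer(n_informative),
               effect_size = as.double(effect_size),
               class_balance = as.double(class_balance),
               noise_sd = as.double(noise_sd),
               correlated_block_size = as.integer(correlated_block_size),
               seed = as.integer(seed))
  if (spec$n_samples < 2L) stop("n_samples must be >= 2")
  if (spec$n_genes < 1L) stop("n_genes must be >= 1")
  if (spec$n_informative < 1L || spec$n_informative > spec$n_genes)
    stop("n_informative must be in [1, n_genes]")
  if (spec$effect_size < 0) stop("effect_size must be >= 0")
  if (spec$class_balance <= 0 || spec$class_balance >= 1)
    stop("class_balance must be in (0, 1)")
  if (spec$noise_sd <= 0) stop("noise_sd must be > 0")
  if (spec$correlated_block_size < 0L)
    stop("correlated_block_size must be >= 0")
  if (spec$n_informative + spec$correlated_block_size > spec$n_genes)
    stop("n_informative + correlated_block_size must be <= n_genes")
  structure(spec, class = "SyntheticSpec")
}

#' Simulate a labeled expression dataset with planted informative genes
#'
#' Labels are assigned at the exact class balance (at least one sample per
#' class). Every gene has its own baseline mean; uninformative genes are
#' class-independent Gaussian noise. Each informative gene's class-1 mean is
#' shifted by `effect_size * noise_sd` (direction randomized per gene, so
#' planted genes can be either up- or down-regulated). Correlated-block
#' genes are noisy copies of informative genes (copy noise sd =
#' `0.2 * noise_sd`, expected correlation about 0.98 at effect size 2).
#' Planted and block genes are scattered to randomized column positions.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with elements `dataset` (an [expression_dataset()]),
#'   `planted` (a `GeneSubset` of the informative genes, tagged `manual`),
#'   and `block_parents` (named character vector mapping each
#'   correlated-block gene to its informative parent).
#' @examples
#' sim <- simulate_expression(synthetic_spec(n_samples = 20, n_genes = 50,
#'                                           n_informative = 5, seed = 7))
#' sim$dataset
#' sim$planted
#' @export
simulate_expression <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  n <- spec$n_samples
  p <- spec$n_genes
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)

  n1 <- max(1L, min(n - 1L, round(n * spec$class_balance)))
  labels <- integer(n)
  labels[sample.int(n, n1)] <- 1L

  gene_ids <- sprintf("G%0*d", nchar(p), seq_len(p))
  sample_ids <- sprintf("S%0*d", nchar(n), seq_len(n))

  baseline <- stats::rnorm(p, mean = 7, sd = 1)
  values <- matrix(stats::rnorm(n * p, sd = spec$noise_sd), n, p)
  values <- sweep(values, 2L, baseline, "+")

  pos <- sample.int(p, spec$n_informative + spec$correlated_block_size)
  inf_pos <- pos[seq_len(spec$n_informative)]
  blk_pos <- pos[-seq_len(spec$n_informative)]

  shift <- spec$effect_size * spec$noise_sd *
    sample(c(-1, 1), spec$n_informative, replace = TRUE)
  for (j in seq_along(inf_pos)) {
    values[labels == 1L, inf_pos[j]] <- values[labels == 1L, inf_pos[j]] + shift[j]
  }

  block_parents <- character(0)
  if (length(blk_pos)) {
    parent_pos <- inf_pos[1L + (seq_along(blk_pos) - 1L) %% length(inf_pos)]
    for (j in seq_along(blk_pos)) {
      values[, blk_pos[j]] <- values[, parent_pos[j]] +
        stats::rnorm(n, sd = 0.2 * spec$noise_sd)
    }
    block_parents <- stats::setNames(gene_ids[parent_pos], gene_ids[blk_pos])
  }

  dataset <- expression_dataset(values, sample_ids, gene_ids, labels)
  list(dataset = dataset,
       planted = gene_subset(gene_ids[sort(inf_pos)], "manual"),
       block_parents = block_parents)
}

# Save/restore the global RNG stream so simulation and search functions are
# seeded purely by their own arguments without disturbing the caller.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
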