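# Stage 1: mutual-information filter. Every gene is scored by the plug-in
# mutual information (in bits) between its discretized expression and the
# binary class label; genes are ranked, the top-k kept, and genes highly
# correlated with a better-ranked retained gene are dropped.

#' Plug-in Shannon entropy of a discrete vector, in bits
#'
#' H(Y) = -sum_j p(y_j) log2 p(y_j) over the observed value frequencies,
#' with the convention 0 * log 0 = 0.
#'
#' @param labels Non-empty vector of discrete values (any atomic type).
#' @return Entropy in bits.
#' @examples
#' entropy_bits(c(0, 1, 0, 1)) # 1 bit
#' entropy_bits(c(1, 1, 1))    # 0 bits
#' @export
entropy_bits <- function(labels) {
  if (length(labels) == 0L) stop("entropy of an empty vector is undefined")
  p <- tabulate(as.integer(factor(labels)))
  p <- p[p > 0] / length(labels)
  -sum(p * log2(p))
}

#' Conditional entropy H(Y | X) of labels given a discretized gene, in bits
#'
#' Sum over observed states x of p(x) times the entropy of the label
#' distribution within that state:
#' H(Y|X) = sum_i p(x_i) \[-sum_j p(y_j | x_i) log2 p(y_j | x_i)\].
#'
#' @param gene_bins Discrete vector (bin indices) for one gene.
#' @param labels Discrete label vector of the same length.
#' @return Conditional entropy in bits.
#' @export
conditional_entropy_bits <- function(gene_bins, labels) {
  if (length(gene_bins) != length(labels))
    stop("gene_bins and labels must have equal length")
  if (length(labels) == 0L) stop("conditional entropy of empty vectors is undefined")
  n <- length(labels)
  joint <- table(gene_bins, labels)
  px <- rowSums(joint) / n
  h <- 0
  for (i in seq_len(nrow(joint))) {
    py_x <- joint[i, ]
    py_x <- py_x[py_x > 0] / sum(joint[i, ])
    h <- h - px[i] * sum(py_x * log2(py_x))
  }
  unname(h)
}

# Equal-frequency discretization into at most n_bins bins. Break points are
# type-1 (inverse-ECDF) quantiles, so binning depends only on the order
# statistics: any strictly monotone transform of x yields identical bins.
# Heavily tied values collapse bins (duplicate breaks are merged); a
# constant vector maps to a single bin.
discretize_ef <- function(x, n_bins) {
  if (n_bins < 2L) stop("n_bins must be >= 2")
  ux <- unique(x)
  # few distinct values: each value is its own state (already discrete)
  if (length(ux) <= n_bins) return(match(x, sort(ux)))
  breaks <- unique(stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1L),
                                   type = 1, names = FALSE))
  if (length(breaks) < 2L) return(rep.int(1L, length(x)))
  cut(x, breaks = breaks, include.lowest = TRUE, labels = FALSE)
}

#' Mutual information between a continuous gene and discrete labels, in bits
#'
#' The gene is discretized by equal-frequency binning (type-1 quantile
#' breaks, so the score is invariant under strictly monotone transforms of
#' expression), then the plug-in identity I(X;Y) = H(Y) - H(Y|X) is applied.
#' The result is clamped at 0 against floating-point underflow. A constant
#' gene carries no information and returns 0.
#'
#' @param gene_values Numeric expression vector for one gene.
#' @param labels Discrete label vector of the same length.
#' @param n_bins Number of equal-frequency bins (>= 2, default 10).
#' @return Mutual information in bits, in `[0, min(H(X), H(Y))]`.
#' @export
mutual_information_bits <- function(gene_values, labels, n_bins = 10L) {
  if (length(gene_values) != length(labels))
    stop("gene_values and labels must have equal length")
  bins <- discretize_ef(gene_values, n_bins)
  mi <- entropy_bits(labels) - conditional_entropy_bits(bins, labels)
  max(mi, 0)
}

#' Configuration for the mutual-information filter
#'
#' @param k Number of top-ranked genes kept before redundancy removal
#'   (default 100).
#' @param n_bins Equal-frequency bins for discretizing expression
#'   (default 10).
#' @param redundancy_threshold Absolute Pearson correlation at or above
#'   which a gene is dropped in favor of a better-ranked retained gene,
#'   in (0, 1] (default 0.9).
#' @return An object of class `FilterConfig`.
#' @export
filter_config <- function(k = 100L, n_bins = 10L, redundancy_threshold = 0.9) {
  k <- as.integer(k); n_bins <- as.integer(n_bins)
  if (k < 1L) stop("k must be >= 1")
  if (n_bins < 2L) stop("n_bins must be >= 2")
  if (redundancy_threshold <= 0 || redundancy_threshold > 1)
    stop("redundancy_threshold must be in (0, 1]")
  structure(list(k = k, n_bins = n_bins,
                 redundancy_threshold = redundancy_threshold,
                 log_base = 2),
            class = "FilterConfig")
}

#' Rank all genes by mutual information and filter to a compact pool
#'
#' The four filter steps: (1) MI between every gene and the label;
#' (2) descending rank, ties broken lexicographically by gene ID for
#' reproducibility; (3) top-k truncation (k clamped to the gene count with
#' a warning); (4) redundancy removal — scanning the kept genes in rank
#' order, a gene whose absolute Pearson correlation with any already
#' retained gene meets the threshold is dropped and recorded with its
#' most-correlated retained partner. The pool may therefore hold fewer than
#' k genes; no backfilling.
#'
#' @param dataset An [expression_dataset()].
#' @param config A [filter_config()].
#' @return An object of class `MIRanking`: list with `scores` (named numeric,
#'   bits), `order` (gene IDs, best first), `kept` (a `GeneSubset` tagged
#'   `"filter"`), and `dropped_redundant` (data frame: dropped, retained,
#'   correlation).
#' @export
rank_and_filter <- function(dataset, config = filter_config()) {
  stopifnot(inherits(dataset, "ExpressionDataset"),
            inherits(config, "FilterConfig"))
  k <- config$k
  if (k > n_genes(dataset)) {
    warning("k = ", k, " exceeds the number of genes (", n_genes(dataset),
            "); clamping")
    k <- n_genes(dataset)
  }
  scores <- vapply(
    dataset$gene_ids,
    function(g) mutual_information_bits(dataset$values[, g], dataset$labels,
                                        config$n_bins),
    numeric(1)
  )
  # descending score, lexicographic gene ID as deterministic tie-break
  ord <- dataset$gene_ids[order(-scores, dataset$gene_ids, method = "radix")]
  top <- ord[seq_len(k)]

  retained <- character(0)
  dropped <- character(0); partner <- character(0); corr <- numeric(0)
  for (g in top) {
    if (length(retained) == 0L) {
      retained <- g
      next
    }
    r <- suppressWarnings(
      abs(stats::cor(dataset$values[, g], dataset$values[, retained])))
    r[is.na(r)] <- 0 # constant gene: correlation undefined, not redundant
    if (max(r) >= config$redundancy_threshold) {
      best <- which.max(r)
      dropped <- c(dropped, g)
      partner <- c(partner, retained[best])
      corr <- c(corr, r[best])
    } else {
      retained <- c(retained, g)
    }
  }
  structure(
    list(scores = scores, order = ord,
         kept = gene_subset(retained, "filter"),
         dropped_redundant = data.frame(dropped = dropped, retained = partner,
                                        correlation = corr,
                                        stringsAsFactors = FALSE)),
    class = "MIRanking"
  )
}

#' @export
print.MIRanking <- function(x, ...) {
  cat("MIRanking:", length(x$scores), "genes scored;",
      length(x$kept$gene_ids), "kept;",
      nrow(x$dropped_redundant), "dropped as redundant\n")
  cat("top genes:", paste(utils::head(x$order, 5), collapse = ", "), "...\n")
  invisible(x)
}

#' Write a ranking table as TSV
#'
#' Columns: gene_id, mi_bits, rank, kept, redundant_partner (empty when not
#' dropped).
#'
#' @param ranking An `MIRanking`.
#' @param path Output path.
#' @export
write_ranking <- function(ranking, path) {
  dr <- ranking$dropped_redundant
  partner <- stats::setNames(dr$retained, dr$dropped)
  df <- data.frame(
    gene_id = ranking$order,
    mi_bits = as.double(ranking$scores[ranking$order]),
    rank = seq_along(ranking$order),
    kept = ranking$order %in% ranking$kept$gene_ids,
    redundant_partner = ifelse(ranking$order %in% names(partner),
                               partner[ranking$order], ""),
    stringsAsFactors = FALSE
  )
  write_tsv_stable(df, path)
}
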