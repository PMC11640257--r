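# Reading, writing and validation of labeled expression matrices and of the
# gene-subset / report artifacts the selection pipeline produces.

#' Construct a labeled expression dataset
#'
#' Bundles a samples-by-genes expression matrix with binary class labels
#' (0 = control / "No Cancer", 1 = case / "Cancer") and validates its
#' integrity. This is the container every stage of the pipeline consumes.
#'
#' @param values Numeric matrix, rows = samples, columns = genes.
#' @param sample_ids Character vector of unique sample identifiers,
#'   length `nrow(values)`.
#' @param gene_ids Character vector of unique gene identifiers,
#'   length `ncol(values)`.
#' @param labels Integer vector of 0/1 class labels, one per sample; both
#'   classes must be present.
#' @return An object of class `ExpressionDataset`: a list with elements
#'   `values` (dimnames set to the IDs), `sample_ids`, `gene_ids`, `labels`.
#' @examples
#' x <- matrix(rnorm(12), 3, 4)
#' ds <- expression_dataset(x, c("s1", "s2", "s3"), paste0("G", 1:4), c(0L, 1L, 1L))
#' n_samples(ds)
#' @export
expression_dataset <- function(values, sample_ids, gene_ids, labels) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  sample_ids <- as.character(sample_ids)
  gene_ids <- as.character(gene_ids)
  labels <- as.integer(labels)
  if (nrow(values) != length(sample_ids))
    stop("row count of 'values' (", nrow(values), ") != number of sample IDs (",
         length(sample_ids), ")")
  if (ncol(values) != length(gene_ids))
    stop("column count of 'values' (", ncol(values), ") != number of gene IDs (",
         length(gene_ids), ")")
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ID: ", sample_ids[duplicated(sample_ids)][1L])
  if (anyDuplicated(gene_ids))
    stop("duplicate gene ID: ", gene_ids[duplicated(gene_ids)][1L])
  if (length(labels) != length(sample_ids))
    stop("length of 'labels' != number of samples")
  if (anyNA(values))
    stop("expression matrix contains missing values; impute before constructing")
  if (anyNA(labels) || !all(labels %in% c(0L, 1L)))
    stop("labels must be 0 or 1 with no missing values")
  if (length(unique(labels)) < 2L)
    stop("both classes (0 and 1) must be present in 'labels'")
  dimnames(values) <- list(sample_ids, gene_ids)
  structure(
    list(values = values, sample_ids = sample_ids, gene_ids = gene_ids,
         labels = labels),
    class = "ExpressionDataset"
  )
}

#' @rdname expression_dataset
#' @param x An `ExpressionDataset`.
#' @export
n_samples <- function(x) length(x$sample_ids)

#' @rdname expression_dataset
#' @export
n_genes <- function(x) length(x$gene_ids)

#' @export
print.ExpressionDataset <- function(x, ...) {
  cat("ExpressionDataset:", n_samples(x), "samples x", n_genes(x), "genes;",
      sum(x$labels == 1L), "positive /", sum(x$labels == 0L), "negative\n")
  invisible(x)
}

#' Construct a gene subset
#'
#' An ordered set of gene identifiers together with the stage that produced
#' it (the mutual-information filter, the particle-swarm search, or a manual
#' list).
#'
#' @param gene_ids Non-empty character vector of gene identifiers, no
#'   duplicates.
#' @param source_stage One of `"filter"`, `"pso"`, `"manual"`.
#' @return An object of class `GeneSubset`.
#' @export
gene_subset <- function(gene_ids, source_stage = c("manual", "filter", "pso")) {
  source_stage <- match.arg(source_stage)
  gene_ids <- as.character(gene_ids)
  if (length(gene_ids) == 0L) stop("a gene subset must contain at least one gene")
  if (anyDuplicated(gene_ids))
    stop("duplicate gene ID in subset: ", gene_ids[duplicated(gene_ids)][1L])
  structure(list(gene_ids = gene_ids, source_stage = source_stage),
            class = "GeneSubset")
}

#' @export
print.GeneSubset <- function(x, ...) {
  cat("GeneSubset (", x$source_stage, "): ", length(x$gene_ids), " genes\n",
      sep = "")
  invisible(x)
}

#' @export
length.GeneSubset <- function(x) length(x$gene_ids)

# Subset columns of a dataset's matrix by a GeneSubset, preserving subset
# order. Errors if any gene is absent.
subset_values <- function(dataset, subset) {
  ids <- if (inherits(subset, "GeneSubset")) subset$gene_ids else as.character(subset)
  missing <- setdiff(ids, dataset$gene_ids)
  if (length(missing))
    stop("gene(s) not present in dataset: ", paste(missing, collapse = ", "))
  dataset$values[, ids, drop = FALSE]
}

#' Load an expression dataset from delimited text files
#'
#' The matrix file must have a header row of gene identifiers and a leading
#' sample-ID column; the labels file maps every sample ID to 0 or 1. Labels
#' are aligned to the matrix by sample ID, so row order in the labels file
#' is irrelevant. The delimiter (comma or tab) is auto-detected per file.
#'
#' @param matrix_path Path to the expression matrix (CSV/TSV, samples in
#'   rows unless `transpose = TRUE`).
#' @param labels_path Path to a two-column labels file (sample_id, label).
#' @param transpose If `TRUE`, the matrix file is gene-major (genes in rows)
#'   and is transposed after reading.
#' @param impute If `TRUE`, missing expression values are replaced by the
#'   per-gene mean; by default missing values are an error.
#' @return An [expression_dataset()].
#' @export
load_dataset <- function(matrix_path, labels_path, transpose = FALSE,
                         impute = FALSE) {
  # check the raw header for duplicate IDs (readers silently rename them)
  header <- readLines(matrix_path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  header_ids <- strsplit(header, sep, fixed = TRUE)[[1L]][-1L]
  if (!transpose && anyDuplicated(header_ids))
    stop("duplicate gene ID in matrix header: ",
         header_ids[duplicated(header_ids)][1L])
  mat_dt <- data.table::fread(matrix_path, header = TRUE, data.table = FALSE,
                              check.names = FALSE)
  if (ncol(mat_dt) < 2L)
    stop("matrix file must have a sample-ID column plus at least one gene column")
  ids <- as.character(mat_dt[[1L]])
  values <- as.matrix(mat_dt[, -1L, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- ids
  if (transpose) values <- t(values)
  gene_ids <- colnames(values)
  sample_ids <- rownames(values)
  if (anyDuplicated(gene_ids))
    stop("duplicate gene ID in matrix header: ",
         gene_ids[duplicated(gene_ids)][1L])
  if (anyNA(values)) {
    if (!impute)
      stop("expression matrix contains missing values (use impute = TRUE ",
           "for per-gene mean imputation)")
    for (j in seq_len(ncol(values))) {
      nas <- is.na(values[, j])
      if (any(nas)) values[nas, j] <- mean(values[!nas, j])
    }
  }

  lab_dt <- data.table::fread(labels_path, header = TRUE, data.table = FALSE,
                              check.names = FALSE)
  if (ncol(lab_dt) < 2L)
    stop("labels file must have two columns: sample_id, label")
  lab_map <- lab_dt[[2L]]
  names(lab_map) <- as.character(lab_dt[[1L]])
  missing <- setdiff(sample_ids, names(lab_map))
  if (length(missing))
    stop("sample(s) missing from labels file: ", paste(missing, collapse = ", "))
  labels <- lab_map[sample_ids]
  if (!all(labels %in% c(0, 1)))
    stop("non-binary label value(s): ",
         paste(unique(labels[!labels %in% c(0, 1)]), collapse = ", "))
  expression_dataset(values, sample_ids, gene_ids, as.integer(labels))
}

#' Write an expression dataset to delimited text files
#'
#' Inverse of [load_dataset()]: values round-trip exactly through the
#' `%.17g` float format and ID ordering is preserved.
#'
#' @param dataset An `ExpressionDataset`.
#' @param matrix_path,labels_path Output paths.
#' @param sep Field delimiter (default comma).
#' @export
write_dataset <- function(dataset, matrix_path, labels_path, sep = ",") {
  con <- file(matrix_path, "wb")
  on.exit(close(con), add = TRUE)
  writeLines(paste(c("sample_id", dataset$gene_ids), collapse = sep), con)
  for (i in seq_len(n_samples(dataset))) {
    writeLines(paste(c(dataset$sample_ids[i],
                       sprintf("%.17g", dataset$values[i, ])), collapse = sep),
               con)
  }
  con2 <- file(labels_path, "wb")
  on.exit(close(con2), add = TRUE)
  writeLines(c(paste("sample_id", "label", sep = sep),
               paste(dataset$sample_ids, dataset$labels, sep = sep)), con2)
  invisible(c(matrix_path, labels_path))
}

#' Read / write a gene-subset list (one gene ID per line)
#'
#' @param path File path.
#' @param source_stage Stage tag recorded on the loaded subset.
#' @return `read_gene_subset()` returns a [gene_subset()];
#'   `write_gene_subset()` returns the path invisibly.
#' @export
read_gene_subset <- function(path, source_stage = "manual") {
  ids <- readLines(path)
  ids <- ids[nzchar(ids)]
  gene_subset(ids, source_stage)
}

#' @rdname read_gene_subset
#' @param subset A `GeneSubset`.
#' @export
write_gene_subset <- function(subset, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(subset$gene_ids, con)
  invisible(path)
}

# Number formatter used for all report files: stable, locale-independent,
# round-trip exact for doubles.
fmt_num <- function(x) sprintf("%.17g", x)

write_tsv_stable <- function(df, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  cols <- lapply(df, function(col) {
    if (is.double(col)) fmt_num(col) else as.character(col)
  })
  writeLines(c(paste(names(df), collapse = "\t"),
               do.call(paste, c(cols, sep = "\t"))), con)
  invisible(path)
}

#' Write an evaluation report to a directory
#'
#' Emits the selected-gene list (`genes.txt`, one ID per line), scalar
#' metrics (`metrics.tsv`, key/value), ROC and PR point sets (`roc.tsv`,
#' `pr.tsv`) and the per-run accuracy table (`runs.tsv`). Output is
#' byte-stable: identical inputs yield byte-identical files.
#'
#' @param report An `EvaluationReport` (see [evaluation_report()]).
#' @param subset The selected `GeneSubset`.
#' @param out_dir Output directory, created if absent.
#' @return Invisibly, the named character vector of files written.
#' @export
write_report <- function(report, subset, out_dir) {
  stopifnot(inherits(report, "EvaluationReport"), inherits(subset, "GeneSubset"))
  if (nrow(report$roc_points) == 0L)
    stop("report has an empty ROC point set; refusing to write an empty curve")
  if (nrow(report$pr_points) == 0L)
    stop("report has an empty PR point set; refusing to write an empty curve")
  if (!dir.exists(out_dir))
    if (!dir.create(out_dir, recursive = TRUE))
      stop("cannot create output directory: ", out_dir)

  paths <- c(genes = file.path(out_dir, "genes.txt"),
             metrics = file.path(out_dir, "metrics.tsv"),
             roc = file.path(out_dir, "roc.tsv"),
             pr = file.path(out_dir, "pr.tsv"),
             runs = file.path(out_dir, "runs.tsv"))
  write_gene_subset(subset, paths[["genes"]])

  cm <- report$confusion
  metrics <- data.frame(
    key = c("n_genes", "tp", "tn", "fp", "fn", "accuracy", "precision",
            "recall", "f_score", "auc_roc", "best", "average", "worst"),
    value = c(length(subset$gene_ids), cm$tp, cm$tn, cm$fp, cm$fn,
              fmt_num(c(report$accuracy, report$precision, report$recall,
                        report$f_score, report$auc_roc, report$best,
                        report$average, report$worst))),
    stringsAsFactors = FALSE
  )
  write_tsv_stable(metrics, paths[["metrics"]])
  write_tsv_stable(report$roc_points, paths[["roc"]])
  write_tsv_stable(report$pr_points, paths[["pr"]])
  write_tsv_stable(
    data.frame(run = seq_along(report$per_run_accuracies),
               accuracy = as.double(report$per_run_accuracies)),
    paths[["runs"]])
  invisible(paths)
}
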