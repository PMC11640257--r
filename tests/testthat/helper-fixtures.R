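# Shared fixtures built in code.

# Small dataset with two well-separated Gaussian classes on every gene.
separable_dataset <- function(n = 20L, p = 4L, gap = 6, seed = 1L) {
  set.seed(seed)
  labels <- rep(c(0L, 1L), length.out = n)
  values <- matrix(rnorm(n * p), n, p) + gap * labels
  expression_dataset(values, paste0("s", seq_len(n)), paste0("G", seq_len(p)),
                     labels)
}

# Independent brute-force plug-in MI over the joint contingency table,
# Sum p(x,y) log2[ p(x,y) / (p(x) p(y)) ] -- the oracle the identity-based
# implementation is checked against.
brute_force_mi <- function(x_disc, y) {
  n <- length(y)
  xs <- unique(x_disc); ys <- unique(y)
  mi <- 0
  for (a in xs) for (b in ys) {
    pxy <- sum(x_disc == a & y == b) / n
    if (pxy > 0) {
      px <- sum(x_disc == a) / n
      py <- sum(y == b) / n
      mi <- mi + pxy * log2(pxy / (px * py))
    }
  }
  mi
}

# Brute-force pairwise-concordance AUC (Mann-Whitney statistic with ties
# counted one half).
concordance_auc <- function(labels, scores) {
  pos <- scores[labels == 1L]
  neg <- scores[labels == 0L]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# Write a dataset's matrix/labels to temp files; returns the two paths.
write_temp_dataset <- function(dataset, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  m <- file.path(dir, "matrix.csv")
  l <- file.path(dir, "labels.csv")
  write_dataset(dataset, m, l)
  c(matrix = m, labels = l)
}
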