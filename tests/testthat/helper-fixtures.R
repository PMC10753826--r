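# Shared fixture builders and independent oracles.

# Build a rel_abundance table from a plain matrix, normalising columns.
make_rel <- function(m, taxa = NULL, samples = NULL) {
  if (is.null(taxa)) taxa <- paste0("t", seq_len(nrow(m)))
  if (is.null(samples)) samples <- paste0("s", seq_len(ncol(m)))
  dimnames(m) <- list(taxa, samples)
  m <- sweep(m, 2, colSums(m), "/")
  rel_abundance(m)
}

# Random relative-abundance table (Dirichlet(1) columns).
random_rel_table <- function(n_taxa, n_samples) {
  m <- matrix(rgamma(n_taxa * n_samples, shape = 1), n_taxa, n_samples)
  # sprinkle structural zeros so detection thresholds bite
  m[runif(length(m)) < 0.3] <- 0
  zero_cols <- colSums(m) == 0
  m[1, zero_cols] <- 1
  make_rel(m)
}

# Brute-force core-membership oracle: explicit loops over taxa and samples,
# independent of the vectorised implementation.
brute_core_members <- function(rel, p, d) {
  members <- character(0)
  for (i in seq_len(nrow(rel))) {
    n_present <- 0L
    for (j in seq_len(ncol(rel)))
      if (rel[i, j] > d) n_present <- n_present + 1L
    if (n_present / ncol(rel) >= p)
      members <- c(members, rownames(rel)[i])
  }
  members
}

# Small ASV-count fixture with named features/samples.
make_counts <- function(m, features = NULL, samples = NULL) {
  if (is.null(features)) features <- paste0("ASV", seq_len(nrow(m)))
  if (is.null(samples)) samples <- paste0("s", seq_len(ncol(m)))
  dimnames(m) <- list(features, samples)
  asv_table(m)
}

# Adjusted Rand index between two labelings (contingency-table formula).
ari <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  s <- function(x) sum(choose(x, 2))
  n <- length(a)
  exp_idx <- s(rowSums(tab)) * s(colSums(tab)) / choose(n, 2)
  max_idx <- (s(rowSums(tab)) + s(colSums(tab))) / 2
  (s(tab) - exp_idx) / (max_idx - exp_idx)
}

# Cluster labels (integer per gene) from a gene_cluster_set, in gene order.
cluster_labels <- function(clusters, genes) {
  cl <- if (inherits(clusters, "gene_cluster_set")) clusters$clusters
        else clusters
  lab <- setNames(rep(names(cl), lengths(cl)), unlist(cl))
  as.integer(factor(lab[genes]))
}
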