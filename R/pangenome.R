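#' minbit similarity normalisation
#'
#' Normalises a pairwise protein alignment bitscore by the smaller of the two
#' self-alignment bitscores: `minbit = score_ab / min(score_aa, score_bb)`.
#' Values near 1 indicate that the alignment covers (nearly) the whole of the
#' shorter protein at full score; weak partial hits score low and are
#' filtered before gene clustering.
#'
#' @param score_ab pairwise bitscore(s), >= 0 (vectorised).
#' @param score_aa,score_bb self-alignment bitscores, > 0.
#' @return numeric minbit value(s).
#' @export
minbit <- function(score_ab, score_aa, score_bb) {
  if (any(score_aa <= 0) || any(score_bb <= 0))
    stop("self-scores must be positive")
  if (any(score_ab < 0)) stop("bitscores must be non-negative")
  score_ab / pmin(score_aa, score_bb)
}

#' Read a pairwise bitscore table from TSV
#'
#' Three columns: `gene_a`, `gene_b`, `bits` (self-pairs included). A header
#' row is accepted. Returns a `bitscore_table`: data.frame plus the
#' extracted named vector of self-scores.
#'
#' @param path file path.
#' @return object of class `bitscore_table`.
#' @export
read_bitscores <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) < 3) stop("bitscore table needs 3 columns: gene_a gene_b bits")
  if (is.na(suppressWarnings(as.numeric(df[1, 3])))) df <- df[-1, ]
  bitscore_table(data.frame(gene_a = as.character(df[[1]]),
                            gene_b = as.character(df[[2]]),
                            bits = as.numeric(df[[3]]),
                            stringsAsFactors = FALSE))
}

#' Construct a bitscore table
#'
#' @param df data.frame with columns `gene_a`, `gene_b`, `bits`; must include
#'   a self-pair for every gene that appears.
#' @return object of class `bitscore_table` (the data.frame, with a
#'   `self_scores` attribute).
#' @export
bitscore_table <- function(df) {
  stopifnot(all(c("gene_a", "gene_b", "bits") %in% names(df)))
  if (any(df$bits < 0)) stop("bitscores must be non-negative")
  genes <- unique(c(df$gene_a, df$gene_b))
  is_self <- df$gene_a == df$gene_b
  self <- tapply(df$bits[is_self], df$gene_a[is_self], max)
  missing <- setdiff(genes, names(self))
  if (length(missing))
    stop("missing self-score for gene: ", missing[1])
  if (any(self <= 0))
    stop("non-positive self-score for gene: ", names(self)[self <= 0][1])
  structure(df, self_scores = self[genes], genes = genes,
            class = c("bitscore_table", "data.frame"))
}

#' Read a gene-to-genome map from TSV
#'
#' Two columns: `gene_id`, `genome_id` (header optional).
#' @param path file path.
#' @return named character vector, gene id -> genome id.
#' @export
read_genome_map <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  if (tolower(df[1, 1]) %in% c("gene_id", "gene")) df <- df[-1, ]
  stats::setNames(as.character(df[[2]]), as.character(df[[1]]))
}

#' Build a minbit-filtered protein similarity graph
#'
#' Computes minbit for every non-self pair and keeps edges whose minbit is at
#' least `threshold` (default 0.5). When both orientations of a pair are
#' present the larger bitscore is used.
#'
#' @param bitscores a [bitscore_table()].
#' @param threshold minimum minbit to keep an edge (default 0.5).
#' @return object of class `similarity_graph`: list with `genes` and
#'   `adjacency` (symmetric weight matrix of minbit values; no self-edges).
#' @export
build_similarity_graph <- function(bitscores, threshold = 0.5) {
  stopifnot(inherits(bitscores, "bitscore_table"))
  genes <- attr(bitscores, "genes")
  self <- attr(bitscores, "self_scores")
  n <- length(genes)
  adj <- matrix(0, n, n, dimnames = list(genes, genes))
  pairs <- bitscores[bitscores$gene_a != bitscores$gene_b, , drop = FALSE]
  if (nrow(pairs)) {
    ia <- match(pairs$gene_a, genes)
    ib <- match(pairs$gene_b, genes)
    # larger bitscore wins when both orientations are reported
    score <- matrix(0, n, n)
    idx <- cbind(ia, ib)
    keep_larger <- pairs$bits > score[idx]
    score[idx[keep_larger, , drop = FALSE]] <- pairs$bits[keep_larger]
    idx_r <- cbind(ib, ia)
    keep_larger <- pairs$bits > score[idx_r]
    score[idx_r[keep_larger, , drop = FALSE]] <- pairs$bits[keep_larger]
    score <- pmax(score, t(score))
    mb <- score / outer(self, self, pmin)
    adj[mb >= threshold] <- mb[mb >= threshold]
    diag(adj) <- 0
  }
  structure(list(genes = genes, adjacency = adj, threshold = threshold),
            class = "similarity_graph")
}

#' Markov clustering (MCL) of a similarity graph
#'
#' Partitions the graph by the Markov Cluster algorithm: starting from the
#' column-stochastic transition matrix of the weighted graph (self-loops
#' added with weight equal to each node's maximum incident edge weight, so
#' isolated regions remain stochastic), alternate expansion (matrix power)
#' and inflation (entrywise power followed by column renormalisation),
#' pruning entries below `pruning`, until the matrix change falls below
#' `tol` or `max_iter` is reached. Clusters are the connected components of
#' the non-zero support of the limit matrix; singletons are allowed.
#'
#' @param graph a `similarity_graph` (or symmetric weight matrix).
#' @param inflation inflation exponent (default 2).
#' @param expansion expansion power (default 2).
#' @param max_iter iteration cap (default 100).
#' @param tol convergence tolerance on the max entry change (default 1e-6).
#' @param pruning entries below this are zeroed each iteration.
#' @return object of class `gene_cluster_set`: list with `clusters`
#'   (named list cluster id -> character vector of genes), `converged`,
#'   `n_iterations`, and parameters.
#' @export
mcl_cluster <- function(graph, inflation = 2, expansion = 2,
                        max_iter = 100, tol = 1e-6, pruning = 1e-8) {
  adj <- if (inherits(graph, "similarity_graph")) graph$adjacency
         else as.matrix(graph)
  if (nrow(adj) != ncol(adj) || max(abs(adj - t(adj))) > 1e-8)
    stop("similarity graph adjacency must be symmetric")
  genes <- rownames(adj)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(adj)))
  n <- nrow(adj)
  if (n == 0) stop("empty graph")
  stopifnot(inflation > 0, expansion >= 1)
  loop <- apply(adj, 1, max)
  loop[loop == 0] <- 1  # isolated nodes keep a unit self-loop
  m <- adj
  diag(m) <- loop
  normalize <- function(x) sweep(x, 2, colSums(x), "/")
  m <- normalize(m)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    m_prev <- m
    m_exp <- m
    for (e in seq_len(expansion - 1)) m_exp <- m_exp %*% m
    m_new <- m_exp^inflation
    m_new[m_new < pruning] <- 0
    m <- normalize(m_new)
    if (max(abs(m - m_prev)) < tol) { converged <- TRUE; break }
  }
  support <- (m > 0) | (t(m) > 0)
  comp <- igraph::components(igraph::graph_from_adjacency_matrix(
    support, mode = "undirected", diag = FALSE))
  clusters <- split(genes, comp$membership)
  # stable ids ordered by size then first member
  ord <- order(-lengths(clusters),
               vapply(clusters, `[`, character(1), 1))
  clusters <- clusters[ord]
  names(clusters) <- sprintf("GC_%05d", seq_along(clusters))
  structure(list(clusters = clusters, converged = converged,
                 n_iterations = it, inflation = inflation,
                 expansion = expansion),
            class = "gene_cluster_set")
}

#' @export
print.gene_cluster_set <- function(x, ...) {
  cat(sprintf("%d gene clusters over %d genes (MCL inflation %.2g, %s)\n",
              length(x$clusters), sum(lengths(x$clusters)), x$inflation,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Cluster presence/absence across genomes
#'
#' @param clusters a `gene_cluster_set` (or named list of gene vectors).
#' @param genome_map named vector, gene id -> genome id, covering all genes.
#' @return binary matrix, clusters x genomes; entry 1 iff the cluster
#'   contains at least one gene of that genome.
#' @export
presence_absence <- function(clusters, genome_map) {
  cl <- if (inherits(clusters, "gene_cluster_set")) clusters$clusters
        else clusters
  genes <- unlist(cl, use.names = FALSE)
  missing <- setdiff(genes, names(genome_map))
  if (length(missing))
    stop("genome map does not cover gene: ", missing[1])
  genomes <- sort(unique(unname(genome_map)))
  pa <- matrix(vapply(cl, function(g)
    as.integer(genomes %in% genome_map[g]), integer(length(genomes))),
    ncol = length(genomes), byrow = TRUE,
    dimnames = list(names(cl), genomes))
  pa
}

#' Partition gene clusters into core / unique / group-specific bins
#'
#' A cluster is *core* when present in every genome, *unique* to a genome
#' when present in exactly that genome, *group-core* (when a genome subset
#' is supplied) when present in all group members and absent from all
#' others, and *accessory* otherwise.
#'
#' @param clusters a `gene_cluster_set` or named list of gene vectors.
#' @param genome_map named vector, gene id -> genome id.
#' @param group optional character vector of genome ids (a strict subset).
#' @return list with `core` (cluster ids), `unique` (named list per
#'   genome), `group_core` (or `NULL`), `accessory`, and the
#'   `presence_absence` matrix.
#' @export
partition_clusters <- function(clusters, genome_map, group = NULL) {
  pa <- presence_absence(clusters, genome_map)
  genomes <- colnames(pa)
  if (!is.null(group)) {
    bad <- setdiff(group, genomes)
    if (length(bad)) stop("unknown genome in group: ", bad[1])
  }
  n_present <- rowSums(pa)
  core <- rownames(pa)[n_present == length(genomes)]
  uniq <- lapply(genomes, function(g)
    rownames(pa)[n_present == 1 & pa[, g] == 1])
  names(uniq) <- genomes
  group_core <- NULL
  if (!is.null(group) && length(group) < length(genomes)) {
    in_group <- rowSums(pa[, group, drop = FALSE]) == length(group)
    out_group <- rowSums(pa[, setdiff(genomes, group), drop = FALSE]) == 0
    group_core <- rownames(pa)[in_group & out_group]
  }
  assigned <- c(core, unlist(uniq, use.names = FALSE), group_core)
  accessory <- setdiff(rownames(pa), assigned)
  list(core = core, unique = uniq, group_core = group_core,
       accessory = accessory, presence_absence = pa)
}
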