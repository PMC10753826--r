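#' Configuration for the synthetic pangenome generator
#'
#' Plants a pangenome with known structure: `n_core_clusters` gene clusters
#' with exactly one member per genome, `n_unique_clusters_per_genome`
#' single-gene clusters per genome, and optional group-specific clusters
#' shared by a genome subset and absent elsewhere. Pairwise protein
#' bitscores are drawn from a high-scoring within-cluster distribution and
#' a low-scoring between-cluster distribution; self-scores dominate every
#' pairwise score involving the gene.
#'
#' @param n_genomes number of genomes (ids `G1`, `G2`, ...).
#' @param n_core_clusters clusters present in every genome.
#' @param n_unique_clusters_per_genome single-gene clusters per genome.
#' @param group_specific list of `list(genomes = <ids or indices>,
#'   n = <count>)` entries for clusters confined to a genome subset.
#' @param within_cluster_bitscore `c(mean, sd)` of within-cluster scores.
#' @param between_cluster_bitscore `c(mean, sd)` of cross-cluster scores;
#'   the within mean must exceed the between mean.
#' @param self_score_scale multiplier (>= 1) applied to the self-score
#'   baseline; values below 1 would allow a self-score below a pairwise
#'   score in expectation and are rejected.
#' @param seed integer seed.
#' @return validated list of class `pangenome_sim_config`.
#' @export
pangenome_sim_config <- function(
    n_genomes = 6,
    n_core_clusters = 40,
    n_unique_clusters_per_genome = 8,
    group_specific = list(list(genomes = c("G1", "G2", "G3"), n = 12)),
    within_cluster_bitscore = c(mean = 200, sd = 15),
    between_cluster_bitscore = c(mean = 30, sd = 10),
    self_score_scale = 1.1,
    seed = 1) {
  cfg <- list(n_genomes = as.integer(n_genomes),
              n_core_clusters = as.integer(n_core_clusters),
              n_unique_clusters_per_genome =
                as.integer(n_unique_clusters_per_genome),
              group_specific = group_specific,
              within_cluster_bitscore = unname(within_cluster_bitscore),
              between_cluster_bitscore = unname(between_cluster_bitscore),
              self_score_scale = self_score_scale,
              seed = as.integer(seed))
  validate_pangenome_sim_config(cfg)
  structure(cfg, class = "pangenome_sim_config")
}

validate_pangenome_sim_config <- function(cfg) {
  if (cfg$n_genomes < 1) stop("n_genomes: must be >= 1")
  if (cfg$n_core_clusters < 0) stop("n_core_clusters: must be >= 0")
  if (cfg$n_unique_clusters_per_genome < 0)
    stop("n_unique_clusters_per_genome: must be >= 0")
  w <- cfg$within_cluster_bitscore; b <- cfg$between_cluster_bitscore
  if (length(w) != 2 || length(b) != 2 || w[2] < 0 || b[2] < 0)
    stop("within/between_cluster_bitscore: must each be c(mean, sd), sd >= 0")
  if (w[1] <= b[1])
    stop("within_cluster_bitscore: mean must exceed the between-cluster mean")
  if (cfg$self_score_scale < 1)
    stop("self_score_scale: must be >= 1 (self-scores would fall below ",
         "pairwise scores in expectation)")
  genomes <- paste0("G", seq_len(cfg$n_genomes))
  for (gs in cfg$group_specific) {
    if (is.null(gs$genomes) || is.null(gs$n))
      stop("group_specific: each entry needs genomes and n")
    ids <- if (is.numeric(gs$genomes)) paste0("G", gs$genomes) else gs$genomes
    if (!all(ids %in% genomes))
      stop("group_specific: unknown genome in group")
    if (gs$n < 0) stop("group_specific: n must be >= 0")
  }
  invisible(cfg)
}

#' Read a pangenome simulation config from YAML or JSON
#' @param path `.yaml`/`.yml` or `.json` file whose keys match
#'   [pangenome_sim_config()] arguments.
#' @return a `pangenome_sim_config`.
#' @export
read_pangenome_sim_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  for (f in c("within_cluster_bitscore", "between_cluster_bitscore"))
    if (!is.null(raw[[f]])) raw[[f]] <- unlist(raw[[f]])
  do.call(pangenome_sim_config, raw)
}

#' Generate a synthetic pangenome
#'
#' @param config a [pangenome_sim_config()].
#' @return list with `bitscores` (a [bitscore_table()] including self-pairs),
#'   `genome_map` (gene id -> genome id), `annotations` (data.frame with
#'   `gene_id`, `ko`, `category`), `modules` (named list of
#'   [kegg_module()]s), and `truth` (the planted cluster partition and bin
#'   ids).
#' @export
generate_pangenome <- function(config) {
  stopifnot(inherits(config, "pangenome_sim_config"))
  validate_pangenome_sim_config(config)
  cfg <- config
  with_seed(cfg$seed, {
    genomes <- paste0("G", seq_len(cfg$n_genomes))
    clusters <- list()
    genome_map <- character(0)
    add_cluster <- function(id, members_genomes) {
      genes <- sprintf("%s_%s", members_genomes, id)
      clusters[[id]] <<- genes
      genome_map[genes] <<- members_genomes
    }
    core_ids <- sprintf("core%04d", seq_len(cfg$n_core_clusters))
    for (id in core_ids) add_cluster(id, genomes)
    group_ids <- list()
    gi <- 0L
    for (gs in cfg$group_specific) {
      ids_g <- if (is.numeric(gs$genomes)) paste0("G", gs$genomes)
               else gs$genomes
      if (gs$n > 0) {
        ids <- sprintf("grp%02d_%04d", gi <- gi + 1L, seq_len(gs$n))
        for (id in ids) add_cluster(id, ids_g)
        group_ids[[length(group_ids) + 1L]] <-
          list(genomes = ids_g, cluster_ids = ids)
      }
    }
    unique_ids <- character(0)
    for (g in genomes) {
      if (cfg$n_unique_clusters_per_genome > 0) {
        ids <- sprintf("uniq_%s_%04d", g,
                       seq_len(cfg$n_unique_clusters_per_genome))
        for (id in ids) add_cluster(id, g)
        unique_ids <- c(unique_ids, ids)
      }
    }

    genes <- names(genome_map)
    cluster_of <- stats::setNames(
      rep(names(clusters), lengths(clusters)), unlist(clusters))
    n <- length(genes)
    wm <- cfg$within_cluster_bitscore[1]; ws <- cfg$within_cluster_bitscore[2]
    bm <- cfg$between_cluster_bitscore[1]
    bs <- cfg$between_cluster_bitscore[2]

    pair_a <- character(0); pair_b <- character(0); bits <- numeric(0)
    if (n > 1) {
      idx <- utils::combn(n, 2)
      same <- cluster_of[genes[idx[1, ]]] == cluster_of[genes[idx[2, ]]]
      score <- numeric(ncol(idx))
      score[same] <- stats::rnorm(sum(same), wm, ws)
      score[!same] <- stats::rnorm(sum(!same), bm, bs)
      score <- pmax(score, 0)
      pair_a <- genes[idx[1, ]]; pair_b <- genes[idx[2, ]]; bits <- score
    }
    # self-scores dominate every pairwise score involving the gene
    max_pair <- stats::setNames(rep(0, n), genes)
    for (k in seq_along(bits)) {
      if (bits[k] > max_pair[pair_a[k]]) max_pair[pair_a[k]] <- bits[k]
      if (bits[k] > max_pair[pair_b[k]]) max_pair[pair_b[k]] <- bits[k]
    }
    self <- cfg$self_score_scale * pmax(wm, max_pair)
    df <- data.frame(gene_a = c(pair_a, genes),
                     gene_b = c(pair_b, genes),
                     bits = c(bits, unname(self)),
                     stringsAsFactors = FALSE)
    bitscores <- bitscore_table(df)

    # annotations: one KO per planted cluster; five CAZy-like categories on
    # the first core clusters (hence present in every genome)
    ko_of_cluster <- stats::setNames(
      sprintf("K%05d", 10000 + seq_along(clusters)), names(clusters))
    cazy_families <- c("GH13", "GT2", "CE1", "AA3", "GH3")
    cat_of_cluster <- stats::setNames(rep(NA_character_, length(clusters)),
                                      names(clusters))
    n_cat <- min(length(cazy_families), length(core_ids))
    if (n_cat > 0)
      cat_of_cluster[core_ids[seq_len(n_cat)]] <- cazy_families[seq_len(n_cat)]
    annotations <- data.frame(
      gene_id = genes,
      ko = unname(ko_of_cluster[cluster_of[genes]]),
      category = unname(cat_of_cluster[cluster_of[genes]]),
      stringsAsFactors = FALSE)

    modules <- list()
    add_module <- function(id, steps) {
      if (length(steps) > 0 && all(lengths(steps) > 0))
        modules[[id]] <<- kegg_module(id, steps)
    }
    core_kos <- unname(ko_of_cluster[core_ids])
    if (length(core_kos) >= 4)
      add_module("M_CORE_A", as.list(core_kos[1:4]))
    if (length(group_ids) && length(core_kos) >= 7) {
      grp_ko <- ko_of_cluster[group_ids[[1]]$cluster_ids[1]]
      # 3 core steps + 1 group-specific step: completeness 0.75 outside the
      # group (the default-threshold boundary), 1.0 inside
      add_module("M_GROUP_B", c(as.list(core_kos[5:7]), list(unname(grp_ko))))
    }
    if (length(unique_ids) >= 3 && length(core_kos) >= 8) {
      u1 <- unique_ids[startsWith(unique_ids, "uniq_G1_")]
      if (length(u1) >= 3)
        add_module("M_UNIQUE_G1",
                   c(list(core_kos[8]), as.list(unname(ko_of_cluster[u1[1:3]]))))
    }
    if (length(core_kos) >= 10 && length(unique_ids) >= 1)
      # step 2 satisfiable by either a core KO or a G1-unique KO
      add_module("M_ALT_C", list(core_kos[9],
                                 c(core_kos[10],
                                   unname(ko_of_cluster[unique_ids[1]]))))

    list(bitscores = bitscores,
         genome_map = genome_map,
         annotations = annotations,
         modules = modules,
         truth = list(clusters = clusters,
                      core_ids = core_ids,
                      unique_ids = unique_ids,
                      group_specific = group_ids,
                      ko_of_cluster = ko_of_cluster,
                      category_of_cluster = cat_of_cluster))
  })
}

#' Write a bitscore table to TSV
#' @param bitscores a [bitscore_table()].
#' @param path output path.
#' @export
write_bitscores <- function(bitscores, path) {
  utils::write.table(as.data.frame(bitscores)[c("gene_a", "gene_b", "bits")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Write a gene-to-genome map to TSV
#' @param genome_map named vector, gene id -> genome id.
#' @param path output path.
#' @export
write_genome_map <- function(genome_map, path) {
  utils::write.table(data.frame(gene_id = names(genome_map),
                                genome_id = unname(genome_map)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Write a gene annotation table to TSV
#' @param annotations data.frame with `gene_id` plus annotation columns.
#' @param path output path.
#' @export
write_annotations <- function(annotations, path) {
  utils::write.table(annotations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
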