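test_that("minbit follows its definition and rejects bad self-scores", {
  expect_equal(minbit(50, 100, 80), 0.625)
  expect_equal(minbit(7, 7, 7), 1)
  expect_error(minbit(10, 0, 5), "self-scores")
  expect_error(minbit(-1, 10, 5), "non-negative")
  # symmetric in the two self-scores
  expect_equal(minbit(30, 120, 60), minbit(30, 60, 120))
})

test_that("minbit agrees with an elementwise oracle on random tables", {
  set.seed(71)
  for (rep in 1:20) {
    n <- sample(3:12, 1)
    self <- runif(n, 50, 400)
    ab <- runif(n * n, 0, 50)
    i <- sample(n, n * n, replace = TRUE)
    j <- sample(n, n * n, replace = TRUE)
    got <- minbit(ab, self[i], self[j])
    for (k in seq_along(ab))
      expect_identical(got[k], ab[k] / min(self[i[k]], self[j[k]]))
  }
})

test_that("similarity graph keeps exactly the edges at or above the minbit cutoff", {
  df <- data.frame(
    gene_a = c("a", "b", "c", "a", "a", "b"),
    gene_b = c("a", "b", "c", "b", "c", "c"),
    bits = c(100, 100, 80, 49, 50, 10))
  g <- build_similarity_graph(bitscore_table(df))
  expect_equal(g$adjacency["a", "b"], 0)        # minbit 0.49 < 0.5
  expect_equal(g$adjacency["a", "c"], 50 / 80)  # min self is 80
  expect_equal(g$adjacency["b", "c"], 0)
  # threshold 0 connects every scored pair
  g0 <- build_similarity_graph(bitscore_table(df), threshold = 0)
  expect_true(all(g0$adjacency[upper.tri(g0$adjacency)] > 0))
  # both orientations present: the larger bitscore wins
  df2 <- rbind(df, data.frame(gene_a = "b", gene_b = "a", bits = 60))
  g2 <- build_similarity_graph(bitscore_table(df2))
  expect_equal(g2$adjacency["a", "b"], 0.6)
  # a missing self-score is an error naming the gene
  expect_error(bitscore_table(df[-1, ]), "self-score for gene: a")
})

test_that("MCL separates disjoint triangles and keeps singletons", {
  adj <- matrix(0, 7, 7,
                dimnames = list(letters[1:7], letters[1:7]))
  for (p in list(c(1, 2), c(2, 3), c(1, 3), c(4, 5), c(5, 6), c(4, 6)))
    adj[p[1], p[2]] <- adj[p[2], p[1]] <- 1
  res <- mcl_cluster(adj)
  expect_length(res$clusters, 3)
  sets <- lapply(res$clusters, sort)
  has_set <- function(x) any(vapply(sets, identical, logical(1), x))
  expect_true(has_set(c("a", "b", "c")))
  expect_true(has_set(c("d", "e", "f")))
  expect_true(has_set("g"))
  single <- mcl_cluster(matrix(0, 1, 1, dimnames = list("x", "x")))
  expect_equal(unname(single$clusters), list("x"))
})

test_that("MCL output is always a partition of the node set", {
  set.seed(73)
  for (rep in 1:5) {
    n <- sample(5:15, 1)
    adj <- matrix(0, n, n)
    idx <- which(upper.tri(adj))
    on <- sample(idx, ceiling(length(idx) * 0.3))
    adj[on] <- runif(length(on), 0.5, 1)
    adj <- adj + t(adj)
    dimnames(adj) <- list(paste0("g", 1:n), paste0("g", 1:n))
    res <- mcl_cluster(adj)
    genes <- unlist(res$clusters)
    expect_setequal(genes, paste0("g", 1:n))
    expect_equal(anyDuplicated(genes), 0L)
  }
})

test_that("higher inflation never coarsens the clustering", {
  # two triangles joined by one moderate bridge
  adj <- matrix(0, 6, 6, dimnames = list(letters[1:6], letters[1:6]))
  for (p in list(c(1, 2), c(2, 3), c(1, 3), c(4, 5), c(5, 6), c(4, 6)))
    adj[p[1], p[2]] <- adj[p[2], p[1]] <- 1
  adj[3, 4] <- adj[4, 3] <- 0.6
  n_low <- length(mcl_cluster(adj, inflation = 1.5)$clusters)
  n_high <- length(mcl_cluster(adj, inflation = 4)$clusters)
  expect_gte(n_high, n_low)
})

test_that("MCL recovers the planted pangenome partition exactly", {
  pg <- generate_pangenome(pangenome_sim_config(
    n_genomes = 3, n_core_clusters = 5, n_unique_clusters_per_genome = 2,
    group_specific = list(),
    within_cluster_bitscore = c(200, 5),
    between_cluster_bitscore = c(10, 3), seed = 11))
  clusters <- mcl_cluster(build_similarity_graph(pg$bitscores))
  genes <- names(pg$genome_map)
  got <- cluster_labels(clusters, genes)
  truth <- cluster_labels(pg$truth$clusters, genes)
  expect_equal(ari(got, truth), 1.0)
  expect_equal(ari(got, truth), mclust::adjustedRandIndex(got, truth))
})

test_that("cluster partitioning bins core, unique and group-specific clusters", {
  clusters <- list(c1 = c("A_x", "B_x", "C_x"),
                   c2 = c("A_y", "B_y"),
                   c3 = c("A_z1", "A_z2"),
                   c4 = "B_w")
  gm <- setNames(c("GA", "GB", "GC", "GA", "GB", "GA", "GA", "GB"),
                 c("A_x", "B_x", "C_x", "A_y", "B_y", "A_z1", "A_z2", "B_w"))
  bins <- partition_clusters(clusters, gm)
  expect_equal(bins$core, "c1")
  expect_equal(bins$unique$GA, "c3")
  expect_equal(bins$unique$GB, "c4")
  expect_equal(bins$accessory, "c2")
  with_group <- partition_clusters(clusters, gm, group = c("GA", "GB"))
  expect_equal(with_group$group_core, "c2")
  expect_error(partition_clusters(clusters, gm, group = "nope"),
               "unknown genome")
})

test_that("planted core and unique bins are recovered at exact sizes", {
  pg <- generate_pangenome(pangenome_sim_config(
    n_genomes = 3, n_core_clusters = 5, n_unique_clusters_per_genome = 2,
    group_specific = list(),
    within_cluster_bitscore = c(200, 5),
    between_cluster_bitscore = c(10, 3), seed = 13))
  clusters <- mcl_cluster(build_similarity_graph(pg$bitscores))
  bins <- partition_clusters(clusters, pg$genome_map)
  expect_length(bins$core, 5)
  expect_equal(sum(lengths(bins$unique)), 6)
  expect_length(bins$accessory, 0)
  pa <- bins$presence_absence
  expect_true(all(rowSums(pa) >= 1))
})

test_that("module completeness counts satisfied steps with alternatives", {
  m <- kegg_module("M1", list("K1", "K2", "K3", "K4"))
  res <- module_completeness(m, c("K1", "K2", "K3"))
  expect_equal(res$completeness, 0.75)
  expect_true(res$complete)  # 3 of 4 steps meets the 0.75 default exactly
  res2 <- module_completeness(m, c("K1", "K2"))
  expect_false(res2$complete)
  expect_equal(module_completeness(m, character(0))$completeness, 0)
  malt <- kegg_module("M2", list(c("K1", "K2"), "K3"))
  expect_equal(module_completeness(malt, "K2")$completeness, 0.5)
  expect_error(kegg_module("M3", list()), "no steps")
  expect_error(kegg_module("M4", list(character(0))), "empty step")
})

test_that("completeness is monotone in the KO set", {
  set.seed(79)
  kos <- paste0("K", 1:8)
  m <- kegg_module("M", list(kos[1:2], kos[3], kos[4:5], kos[6], kos[7:8]))
  for (rep in 1:30) {
    small <- sample(kos, sample(0:7, 1))
    big <- union(small, sample(kos, sample(1:8, 1)))
    expect_lte(module_completeness(m, small)$completeness,
               module_completeness(m, big)$completeness)
  }
})

test_that("per-genome metabolism estimation reflects the planted module design", {
  pg <- generate_pangenome(pangenome_sim_config(seed = 17))
  metab <- estimate_metabolism(pg$modules, pg$annotations, pg$genome_map)
  core_a <- metab[metab$module_id == "M_CORE_A", ]
  expect_true(all(core_a$completeness == 1))
  grp <- metab[metab$module_id == "M_GROUP_B", ]
  in_group <- grp$genome_id %in% c("G1", "G2", "G3")
  expect_true(all(grp$completeness[in_group] == 1))
  expect_true(all(grp$completeness[!in_group] == 0.75))
  expect_true(all(grp$complete))  # 0.75 sits exactly at the default cutoff
  uniq <- metab[metab$module_id == "M_UNIQUE_G1", ]
  expect_equal(uniq$completeness[uniq$genome_id == "G1"], 1)
  expect_true(all(uniq$completeness[uniq$genome_id != "G1"] == 0.25))
})

test_that("annotation category counts recover the planted per-genome tallies", {
  empty <- count_annotation_categories(
    data.frame(gene_id = character(0), category = character(0)),
    setNames("G1", "g1"))
  expect_equal(unname(empty$totals), 0L)

  ann <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                    category = c("GH13", "GH13", "GH13", NA))
  gm <- setNames(c("G1", "G1", "G1", "G1"), paste0("g", 1:4))
  res <- count_annotation_categories(ann, gm)
  expect_equal(res$counts["G1", "GH13"], 3L)
  expect_equal(unname(res$totals["G1"]), 3L)

  pg <- generate_pangenome(pangenome_sim_config(
    n_genomes = 4, n_core_clusters = 10, n_unique_clusters_per_genome = 1,
    group_specific = list(), seed = 19))
  res2 <- count_annotation_categories(pg$annotations, pg$genome_map)
  # five CAZy-like families planted on core clusters: one gene per genome
  expect_equal(dim(res2$counts), c(4L, 5L))
  expect_true(all(res2$counts == 1L))
  expect_true(all(res2$totals == 5L))
  # category_map collapses raw labels before counting
  res3 <- count_annotation_categories(
    pg$annotations, pg$genome_map,
    category_map = c(GH13 = "GH", GH3 = "GH"))
  expect_equal(unname(res3$counts[, "GH"]), rep(2L, 4))
})
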