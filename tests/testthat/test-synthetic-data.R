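test_that("community generator is bit-identical under a fixed seed", {
  cfg <- community_sim_config(seed = 42)
  a <- generate_community(cfg)
  b <- generate_community(cfg)
  expect_identical(a$table, b$table)
  expect_identical(a$taxonomy, b$taxonomy)
  expect_identical(a$metadata, b$metadata)
  c2 <- generate_community(community_sim_config(seed = 43))
  expect_false(identical(unclass(a$table), unclass(c2$table)))
})

test_that("generated counts are non-negative integers at in-range depths", {
  sim <- generate_community(community_sim_config(seed = 5))
  counts <- unclass(sim$table)
  expect_true(all(counts >= 0))
  expect_true(is.integer(counts))
  depths <- colSums(counts)
  expect_true(all(depths >= 2000 & depths <= 5000))
})

test_that("a fully prevalent planted taxon hits its target mean abundance under low noise", {
  cfg <- community_sim_config(
    n_samples_per_type = c(mycelium = 10),
    planted_core = data.frame(taxon_id = "ASV_planted",
                              sample_type = "mycelium",
                              occupancy = 1.0, mean_abundance = 0.5),
    n_background_taxa = 50,
    dirichlet_concentration = 1e6,  # noise-free limit
    n_controls = 0, contaminant_taxa = character(0),
    depth_range = c(5000, 5000), seed = 8)
  sim <- generate_community(cfg)
  rel <- tss_normalize(sim$table)
  expect_lt(abs(mean(rel["ASV_planted", ]) - 0.5), 0.05)
})

test_that("planted occupancy converges to the configured Bernoulli rate", {
  n <- 300
  pi0 <- 0.6
  cfg <- community_sim_config(
    n_samples_per_type = c(mycelium = n),
    planted_core = data.frame(taxon_id = "ASV_planted",
                              sample_type = "mycelium",
                              occupancy = pi0, mean_abundance = 0.3),
    n_background_taxa = 30, n_controls = 0,
    contaminant_taxa = character(0), seed = 21)
  sim <- generate_community(cfg)
  occ <- mean(unclass(sim$table)["ASV_planted", ] > 0)
  # 99.9% binomial band: wide enough that a correctly calibrated generator
  # fails only once in a thousand seeds
  ci_half <- 3.29 * sqrt(pi0 * (1 - pi0) / n)
  expect_lt(abs(occ - pi0), ci_half)
})

test_that("contaminant taxa have nonzero counts in every control sample", {
  sim <- generate_community(community_sim_config(seed = 3))
  ctrl <- sim$metadata$sample_id[sim$metadata$sample_type == "control"]
  expect_length(ctrl, 2)
  contam <- unclass(sim$table)[sim$truth$contaminants, ctrl, drop = FALSE]
  expect_true(all(contam > 0))
})

test_that("community config invariants are rejected with the field named", {
  expect_error(community_sim_config(
    planted_core = data.frame(taxon_id = "x", sample_type = "mycelium",
                              occupancy = 1.2, mean_abundance = 0.1)),
    "occupancy")
  expect_error(community_sim_config(
    planted_core = data.frame(taxon_id = c("x", "y"),
                              sample_type = "mycelium",
                              occupancy = 0.5,
                              mean_abundance = c(0.6, 0.5))),
    "mean_abundance")
  expect_error(community_sim_config(depth_range = c(0, 10)), "depth_range")
  expect_error(community_sim_config(dirichlet_concentration = 0),
               "dirichlet_concentration")
  expect_error(community_sim_config(n_background_taxa = 0),
               "n_background_taxa")
})

test_that("community config round-trips through YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  cfg <- community_sim_config(n_samples_per_type = c(mycelium = 4),
                              n_background_taxa = 10, n_controls = 1,
                              contaminant_taxa = "ASV_c1", seed = 2)
  yaml::write_yaml(list(
    n_samples_per_type = list(mycelium = 4),
    n_background_taxa = 10, n_controls = 1,
    contaminant_taxa = "ASV_c1", seed = 2,
    planted_core = lapply(seq_len(nrow(cfg$planted_core)), function(i)
      as.list(cfg$planted_core[i, ]))), path)
  cfg2 <- read_community_sim_config(path)
  expect_identical(generate_community(cfg)$table,
                   generate_community(cfg2)$table)
})

test_that("pangenome generator plants the requested presence/absence structure", {
  cfg <- pangenome_sim_config(n_genomes = 3, n_core_clusters = 5,
                              n_unique_clusters_per_genome = 2,
                              group_specific = list(), seed = 4)
  pg <- generate_pangenome(cfg)
  pa <- presence_absence(pg$truth$clusters, pg$genome_map)
  expect_equal(sum(rowSums(pa) == 3), 5)  # 5 all-ones rows
  expect_equal(sum(rowSums(pa) == 1), 6)  # 6 single-one rows
  # planted core clusters: exactly one member per genome
  for (id in pg$truth$core_ids)
    expect_setequal(unname(pg$genome_map[pg$truth$clusters[[id]]]),
                    c("G1", "G2", "G3"))
})

test_that("well-separated score distributions give separated minbit values", {
  cfg <- pangenome_sim_config(n_genomes = 3, n_core_clusters = 5,
                              n_unique_clusters_per_genome = 2,
                              group_specific = list(),
                              within_cluster_bitscore = c(200, 5),
                              between_cluster_bitscore = c(10, 3),
                              self_score_scale = 1.1, seed = 9)
  pg <- generate_pangenome(cfg)
  bs <- as.data.frame(pg$bitscores)
  self <- attr(pg$bitscores, "self_scores")
  cluster_of <- setNames(rep(names(pg$truth$clusters),
                             lengths(pg$truth$clusters)),
                         unlist(pg$truth$clusters))
  pairs <- bs[bs$gene_a != bs$gene_b, ]
  mb <- minbit(pairs$bits, self[pairs$gene_a], self[pairs$gene_b])
  same <- cluster_of[pairs$gene_a] == cluster_of[pairs$gene_b]
  expect_gt(min(mb[same]), max(mb[!same]))
  # self-scores dominate every pairwise score involving the gene
  expect_true(all(pairs$bits <= pmin(self[pairs$gene_a],
                                     self[pairs$gene_b])))
})

test_that("pangenome generator is deterministic and validates its config", {
  cfg <- pangenome_sim_config(n_genomes = 3, n_core_clusters = 4,
                              n_unique_clusters_per_genome = 1,
                              group_specific = list(), seed = 12)
  expect_identical(generate_pangenome(cfg)$bitscores,
                   generate_pangenome(cfg)$bitscores)
  expect_error(pangenome_sim_config(self_score_scale = 0.8),
               "self_score_scale")
  expect_error(pangenome_sim_config(within_cluster_bitscore = c(10, 1),
                                    between_cluster_bitscore = c(50, 1)),
               "within_cluster_bitscore")
  expect_error(pangenome_sim_config(
    group_specific = list(list(genomes = "G99", n = 2))), "group")
})

test_that("generated tables round-trip through the pipeline's TSV formats", {
  sim <- generate_community(community_sim_config(
    n_samples_per_type = c(mycelium = 3), n_background_taxa = 8,
    n_controls = 1, seed = 6))
  d <- withr::local_tempdir()
  write_asv_table(sim$table, file.path(d, "t.tsv"))
  write_taxonomy(sim$taxonomy, file.path(d, "x.tsv"))
  write_metadata(sim$metadata, file.path(d, "m.tsv"))
  expect_identical(unclass(read_asv_table(file.path(d, "t.tsv"))),
                   unclass(sim$table))
  expect_equal(read_taxonomy(file.path(d, "x.tsv")), sim$taxonomy)
  expect_equal(read_metadata(file.path(d, "m.tsv")), sim$metadata)

  pg <- generate_pangenome(pangenome_sim_config(
    n_genomes = 2, n_core_clusters = 3, n_unique_clusters_per_genome = 1,
    group_specific = list(), seed = 7))
  write_bitscores(pg$bitscores, file.path(d, "b.tsv"))
  write_genome_map(pg$genome_map, file.path(d, "g.tsv"))
  bs <- read_bitscores(file.path(d, "b.tsv"))
  expect_equal(sort(attr(bs, "genes")), sort(attr(pg$bitscores, "genes")))
  expect_identical(read_genome_map(file.path(d, "g.tsv")), pg$genome_map)
  mods <- withr::local_tempfile(fileext = ".txt")
  write_kegg_modules(pg$modules, mods)
  back <- read_kegg_modules(mods)
  expect_equal(lapply(back, unclass), lapply(pg$modules, unclass),
               ignore_attr = TRUE)
})
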