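# morelbiome

Tools for characterising the bacterial communities ("bacteriome") that
inhabit fungal structures — morel (*Morchella*) mycelium, sclerotia and
fruiting bodies — from denoised 16S rRNA amplicon data, together with a
comparative-genomics stage for associated bacterial isolates. The package
is aimed at microbial ecologists who have an ASV count table, a taxonomy
and sample metadata in hand and want a tested, reproducible route from
there to core-community statements, ordination-based group validation and
pangenome summaries.

## What it computes

**Layered core community.** A taxon with relative abundances $x_{is}$
belongs to the core at prevalence threshold $p$ and detection threshold
$d$ when

$$\frac{1}{n}\bigl|\{s : x_{is} > d\}\bigr| \ge p .$$

Rather than committing to one arbitrary $(p,d)$, the package evaluates a
full grid (prevalence 30–100% in 5% steps; detection 0.05–10% across 12
values) and collapses it into a chain of nested core layers — inner layers
holding the most ubiquitous taxa, outer layers increasingly marginal ones —
exported as JSON for Venn-style rendering.

**Community structure.** Bray–Curtis dissimilarities
($d_{ij} = 1-\sum_f \min(x_{fi},x_{fj})$), nonmetric multidimensional
scaling minimising Kruskal stress-1 with isotonic disparities, and a
one-factor PERMANOVA,

$$F = \frac{SS_\mathrm{between}/(a-1)}{SS_\mathrm{within}/(N-a)},\qquad
p = \frac{1+\#\{F^\ast \ge F\}}{1+B},$$

all implemented from first principles and cross-checked against vegan in
the test suite.

**Pangenome.** From pairwise protein bitscores: minbit normalisation
($s_{ab}/\min(s_{aa},s_{bb})$, cutoff 0.5), Markov clustering (expansion 2,
inflation 2) into gene clusters, core/unique/group-specific binning from
cluster-by-genome presence/absence, KEGG-module completeness (fraction of
steps with at least one alternative KO present; complete at ≥ 0.75) and
per-genome annotation-category tallies.

**Synthetic data.** Seeded generators plant known community structure
(Bernoulli occupancy × Dirichlet-multinomial composition, log-normal
background, no-template-control contaminants) and known pangenome
structure (core/unique/group clusters with separated bitscore
distributions), so every stage is testable without external data.

## Worked example

```r
library(morelbiome)

# simulate a study: 26 mycelium, 8 sclerotia, 10 fruiting bodies + 2 controls
sim <- generate_community(community_sim_config(seed = 7))
rel <- preprocess_asv_table(sim$table, sim$taxonomy, sim$metadata)

# layered core community per structure type
for (t in c("mycelium", "sclerotia", "fruiting_body")) {
  ids <- sim$metadata$sample_id[sim$metadata$sample_type == t]
  grid <- compute_core_grid(rel_abundance(unclass(rel)[, ids], check = FALSE))
  inner <- innermost_core(grid)
  cat(sprintf("%-14s innermost core at (p=%.2f, d=%.2g%%): %s (max occupancy %.2f)\n",
              t, inner$core$p, 100 * inner$core$d,
              paste(inner$core$members, collapse = ", "),
              inner$max_prevalence))
}
#> mycelium       innermost core at (p=0.90, d=10%): Pseudomonas (max occupancy 0.92)
#> sclerotia      innermost core at (p=1.00, d=10%): Pseudomonas (max occupancy 1.00)
#> fruiting_body  innermost core at (p=0.55, d=0.05%): bg_040 (max occupancy 0.60)

# ordination and group validation
d <- bray_curtis(rel)
nmds(d, k = 2, n_starts = 20, seed = 1)
#> NMDS: 44 points in 2 dimensions, stress-1 = 0.21874 (converged)
groups <- setNames(sim$metadata$sample_type, sim$metadata$sample_id)
permanova(d, groups[colnames(rel)], n_permutations = 999, seed = 2)
#> PERMANOVA: pseudo-F(2, 41) = 3.638, p = 0.001 (999 permutations)
#>   SS between = 2.275, SS within = 12.82, SS total = 15.09

# pangenome: cluster genes from bitscores, bin, score KEGG modules
pg <- generate_pangenome(pangenome_sim_config(seed = 7))
clusters <- mcl_cluster(build_similarity_graph(pg$bitscores, threshold = 0.5))
clusters
#> 100 gene clusters over 324 genes (MCL inflation 2, converged)
bins <- partition_clusters(clusters, pg$genome_map, group = c("G1", "G2", "G3"))
cat(sprintf("core: %d   unique: %d   group-core (G1-G3): %d\n",
            length(bins$core), sum(lengths(bins$unique)), length(bins$group_core)))
#> core: 40   unique: 48   group-core (G1-G3): 12
```

Read through: the dominant planted taxon gives mycelium and sclerotia a
high-prevalence, high-abundance innermost core (occupancy 0.92 and 1.00 at
the 10% detection threshold), while the fruiting-body core is diffuse —
its innermost non-empty cell sits at prevalence 0.55 and the lowest
detection threshold, occupied by a background genus. The PERMANOVA
confirms that structure type explains community composition (p = 0.001),
and the gene clustering recovers the planted pangenome exactly (40 core,
48 unique, 12 group-specific clusters).

Equivalent I/O exists for real data: `read_asv_table()`,
`read_taxonomy()`, `read_metadata()`, `read_bitscores()`,
`read_genome_map()`, `read_annotations()`, `read_kegg_modules()`, and
`run_pipeline()` orchestrates the stages end-to-end from a YAML/JSON
config with a checksummed run manifest.

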