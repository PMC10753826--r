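---
title: "Methods: layered core-bacteriome delineation and comparative genomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: layered core-bacteriome delineation and comparative genomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morelbiome)
```

# Scope

`morelbiome` analyses the bacterial communities that live in and on fungal
structures — vegetative mycelium, sclerotia (compact survival structures)
and fruiting bodies — starting from a denoised 16S rRNA amplicon sequence
variant (ASV) count table, and complements the community view with a
comparative-genomics stage for bacterial isolates (here, *Pseudomonas*-like
genomes). Everything upstream of the ASV table (primer trimming, denoising,
chimera removal, taxonomic classification) and everything upstream of the
pairwise protein bitscore table (assembly, annotation, all-versus-all
alignment) is out of scope: the package consumes those standard products
and implements the analysis that turns them into biological statements.

# Preprocessing model

Four steps run in a fixed order, each a small, separately testable
operation:

1. **Control-based decontamination.** Any feature with at least one read in
   any no-template control sample is removed, then the control columns are
   dropped. This is presence-based filtering, deliberately conservative:
   fungal-structure samples are low-biomass, so reagent contaminants can be
   abundant, and a single control read is treated as evidence of
   contamination. A `min_count` override exists for users who prefer a
   higher bar. The filter is idempotent and, with zero controls, the
   identity.
2. **Kingdom filtering.** Only features classified to kingdom *Bacteria*
   are retained; unassigned kingdoms (including features missing from the
   taxonomy entirely) are discarded along with chloroplast/eukaryote
   carry-over.
3. **Total-sum scaling (TSS).** Counts become per-sample proportions.
   Filtering precedes TSS so that proportions are computed on the cleaned
   table; an all-zero sample is an error (it cannot be normalised), named
   in the message.
4. **Genus agglomeration.** Proportions of ASVs sharing an assigned genus
   are summed; genera that carry no information ("uncultured",
   "metagenome", and similar placeholder tokens — the list is configurable
   because taxonomies do not standardise them) are pooled into a single
   `unassigned` row. Sums of proportions are exact, so per-sample totals
   stay at 1 to within floating-point error; tests enforce 1e-9.

Downstream analyses run on the genus-level table by default. Core-community
labels are genus names in practice, and genus-level aggregation makes
occupancy robust to ASV-level splitting of one population into several
near-identical variants; a `genus_level = FALSE` switch runs everything at
ASV level instead.

# Layered core community

A taxon is *detected* in a sample when its relative abundance strictly
exceeds a detection threshold $d$ ("abundance above which a taxon is
considered present"); its *occupancy* (prevalence) is the fraction of
samples in which it is detected. The core community at a threshold pair
$(p, d)$ is

$$\mathrm{core}(p,d) = \{\,i : \tfrac{1}{n}\,|\{s : x_{is} > d\}| \ge p\,\}.$$

Because no single $(p, d)$ choice is canonical, the package evaluates a
full grid — by default prevalence 30–100% in 5% steps and detection
thresholds of 0.05, 0.10, 0.15, 0.20, 0.30, 0.40, 0.50, 0.75, 1, 2, 5 and
10 percent (fractions internally; percent values are divided by exactly
100 at the interface). The grid is monotone by construction: raising either
threshold can only shrink the core, which is the package's most heavily
tested invariant (exhaustive brute-force agreement on random tables, plus
subset checks across comparable cells).

The comparison conventions ($>$ on detection, $\ge$ on prevalence) are the
package's reading of the definitions above; both are exposed as flags
because existing core-microbiome implementations differ on boundary
behaviour.

## From a 2-D grid to nested layers

The grid is summarised as a chain of nested "layers" — the structure drawn
as an inclusive Venn diagram, with the innermost layer holding the most
ubiquitous taxa. Collapsing a partially ordered grid onto a chain admits
more than one defensible rule, so two are implemented and the choice is
recorded in the export:

- **diagonal** (default): pair the $k$-th largest prevalence with the
  $k$-th largest detection value, index-mapping the shorter grid
  proportionally onto the longer. Both thresholds relax together, so
  nesting follows directly from monotonicity.
- **union-rank**: score each cell by the number of grid cells it dominates
  (both thresholds at or below its own), so the strictest cell has the
  highest rank, and let layer $k$ be the union of all cells at or above
  the $k$-th highest rank. The pooled family grows as the cutoff drops,
  again giving a chain. (Orienting the rank the other way is vacuous:
  since every looser cell's core contains every stricter cell's core, all
  such unions collapse to the loosest cell's set.)

Consecutive identical layers are collapsed in both modes. The *innermost
core* of a grid is the non-empty cell with lexicographically highest
$(p, d)$ — prevalence first, as the leading parameter — together with the
maximum occupancy among its members; ties cannot arise because the scan
order is total. The JSON export carries thresholds, members and
occupancies so that external tools can render proportional Venn diagrams;
the geometry of such diagrams is explicitly out of scope.

# Ordination and group validation

Community dissimilarity is Bray–Curtis on TSS proportions,
$d_{ij} = 1 - \sum_f \min(x_{fi}, x_{fj})$, the standard abundance-based
ecological distance (equivalent to the count formulation once samples are
normalised). Both the metric and the taxonomic level are recorded in the
ordination output so a reader knows exactly what was embedded.

**NMDS.** Nonmetric multidimensional scaling follows Kruskal: find
$k$-dimensional coordinates whose inter-point distances $\delta_{ij}$
preserve the rank order of the $d_{ij}$, minimising stress-1
$\sqrt{\sum(\delta_{ij} - \hat d_{ij})^2 / \sum \delta_{ij}^2}$ where the
disparities $\hat d$ are the isotonic (pool-adjacent-violators, via
`stats::isoreg`) regression of $\delta$ on the rank order of $d$; rank
ties are broken by the current configuration distances (primary
treatment). Each iteration applies the Guttman/SMACOF majorisation update
with the current disparities as targets; a step that would increase stress
terminates the run instead, so stress is non-increasing within a run. The
first start is the classical metric-scaling configuration (`cmdscale`),
the remainder random; defaults are $k = 2$, 20 starts, tolerance $10^{-7}$
on the stress change, 300 iterations. The reported stress is exactly
recomputable from the returned coordinates (`nmds_stress`), which the
tests check to $10^{-8}$.

**PERMANOVA.** The one-factor permutation test computes
$SS_\mathrm{total} = \tfrac{1}{N}\sum_{i<j} d_{ij}^2$,
$SS_\mathrm{within} = \sum_g \tfrac{1}{n_g}\sum_{i<j \in g} d_{ij}^2$,
$SS_\mathrm{between} = SS_\mathrm{total} - SS_\mathrm{within}$ and
pseudo-$F = \tfrac{SS_\mathrm{between}/(a-1)}{SS_\mathrm{within}/(N-a)}$,
with the p-value $(1 + \#\{F^* \ge F\})/(1 + B)$ over $B$ uniform label
permutations (default 999, the conventional choice). Permutations are
unrestricted — the design is a single factor without strata. A degenerate
geometry with all pairwise distances equal yields pseudo-$F = 1$ exactly
(the between- and within-group mean squares coincide), hence $p = 1$;
perfectly separated blocks yield the minimal attainable p-value
$1/(B+1)$. Test calibration is checked by simulation: under a null where
both groups share one generative distribution, the rejection rate at
$\alpha = 0.05$ over 500 replicates of 999 permutations must fall inside
the binomial band [0.032, 0.070], and the p-value distribution must pass a
Kolmogorov–Smirnov uniformity check.

# Comparative genomics

The pangenome stage consumes a table of pairwise protein bitscores
(including self-alignments) and a gene-to-genome map.

- **minbit filtering.** Each pair is scored
  $\mathrm{minbit}(a,b) = s_{ab} / \min(s_{aa}, s_{bb})$ — the fraction of
  the weaker self-alignment recovered by the cross-alignment. Pairs below
  0.5 (the conventional default) are discarded; when both orientations of
  a pair are reported, the larger bitscore is used.
- **Markov clustering (MCL).** The surviving weighted graph is clustered
  by alternating expansion (matrix power, 2) and inflation (entrywise
  power, default 2.0, then column renormalisation) on the column-stochastic
  transition matrix, with self-loops weighted by each node's maximum
  incident edge so that every column is stochastic from the start. Entries
  below $10^{-8}$ are pruned each iteration; iteration stops when the
  matrix changes by less than $10^{-6}$ or after 100 iterations (the
  result then carries `converged = FALSE`). Clusters are the connected
  components of the limit matrix's non-zero support; singletons are legal
  clusters. Inflation 2.0 is the documented common default of MCL
  implementations; it is exposed, as higher inflation yields finer
  partitions (tested as non-coarsening on a bridged-triangles fixture).
- **Binning.** From the cluster-by-genome presence/absence matrix
  (presence = at least one member gene), clusters are binned as *core*
  (all genomes), *unique* (exactly one genome), *group-core* (all of a
  given genome subset and none outside it) and *accessory* (the rest).
- **KEGG-module completeness.** A module is an ordered list of steps, each
  satisfiable by alternative KEGG Orthologs; completeness is the fraction
  of satisfied steps and a module is called complete at a threshold of
  0.75 (three of four steps suffice — the boundary is inclusive). The full
  KEGG boolean definition grammar (nested AND/OR, optional steps) is
  deliberately not parsed: threshold-based completeness over flat
  steps-with-alternatives is what the downstream comparisons consume. The
  plain-text module format is one line per module,
  `ID<TAB>alt1,alt2;step2;...`.
- **Annotation tallies.** Generic per-genome category counting (used here
  for CAZy-style family tallies) with an optional label-collapsing map.

# The synthetic-data generator

Because the sequencing data behind studies of this kind are rarely
re-distributable, every stage is exercised against a generator with known
planted structure.

**Communities.** For each sample of type $t$, a target composition is
built: each planted taxon of type $t$ is present with its configured
occupancy $\pi$ (independent Bernoulli — the simplest model matching the
prevalence definition) at its configured mean relative abundance $\mu$;
contaminant taxa carry a trace share ($2 \times 10^{-3}$); the remaining
mass goes to background taxa with log-normal shares. The composition is
then drawn from a Dirichlet centred on the target (concentration
$\times$ target as the parameter vector), and counts from a multinomial at
a uniform-random depth. Controls are contaminant-dominated (80% of target
mass); one read per contaminant is reserved before the multinomial draw so
that contaminants are always represented in controls while the total depth
stays inside the configured range (configs where the minimum depth cannot
accommodate the reservation are rejected).

Two generator choices deserve justification:

- **Background shares are redrawn per sample**, not fixed per sample type.
  Real fungal-structure communities — fruiting bodies especially — show
  strong sample-to-sample turnover: most taxa are not shared between
  specimens. Redrawing heavy-tailed (sdlog 3) log-normal shares for every
  sample reproduces that turnover, which is exactly what makes a diffuse,
  low-occupancy core detectably different from a dominant, high-occupancy
  one. A fixed background profile would give every abundant background
  taxon occupancy near 1 and erase the contrast the core analysis exists
  to measure.
- **Defaults mirror the target study design**: 26 mycelium, 8 sclerotia
  and 10 fruiting-body samples plus 2 no-template controls; a
  Pseudomonas-like taxon planted at occupancy 0.95/abundance 0.20 in
  mycelium and 1.0/0.25 in sclerotia; a diffuse Pedobacter/
  Bradyrhizobium-like fruiting-body core at 0.55/0.02; 120 background
  taxa; depth 2000–5000; Dirichlet concentration 100 (moderate
  compositional noise).

What the generator does *not* emulate: read-level error and chimeras,
phylogenetic correlation between taxon abundances, depth-dependent taxon
discovery, or cross-sample contamination gradients. Passing tests
therefore demonstrate that the implementation computes its definitions
correctly on data with realistic compositional structure — not that the
pipeline is robust to every artefact of real sequencing runs.

**Pangenomes.** Planted clusters (core: one gene per genome; unique:
single genes; group-specific: one gene per group member) receive
within-cluster bitscores from a high distribution and cross-cluster scores
from a low one (within mean must exceed between mean); each gene's
self-score is `self_score_scale` (≥ 1, enforced) times the larger of the
within-cluster mean and the gene's largest pairwise score, so self-scores
dominate as they must. One KO per planted cluster and five CAZy-like
families on core clusters feed module-completeness and category-count
tests, including a module whose completeness is exactly 0.75 outside a
planted genome group — the threshold boundary.

Both generators funnel all randomness through one integer seed and are
bit-reproducible; the caller's RNG state is saved and restored.

# Orchestration and reproducibility

`run_pipeline()` executes simulate (optional) → preprocess → per-structure
core grids and layers → ordination with PERMANOVA → pangenome, writing
TSV/JSON artifacts plus a manifest (config echo, seed, package version,
md5 checksum per file). Stage seeds are derived from the master seed by
fixed offsets, so two runs with the same config produce byte-identical
artifacts; a failing stage aborts with its name while earlier artifacts
remain on disk. Configuration is a nested list, loadable from YAML or
JSON with unknown keys rejected.

# Problem sizes and numerical choices

The test suite validates the statistics at deliberately modest sizes — the
package's own choice of what suffices to pin each property down:
brute-force core agreement on 1000 random tables up to 10 × 10;
monotonicity on 200 tables across the full default grid; planted-core
contrast on 100 replicate simulated studies (26 vs 10 samples); PERMANOVA
calibration on 500 null datasets of 16 samples × 999 permutations; NMDS
recovery of an exact planar 20-point configuration to stress < 0.01; MCL
recovery of a 21-gene, 3-genome planted pangenome to adjusted Rand index
1.0; and module completeness against direct counting over every KO subset
for modules up to 6 steps. Key numeric guards: per-sample proportion sums
to within 1e-9; NMDS stress recomputation to 1e-8; MCL pruning at 1e-8;
symmetric-matrix tolerance 1e-8.

# Known limitations

- The core definition is binary presence/absence above a threshold;
  abundance-weighted or phylogenetic core definitions are not offered.
- PERMANOVA is single-factor and unrestricted; no strata, no pairwise
  post-hoc tests, no dispersion (PERMDISP) companion.
- The dense-matrix MCL implementation targets isolate-scale pangenomes
  (thousands of genes); metagenome-scale graphs would need a sparse
  implementation.
- KEGG modules are flat steps-with-alternatives; deeply nested module
  definitions must be flattened by the user.
- The simulator's independence assumptions (Bernoulli occupancy,
  independent background draws) understate the correlation structure of
  real communities.
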