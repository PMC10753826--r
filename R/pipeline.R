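#' Default pipeline configuration
#'
#' Runs the full synthetic demo: simulate a community and a pangenome,
#' preprocess, compute per-structure core grids and layers, ordinate and
#' test groups, and run the comparative-genomics stage.
#'
#' @param out_dir output directory.
#' @param seed master seed; stage seeds derive from it.
#' @return nested configuration list of class `pipeline_config`.
#' @export
default_pipeline_config <- function(out_dir = tempfile("morelbiome_run_"),
                                    seed = 1) {
  structure(list(
    out_dir = out_dir,
    seed = as.integer(seed),
    stages = list(core = TRUE, ordination = TRUE, pangenome = TRUE),
    simulate = TRUE,
    community = list(),     # overrides for community_sim_config()
    pangenome_sim = list(), # overrides for pangenome_sim_config()
    inputs = list(asv_table = NULL, taxonomy = NULL, metadata = NULL,
                  bitscores = NULL, genome_map = NULL, annotations = NULL,
                  modules = NULL),
    preprocess = list(min_count = 1, genus_level = TRUE),
    core = list(p_grid = default_p_grid(), d_grid = default_d_grid(),
                mode = "diagonal"),
    ordination = list(k = 2, n_starts = 20, n_permutations = 999,
                      group_by = "sample_type"),
    pangenome = list(minbit_threshold = 0.5, inflation = 2,
                     completeness_threshold = 0.75, group = NULL)),
    class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Keys override [default_pipeline_config()]; unknown keys are rejected.
#' @param path `.yaml`/`.yml` or `.json` config file.
#' @param out_dir optional override of the output directory.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path, out_dir = NULL) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  cfg <- default_pipeline_config()
  unknown <- setdiff(names(raw), names(cfg))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  for (k in names(raw)) {
    cfg[[k]] <- if (is.list(cfg[[k]]) && is.list(raw[[k]]))
      utils::modifyList(cfg[[k]], raw[[k]]) else raw[[k]]
  }
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  structure(cfg, class = "pipeline_config")
}

validate_pipeline_config <- function(cfg) {
  if (!isTRUE(cfg$simulate)) {
    need <- c("asv_table", "taxonomy", "metadata")
    if (isTRUE(cfg$stages$pangenome))
      need <- c(need, "bitscores", "genome_map", "annotations", "modules")
    for (f in need) {
      p <- cfg$inputs[[f]]
      if (is.null(p))
        stop("config error: simulation disabled but inputs$", f, " missing")
      if (!file.exists(p))
        stop("config error: inputs$", f, " does not exist: ", p)
    }
  }
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1)
    stop("config error: seed must be a single integer")
  invisible(cfg)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes (optionally) simulation, preprocessing, per-structure core
#' delineation, ordination with PERMANOVA, and the pangenome stage, writing
#' per-stage artifacts plus a run manifest (config echo, seeds, package
#' version, md5 checksums of every written file) into the output directory.
#' A stage failure aborts with the failing stage named; artifacts written
#' by earlier stages are preserved.
#'
#' @param config a `pipeline_config` (see [default_pipeline_config()],
#'   [read_pipeline_config()]).
#' @return invisibly, a result bundle: the in-memory objects per stage plus
#'   `manifest`.
#' @export
run_pipeline <- function(config = default_pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  validate_pipeline_config(config)
  cfg <- config
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  out <- function(name) {
    p <- file.path(cfg$out_dir, name)
    files <<- c(files, p)
    p
  }
  bundle <- list(config = cfg)

  # --- inputs: simulate or read -------------------------------------------
  if (isTRUE(cfg$simulate)) {
    sim <- run_stage("generate", {
      ccfg <- do.call(community_sim_config,
                      utils::modifyList(list(seed = cfg$seed),
                                        cfg$community))
      generate_community(ccfg)
    })
    table <- sim$table; taxonomy <- sim$taxonomy; meta <- sim$metadata
    bundle$simulation <- sim
    run_stage("generate", {
      write_asv_table(table, out("asv_table.tsv"))
      write_taxonomy(taxonomy, out("taxonomy.tsv"))
      write_metadata(meta, out("metadata.tsv"))
    })
  } else {
    run_stage("read_inputs", {
      table <- read_asv_table(cfg$inputs$asv_table)
      taxonomy <- read_taxonomy(cfg$inputs$taxonomy)
      meta <- read_metadata(cfg$inputs$metadata)
    })
  }

  # --- preprocess ----------------------------------------------------------
  rel <- run_stage("preprocess", {
    r <- preprocess_asv_table(table, taxonomy, meta,
                              min_count = cfg$preprocess$min_count,
                              genus_level = cfg$preprocess$genus_level)
    utils::write.table(
      data.frame(taxon = rownames(r), unclass(r), check.names = FALSE),
      out("relative_abundance.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    r
  })
  bundle$rel_abundance <- rel
  real_meta <- meta[meta$sample_type != "control", , drop = FALSE]
  real_meta <- real_meta[real_meta$sample_id %in% colnames(rel), ,
                         drop = FALSE]

  # --- core community per structure type ----------------------------------
  if (isTRUE(cfg$stages$core)) {
    bundle$core <- run_stage("core", {
      res <- list()
      for (t in intersect(unique(real_meta$sample_type),
                          setdiff(SAMPLE_TYPES, "control"))) {
        ids <- real_meta$sample_id[real_meta$sample_type == t]
        if (length(ids) < 1) next
        rel_t <- rel_abundance(unclass(rel)[, ids, drop = FALSE],
                               check = FALSE)
        grid <- compute_core_grid(rel_t, cfg$core$p_grid, cfg$core$d_grid)
        layers <- build_core_layers(grid, mode = cfg$core$mode)
        write_core_grid(grid, out(paste0("core_grid_", t, ".tsv")))
        export_core_sets(layers, out(paste0("core_layers_", t, ".json")))
        inner <- innermost_core(grid)
        res[[t]] <- list(grid = grid, layers = layers, innermost = inner)
      }
      summary <- lapply(res, function(x)
        list(p = x$innermost$core$p, d = x$innermost$core$d,
             members = as.list(x$innermost$core$members),
             max_prevalence = x$innermost$max_prevalence))
      jsonlite::write_json(summary, out("core_summary.json"),
                           auto_unbox = TRUE, digits = NA, na = "null")
      res
    })
  }

  # --- ordination + group validation --------------------------------------
  if (isTRUE(cfg$stages$ordination)) {
    bundle$ordination <- run_stage("ordination", {
      d <- bray_curtis(rel)
      ord <- nmds(d, k = cfg$ordination$k,
                  n_starts = cfg$ordination$n_starts,
                  seed = cfg$seed + 1L)
      groups <- stats::setNames(real_meta[[cfg$ordination$group_by]],
                                real_meta$sample_id)
      perm <- permanova(d, groups,
                        n_permutations = cfg$ordination$n_permutations,
                        seed = cfg$seed + 2L)
      utils::write.table(
        data.frame(sample_id = rownames(ord$coordinates),
                   ord$coordinates, check.names = FALSE),
        out("nmds_coordinates.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
      jsonlite::write_json(
        list(distance = "bray_curtis",
             level = if (isTRUE(cfg$preprocess$genus_level)) "genus"
                     else "asv",
             stress = ord$stress, converged = ord$converged,
             group_by = cfg$ordination$group_by,
             pseudo_F = perm$pseudo_F, p_value = perm$p_value,
             n_permutations = perm$n_permutations),
        out("ordination_summary.json"), auto_unbox = TRUE, digits = NA)
      list(distance = d, nmds = ord, permanova = perm)
    })
  }

  # --- pangenome -----------------------------------------------------------
  if (isTRUE(cfg$stages$pangenome)) {
    bundle$pangenome <- run_stage("pangenome", {
      if (isTRUE(cfg$simulate)) {
        pcfg <- do.call(pangenome_sim_config,
                        utils::modifyList(list(seed = cfg$seed + 3L),
                                          cfg$pangenome_sim))
        pg <- generate_pangenome(pcfg)
        write_bitscores(pg$bitscores, out("bitscores.tsv"))
        write_genome_map(pg$genome_map, out("genome_map.tsv"))
        write_annotations(pg$annotations, out("annotations.tsv"))
        write_kegg_modules(pg$modules, out("kegg_modules.txt"))
        bitscores <- pg$bitscores; genome_map <- pg$genome_map
        annotations <- pg$annotations; modules <- pg$modules
      } else {
        bitscores <- read_bitscores(cfg$inputs$bitscores)
        genome_map <- read_genome_map(cfg$inputs$genome_map)
        annotations <- read_annotations(cfg$inputs$annotations)
        modules <- read_kegg_modules(cfg$inputs$modules)
      }
      graph <- build_similarity_graph(
        bitscores, threshold = cfg$pangenome$minbit_threshold)
      clusters <- mcl_cluster(graph, inflation = cfg$pangenome$inflation)
      bins <- partition_clusters(clusters, genome_map,
                                 group = cfg$pangenome$group)
      metab <- estimate_metabolism(
        modules, annotations, genome_map,
        threshold = cfg$pangenome$completeness_threshold)
      cats <- count_annotation_categories(annotations, genome_map)
      jsonlite::write_json(
        list(n_clusters = length(clusters$clusters),
             core = as.list(bins$core),
             unique = lapply(bins$unique, as.list),
             group_core = as.list(bins$group_core %||% character(0)),
             accessory = as.list(bins$accessory)),
        out("gene_cluster_bins.json"), auto_unbox = TRUE)
      utils::write.table(metab, out("module_completeness.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      utils::write.table(
        data.frame(genome_id = rownames(cats$counts), cats$counts,
                   total = cats$totals, check.names = FALSE),
        out("annotation_categories.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
      list(graph = graph, clusters = clusters, bins = bins,
           completeness = metab, categories = cats)
    })
  }

  # --- manifest ------------------------------------------------------------
  manifest_path <- file.path(cfg$out_dir, "manifest.json")
  checksums <- tools::md5sum(files)
  names(checksums) <- basename(names(checksums))
  manifest <- list(
    package = "morelbiome",
    version = as.character(utils::packageVersion("morelbiome")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = cfg$seed,
    config = unclass(cfg),
    checksums = as.list(checksums))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  bundle$manifest <- manifest
  invisible(bundle)
}
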