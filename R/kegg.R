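#' Construct a KEGG-module definition
#'
#' A module is an ordered list of enzymatic steps; each step is satisfiable
#' by any one of a set of alternative KEGG Orthologs (KOs). This simplified
#' representation covers threshold-based completeness estimation; the full
#' KEGG boolean definition grammar (nested AND/OR, optional steps) is out of
#' scope.
#'
#' @param module_id module identifier (e.g. `"M00001"`).
#' @param steps list of character vectors, each the alternative KOs of one
#'   step; at least one step, each non-empty.
#' @return object of class `kegg_module`.
#' @export
kegg_module <- function(module_id, steps) {
  if (!length(steps)) stop("module ", module_id, " has no steps")
  steps <- lapply(steps, function(s) {
    s <- as.character(s)
    if (!length(s) || any(!nzchar(s)))
      stop("module ", module_id, " has an empty step")
    unique(s)
  })
  structure(list(module_id = as.character(module_id), steps = steps),
            class = "kegg_module")
}

#' Read KEGG-module step definitions from plain text
#'
#' One module per line: `MODULE_ID<TAB>step1_alt1,step1_alt2;step2;...` —
#' steps separated by `;`, alternative KOs within a step by `,`. `#` lines
#' are ignored.
#'
#' @param path file path.
#' @return named list of [kegg_module()] objects.
#' @export
read_kegg_modules <- function(path) {
  lines <- read_tsv_lines(path)
  mods <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 2) stop("malformed module line: ", l)
    steps <- strsplit(strsplit(f[2], ";", fixed = TRUE)[[1]], ",",
                      fixed = TRUE)
    kegg_module(f[1], steps)
  })
  stats::setNames(mods, vapply(mods, `[[`, character(1), "module_id"))
}

#' Write KEGG-module definitions to plain text
#' @param modules list of [kegg_module()] objects.
#' @param path output path.
#' @export
write_kegg_modules <- function(modules, path) {
  lines <- vapply(modules, function(m)
    paste0(m$module_id, "\t",
           paste(vapply(m$steps, paste, character(1), collapse = ","),
                 collapse = ";")), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' KEGG-module completeness for one set of KOs
#'
#' A step is satisfied when any of its alternative KOs is present;
#' completeness is the fraction of satisfied steps, and the module counts as
#' complete when that fraction reaches `threshold` (default 0.75, i.e. 75%
#' of the required steps present in a genome).
#'
#' @param module a [kegg_module()].
#' @param kos_present character vector of KO identifiers present in the
#'   genome.
#' @param threshold completeness threshold (default 0.75).
#' @param genome_id optional label carried into the result.
#' @return object of class `completeness_result`: `module_id`, `genome_id`,
#'   `completeness`, `complete`, `satisfied_steps`, `total_steps`.
#' @export
module_completeness <- function(module, kos_present, threshold = 0.75,
                                genome_id = NA_character_) {
  stopifnot(inherits(module, "kegg_module"))
  satisfied <- vapply(module$steps, function(s)
    any(s %in% kos_present), logical(1))
  c_val <- sum(satisfied) / length(satisfied)
  structure(list(module_id = module$module_id,
                 genome_id = genome_id,
                 completeness = c_val,
                 complete = c_val >= threshold,
                 satisfied_steps = sum(satisfied),
                 total_steps = length(satisfied),
                 threshold = threshold),
            class = "completeness_result")
}

#' Read a gene annotation table from TSV
#'
#' Columns: `gene_id` plus any of `ko`, `category` (header required; extra
#' columns kept). Empty strings are treated as missing annotations.
#'
#' @param path file path.
#' @return data.frame with at least `gene_id`.
#' @export
read_annotations <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, comment.char = "#",
                          quote = "")
  if (!"gene_id" %in% names(df))
    stop("annotation table missing gene_id column")
  df
}

#' Module completeness across genomes
#'
#' Convenience wrapper: collects each genome's KO set from an annotation
#' table and scores every module.
#'
#' @param modules named list of [kegg_module()] objects.
#' @param annotations data.frame with `gene_id` and `ko` columns.
#' @param genome_map named vector, gene id -> genome id.
#' @param threshold completeness threshold (default 0.75).
#' @return data.frame with one row per (module, genome): `module_id`,
#'   `genome_id`, `completeness`, `complete`.
#' @export
estimate_metabolism <- function(modules, annotations, genome_map,
                                threshold = 0.75) {
  stopifnot("gene_id" %in% names(annotations), "ko" %in% names(annotations))
  ann <- annotations[!is.na(annotations$ko) & nzchar(annotations$ko), ]
  genome <- genome_map[ann$gene_id]
  kos_by_genome <- split(ann$ko, genome)
  genomes <- sort(unique(unname(genome_map)))
  rows <- list()
  for (m in modules)
    for (g in genomes) {
      res <- module_completeness(m, kos_by_genome[[g]] %||% character(0),
                                 threshold = threshold, genome_id = g)
      rows[[length(rows) + 1L]] <- data.frame(
        module_id = res$module_id, genome_id = g,
        completeness = res$completeness, complete = res$complete,
        stringsAsFactors = FALSE)
    }
  do.call(rbind, rows)
}

#' Per-genome annotation category counts
#'
#' Tallies, per genome, how many genes carry each annotation category (e.g.
#' carbohydrate-active enzyme families). An optional `category_map` renames
#' raw labels to display categories before counting.
#'
#' @param annotations data.frame with `gene_id` and `category` columns.
#' @param genome_map named vector, gene id -> genome id.
#' @param category_map optional named vector, raw label -> category.
#' @return list with `counts` (genomes x categories integer matrix) and
#'   `totals` (named per-genome totals).
#' @export
count_annotation_categories <- function(annotations, genome_map,
                                        category_map = NULL) {
  stopifnot("gene_id" %in% names(annotations))
  genomes <- sort(unique(unname(genome_map)))
  cat_col <- annotations$category %||% character(0)
  ann <- annotations[!is.na(cat_col) & nzchar(cat_col), , drop = FALSE]
  if (!nrow(ann)) {
    counts <- matrix(0L, nrow = length(genomes), ncol = 0,
                     dimnames = list(genomes, NULL))
    return(list(counts = counts,
                totals = stats::setNames(integer(length(genomes)), genomes)))
  }
  category <- as.character(ann$category)
  if (!is.null(category_map)) {
    mapped <- category_map[category]
    category <- ifelse(is.na(mapped), category, mapped)
  }
  genome <- genome_map[ann$gene_id]
  tab <- table(factor(genome, levels = genomes), category)
  counts <- matrix(as.integer(tab), nrow = length(genomes),
                   dimnames = list(genomes, colnames(tab)))
  list(counts = counts, totals = rowSums(counts))
}
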