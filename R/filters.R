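#' Remove ASVs detected in no-template control samples
#'
#' Every feature with at least `min_count` reads in *any* control sample is
#' excluded from the table, after which the control samples themselves are
#' dropped. This is presence-based decontamination: a single read in a
#' negative control is enough to flag a feature, which is deliberately
#' conservative for low-biomass fungal-structure samples where reagent
#' contaminants can dominate.
#'
#' @param table an [asv_table()].
#' @param meta a [sample_metadata()] covering every sample in `table`;
#'   controls are the rows with `sample_type == "control"`.
#' @param min_count minimum control count that flags a feature (default 1).
#' @return an [asv_table()] without flagged features or control columns.
#'   With zero control samples the feature set is unchanged.
#' @export
remove_control_contaminants <- function(table, meta, min_count = 1L) {
  stopifnot(inherits(table, "asv_table"))
  meta <- align_metadata(table, meta)
  is_control <- meta$sample_type == "control"
  if (!any(is_control)) return(table)
  ctrl <- unclass(table)[, is_control, drop = FALSE]
  contaminated <- rowSums(ctrl >= min_count) > 0
  kept <- unclass(table)[!contaminated, !is_control, drop = FALSE]
  asv_table(kept)
}

#' Keep only features assigned to the Bacteria kingdom
#'
#' Features whose kingdom rank is anything other than `Bacteria` — including
#' unassigned kingdoms and features absent from the taxonomy — are discarded.
#'
#' @param table an [asv_table()].
#' @param taxonomy a [taxonomy_table()]; features missing from it are treated
#'   as unassigned.
#' @return filtered [asv_table()].
#' @export
filter_nonbacterial <- function(table, taxonomy) {
  stopifnot(inherits(table, "asv_table"))
  kingdom <- rep(UNASSIGNED, nrow(table))
  hit <- match(rownames(table), taxonomy$feature_id)
  kingdom[!is.na(hit)] <- taxonomy$kingdom[hit[!is.na(hit)]]
  asv_table(unclass(table)[kingdom == "Bacteria", , drop = FALSE])
}

#' Total-sum scaling (TSS) normalisation
#'
#' Divides each sample's counts by its total, yielding per-sample proportions
#' that sum to one.
#'
#' @param table an [asv_table()]; every sample must have total count >= 1.
#' @return a [rel_abundance()] table.
#' @export
tss_normalize <- function(table) {
  stopifnot(inherits(table, "asv_table"))
  totals <- colSums(table)
  if (any(totals == 0))
    stop("sample ", colnames(table)[which(totals == 0)[1]],
         " has zero total count; cannot TSS-normalize")
  rel_abundance(sweep(unclass(table), 2, totals, "/"))
}

#' Default placeholder genus tokens
#'
#' Genus strings that carry no taxonomic information (environmental-sequence
#' placeholders in SILVA-style taxonomies) and are merged into the single
#' `unassigned` row by [agglomerate_genus()]. Matching is case-insensitive
#' on the whole token or a leading word (e.g. `"uncultured bacterium"`).
#' @export
PLACEHOLDER_GENERA <- c("unassigned", "uncultured", "metagenome",
                        "uncultured bacterium", "uncultured organism",
                        "unidentified", "gut metagenome", "ambiguous_taxa")

is_placeholder_genus <- function(genus, placeholders) {
  g <- tolower(trimws(genus))
  first <- sub("[ _].*$", "", g)
  g %in% tolower(placeholders) | first %in% tolower(placeholders)
}

#' Agglomerate relative abundances at the genus rank
#'
#' Features sharing an assigned genus are summed into a single row keyed by
#' the genus name; features whose genus is unassigned or a non-informative
#' placeholder (see [PLACEHOLDER_GENERA]) are pooled into one `unassigned`
#' row. Per-sample sums are preserved exactly (proportions add).
#'
#' @param rel a [rel_abundance()] table with ASV-level rows.
#' @param taxonomy a [taxonomy_table()]; features missing from it count as
#'   unassigned.
#' @param placeholders character vector of genus tokens to treat as
#'   unassigned.
#' @return a genus-level [rel_abundance()] table.
#' @export
agglomerate_genus <- function(rel, taxonomy,
                              placeholders = PLACEHOLDER_GENERA) {
  stopifnot(inherits(rel, "rel_abundance"))
  genus <- rep(UNASSIGNED, nrow(rel))
  hit <- match(rownames(rel), taxonomy$feature_id)
  genus[!is.na(hit)] <- taxonomy$genus[hit[!is.na(hit)]]
  genus[is_placeholder_genus(genus, placeholders)] <- UNASSIGNED
  m <- rowsum(unclass(rel), group = genus, reorder = FALSE)
  # stable, abundance-independent ordering: assigned genera alphabetically,
  # unassigned last
  ord <- order(rownames(m) == UNASSIGNED, rownames(m))
  rel_abundance(m[ord, , drop = FALSE], check = FALSE)
}

#' Standard preprocessing chain
#'
#' Applies, in order: control-contaminant removal, non-bacterial filtering,
#' TSS normalisation, genus agglomeration. Filtering precedes normalisation
#' so proportions are computed on the cleaned table.
#'
#' @inheritParams remove_control_contaminants
#' @inheritParams filter_nonbacterial
#' @param placeholders passed to [agglomerate_genus()].
#' @param genus_level if `FALSE`, skip genus agglomeration and return the
#'   ASV-level relative-abundance table.
#' @return a [rel_abundance()] table (genus- or ASV-level).
#' @export
preprocess_asv_table <- function(table, taxonomy, meta, min_count = 1L,
                                 placeholders = PLACEHOLDER_GENERA,
                                 genus_level = TRUE) {
  table <- remove_control_contaminants(table, meta, min_count = min_count)
  table <- filter_nonbacterial(table, taxonomy)
  rel <- tss_normalize(table)
  if (genus_level) rel <- agglomerate_genus(rel, taxonomy, placeholders)
  rel
}
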