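# Canonical rank names for 7-rank SILVA-style lineages.
TAXONOMY_RANKS <- c("kingdom", "phylum", "class", "order", "family", "genus",
                    "species")

#' Token used for missing taxonomic assignments
#'
#' Any empty or absent rank in a lineage string is stored as this token, so
#' downstream code can test assignment with a simple equality check.
#' @export
UNASSIGNED <- "unassigned"

SAMPLE_TYPES <- c("mycelium", "sclerotia", "fruiting_body", "control")
CLADES <- c("Elata", "Esculenta", "Rufobrunnea", "unknown")

#' Construct an ASV count table
#'
#' An ASV (amplicon sequence variant) count table is a non-negative integer
#' matrix with features (ASVs or genera) as rows and samples as columns. This
#' is the raw input of the pipeline; denoising and taxonomic classification
#' happen upstream.
#'
#' @param counts integer matrix, features x samples, with unique non-empty
#'   rownames (feature ids) and colnames (sample ids).
#' @return an object of class `asv_table` (an integer matrix).
#' @export
asv_table <- function(counts) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("asv_table requires feature ids (rownames) and sample ids (colnames)")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate feature id: ",
         rownames(counts)[duplicated(rownames(counts))][1])
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample id: ",
         colnames(counts)[duplicated(colnames(counts))][1])
  if (any(is.na(counts)))
    stop("counts contain missing values")
  if (any(counts < 0))
    stop("counts must be non-negative")
  if (any(counts != round(counts)))
    stop("counts must be integers")
  storage.mode(counts) <- "integer"
  class(counts) <- c("asv_table", class(counts))
  counts
}

#' Construct a relative-abundance table
#'
#' Same shape as an [asv_table()] but holding per-sample proportions that sum
#' to one (total-sum scaling).
#'
#' @param values numeric matrix of proportions, features x samples.
#' @param check if `TRUE`, verify that each sample sums to 1 within 1e-9.
#' @return an object of class `rel_abundance` (a numeric matrix).
#' @export
rel_abundance <- function(values, check = TRUE) {
  values <- as.matrix(values)
  if (nrow(values) > 0 && ncol(values) > 0 &&
      (is.null(rownames(values)) || is.null(colnames(values))))
    stop("rel_abundance requires feature ids and sample ids")
  if (any(values < 0) || any(values > 1 + 1e-9))
    stop("relative abundances must lie in [0, 1]")
  if (check && ncol(values) > 0) {
    sums <- colSums(values)
    bad <- which(abs(sums - 1) > 1e-9)
    if (length(bad))
      stop("sample ", colnames(values)[bad[1]], " does not sum to 1 (",
           format(sums[bad[1]]), ")")
  }
  storage.mode(values) <- "double"
  class(values) <- c("rel_abundance", class(values))
  values
}

#' Construct a taxonomy table
#'
#' @param feature_id character vector of feature ids.
#' @param ranks character matrix or data.frame with the 7 canonical rank
#'   columns (kingdom, phylum, class, order, family, genus, species); empty
#'   strings/NA are replaced by the [UNASSIGNED] token.
#' @return data.frame of class `taxonomy_table` with `feature_id` plus the
#'   7 rank columns.
#' @export
taxonomy_table <- function(feature_id, ranks) {
  ranks <- as.data.frame(ranks, stringsAsFactors = FALSE)
  if (ncol(ranks) != 7)
    stop("taxonomy requires exactly 7 rank columns, got ", ncol(ranks))
  names(ranks) <- TAXONOMY_RANKS
  if (anyDuplicated(feature_id))
    stop("duplicate feature id: ", feature_id[duplicated(feature_id)][1])
  for (r in TAXONOMY_RANKS) {
    v <- as.character(ranks[[r]])
    v[is.na(v) | !nzchar(trimws(v))] <- UNASSIGNED
    ranks[[r]] <- trimws(v)
  }
  out <- cbind(data.frame(feature_id = as.character(feature_id),
                          stringsAsFactors = FALSE), ranks)
  rownames(out) <- out$feature_id
  class(out) <- c("taxonomy_table", "data.frame")
  out
}

#' Construct a sample metadata table
#'
#' @param sample_id character vector of sample ids.
#' @param sample_type one of mycelium, sclerotia, fruiting_body, control.
#' @param clade one of Elata, Esculenta, Rufobrunnea, unknown.
#' @param specimen_id optional biological specimen identifier.
#' @return data.frame of class `sample_metadata`.
#' @export
sample_metadata <- function(sample_id, sample_type,
                            clade = "unknown", specimen_id = sample_id) {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id))
    stop("duplicate sample id: ", sample_id[duplicated(sample_id)][1])
  sample_type <- as.character(sample_type)
  bad <- setdiff(unique(sample_type), SAMPLE_TYPES)
  if (length(bad))
    stop("unknown sample_type: ", bad[1])
  clade <- rep_len(as.character(clade), length(sample_id))
  badc <- setdiff(unique(clade), CLADES)
  if (length(badc))
    stop("unknown clade: ", badc[1])
  out <- data.frame(sample_id = sample_id,
                    sample_type = rep_len(sample_type, length(sample_id)),
                    clade = clade,
                    specimen_id = rep_len(as.character(specimen_id),
                                          length(sample_id)),
                    stringsAsFactors = FALSE)
  rownames(out) <- out$sample_id
  class(out) <- c("sample_metadata", "data.frame")
  out
}

# Check that metadata covers every sample of a table; returns metadata
# subset aligned to the table's samples.
align_metadata <- function(table, meta) {
  missing <- setdiff(colnames(table), meta$sample_id)
  if (length(missing))
    stop("no metadata for sample(s): ", paste(missing, collapse = ", "))
  meta[colnames(table), , drop = FALSE]
}

read_tsv_lines <- function(path) {
  lines <- readLines(path)
  lines[!grepl("^#", lines) & nzchar(lines)]
}

#' Read an ASV count table from TSV
#'
#' Expects a header row of sample ids, first column of feature ids, and
#' tab-separated integer counts. Lines starting with `#` are ignored (the
#' BIOM-TSV dialect's comment/header convention).
#'
#' @param path file path.
#' @return an [asv_table()].
#' @export
read_asv_table <- function(path) {
  lines <- read_tsv_lines(path)
  if (length(lines) < 1) stop("empty ASV table: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  sample_ids <- header[-1]
  if (!length(sample_ids)) stop("ASV table has no sample columns: ", path)
  body <- fields[-1]
  n_col <- length(header)
  feature_ids <- character(length(body))
  counts <- matrix(0L, nrow = length(body), ncol = length(sample_ids))
  for (i in seq_along(body)) {
    f <- body[[i]]
    if (length(f) != n_col)
      stop("line ", i + 1L, ": expected ", n_col, " fields, got ", length(f))
    feature_ids[i] <- f[1]
    vals <- suppressWarnings(as.numeric(f[-1]))
    if (any(is.na(vals)) || any(vals != round(vals)))
      stop("line ", i + 1L, " (", f[1], "): non-integer count")
    counts[i, ] <- as.integer(vals)
  }
  dimnames(counts) <- list(feature_ids, sample_ids)
  asv_table(counts)
}

#' Write an ASV count table to TSV
#'
#' Round-trips bit-exactly through [read_asv_table()] for integer counts.
#' @param table an [asv_table()].
#' @param path output path.
#' @export
write_asv_table <- function(table, path) {
  df <- data.frame(feature_id = rownames(table),
                   unclass(table)[, , drop = FALSE],
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Strip SILVA/Greengenes-style rank prefixes: "D_0__Bacteria", "k__Bacteria".
strip_rank_prefix <- function(x) {
  sub("^(D_[0-9]+__|[a-zA-Z]__)", "", x)
}

#' Parse a semicolon-separated lineage string into 7 ranks
#'
#' SILVA-style prefixes (`D_0__`, `k__`, ...) are stripped; missing trailing
#' ranks and empty fields become the [UNASSIGNED] token.
#'
#' @param lineage character vector of lineage strings.
#' @return character matrix with 7 columns.
#' @export
parse_lineage <- function(lineage) {
  parts <- strsplit(as.character(lineage), ";", fixed = TRUE)
  out <- t(vapply(parts, function(p) {
    p <- strip_rank_prefix(trimws(p))
    p <- p[seq_len(min(length(p), 7))]
    c(p, rep("", 7 - length(p)))
  }, character(7)))
  out[!nzchar(out)] <- UNASSIGNED
  colnames(out) <- TAXONOMY_RANKS
  out
}

#' Read a taxonomy table from TSV
#'
#' Two columns: feature id and semicolon-separated lineage (SILVA-style
#' prefixes accepted). A header row is detected and skipped when its second
#' field does not parse as a lineage with an assigned kingdom-level token
#' matching a data row pattern; explicitly, a first line whose first field is
#' `feature_id` (case-insensitive) or starts with `#` is treated as a header.
#'
#' @param path file path.
#' @return a [taxonomy_table()].
#' @export
read_taxonomy <- function(path) {
  lines <- read_tsv_lines(path)
  if (!length(lines)) stop("empty taxonomy file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (tolower(fields[[1]][1]) %in% c("feature_id", "feature id", "otu id"))
    fields <- fields[-1]
  ids <- vapply(fields, `[`, character(1), 1)
  lin <- vapply(fields, function(f) {
    if (length(f) < 2) "" else f[2]
  }, character(1))
  taxonomy_table(ids, parse_lineage(lin))
}

#' Write a taxonomy table to TSV
#' @param taxonomy a [taxonomy_table()].
#' @param path output path.
#' @export
write_taxonomy <- function(taxonomy, path) {
  lineage <- apply(as.matrix(taxonomy[TAXONOMY_RANKS]), 1, paste,
                   collapse = ";")
  utils::write.table(
    data.frame(feature_id = taxonomy$feature_id, taxonomy = lineage),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata from TSV
#'
#' Columns: `sample_id`, `sample_type`, and optionally `clade`,
#' `specimen_id`.
#' @param path file path.
#' @return a [sample_metadata()].
#' @export
read_metadata <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, comment.char = "#")
  need <- c("sample_id", "sample_type")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("metadata missing column(s): ", paste(missing, collapse = ", "))
  sample_metadata(df$sample_id, df$sample_type,
                  clade = if ("clade" %in% names(df)) df$clade else "unknown",
                  specimen_id = if ("specimen_id" %in% names(df))
                    df$specimen_id else df$sample_id)
}

#' Write sample metadata to TSV
#' @param meta a [sample_metadata()].
#' @param path output path.
#' @export
write_metadata <- function(meta, path) {
  utils::write.table(as.data.frame(meta), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
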