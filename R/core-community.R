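#' Default prevalence grid (fractions)
#'
#' Prevalence (occupancy) thresholds from 30% to 100% in steps of 5%.
#' @export
default_p_grid <- function() seq(0.30, 1.00, by = 0.05)

#' Default detection grid (fractions)
#'
#' Relative-abundance detection thresholds of 0.05, 0.10, 0.15, 0.20, 0.30,
#' 0.40, 0.50, 0.75, 1.00, 2.00, 5.00 and 10.00 percent, expressed as
#' fractions.
#' @export
default_d_grid <- function()
  c(0.05, 0.10, 0.15, 0.20, 0.30, 0.40, 0.50, 0.75, 1, 2, 5, 10) / 100

#' Core-community membership at one threshold pair
#'
#' A taxon belongs to the core at prevalence threshold `p` and detection
#' threshold `d` when its occupancy — the fraction of samples in which its
#' relative abundance exceeds `d` — is at least `p`. By default the detection
#' comparison is strict (`>`, "abundance above which a taxon is considered
#' present") and the prevalence comparison inclusive (`>=`); both are
#' configurable because core definitions differ between implementations.
#'
#' @param rel a [rel_abundance()] table (taxa x samples).
#' @param p prevalence threshold, fraction in \[0, 1\].
#' @param d detection threshold, relative-abundance fraction in \[0, 1\].
#' @param strict_detection use `>` (default) rather than `>=` on `d`.
#' @param inclusive_prevalence use `>=` (default) rather than `>` on `p`.
#' @return an object of class `core_set`: list with `p`, `d`, `members`
#'   (character vector of taxon ids) and `occupancy` (named fractions for
#'   the members).
#' @export
core_membership <- function(rel, p, d, strict_detection = TRUE,
                            inclusive_prevalence = TRUE) {
  stopifnot(inherits(rel, "rel_abundance"),
            length(p) == 1, length(d) == 1,
            p >= 0, p <= 1, d >= 0, d <= 1)
  if (nrow(rel) == 0 || ncol(rel) == 0)
    return(structure(list(p = p, d = d, members = character(0),
                          occupancy = numeric(0)), class = "core_set"))
  present <- if (strict_detection) unclass(rel) > d else unclass(rel) >= d
  occ <- rowMeans(present)
  keep <- if (inclusive_prevalence) occ >= p else occ > p
  structure(list(p = p, d = d,
                 members = rownames(rel)[keep],
                 occupancy = occ[keep]),
            class = "core_set")
}

#' @export
print.core_set <- function(x, ...) {
  cat(sprintf("core set (prevalence >= %.3g, detection > %.4g): %d taxa\n",
              x$p, x$d, length(x$members)))
  if (length(x$members))
    cat(" ", paste(sprintf("%s (%.2f)", x$members, x$occupancy),
                   collapse = ", "), "\n")
  invisible(x)
}

#' Core communities over a prevalence x detection threshold grid
#'
#' Computes [core_membership()] for every combination of the prevalence and
#' detection grids. The defaults reproduce the conventional 15 x 12 grid
#' (prevalence 30--100% step 5%; twelve detection values from 0.05% to 10%).
#'
#' @inheritParams core_membership
#' @param p_grid strictly increasing prevalence thresholds (fractions).
#' @param d_grid strictly increasing detection thresholds (fractions).
#' @return an object of class `core_grid`: list with `p_grid`, `d_grid`,
#'   an `occupancy` matrix (taxa x detection thresholds), and `cells`, a
#'   list-matrix of `core_set`s indexed `[p, d]`.
#' @export
compute_core_grid <- function(rel, p_grid = default_p_grid(),
                              d_grid = default_d_grid(),
                              strict_detection = TRUE,
                              inclusive_prevalence = TRUE) {
  stopifnot(inherits(rel, "rel_abundance"))
  if (length(p_grid) < 1 || any(diff(p_grid) <= 0))
    stop("p_grid must be strictly increasing")
  if (length(d_grid) < 1 || any(diff(d_grid) <= 0))
    stop("d_grid must be strictly increasing")
  if (any(p_grid < 0 | p_grid > 1) || any(d_grid < 0 | d_grid > 1))
    stop("thresholds must be fractions in [0, 1]")
  taxa <- rownames(rel)
  m <- unclass(rel)
  # occupancy per taxon per detection threshold, shared by all prevalence rows
  occ <- matrix(NA_real_, nrow(m), length(d_grid),
                dimnames = list(taxa, format(d_grid)))
  if (nrow(m) > 0 && ncol(m) > 0)
    for (j in seq_along(d_grid))
      occ[, j] <- if (strict_detection) rowMeans(m > d_grid[j])
                  else rowMeans(m >= d_grid[j])
  cells <- vector("list", length(p_grid) * length(d_grid))
  dim(cells) <- c(length(p_grid), length(d_grid))
  dimnames(cells) <- list(format(p_grid), format(d_grid))
  for (j in seq_along(d_grid)) {
    oj <- occ[, j]
    for (i in seq_along(p_grid)) {
      keep <- if (inclusive_prevalence) oj >= p_grid[i] else oj > p_grid[i]
      cells[[i, j]] <- structure(
        list(p = p_grid[i], d = d_grid[j],
             members = taxa[keep], occupancy = oj[keep]),
        class = "core_set")
    }
  }
  structure(list(p_grid = p_grid, d_grid = d_grid, occupancy = occ,
                 cells = cells),
            class = "core_grid")
}

#' @export
print.core_grid <- function(x, ...) {
  sizes <- apply(x$cells, c(1, 2), function(s) length(s[[1]]$members))
  cat(sprintf("core grid: %d prevalence x %d detection thresholds\n",
              length(x$p_grid), length(x$d_grid)))
  print(sizes)
  invisible(x)
}

#' Linearise a core grid into nested core layers
#'
#' The 2-D threshold grid is collapsed into a chain of nested core sets
#' ("layers"), innermost (most stringent, fewest taxa) first — the structure
#' drawn as an inclusive Venn diagram, in which inner layers hold the most
#' ubiquitous taxa and outer layers increasingly marginal ones.
#'
#' Two linearisations are offered. `"diagonal"` (default) pairs the k-th
#' largest prevalence with the k-th largest detection threshold, mapping the
#' shorter grid proportionally onto the longer, so both thresholds relax
#' together and nesting is guaranteed by monotonicity. `"union-rank"` scores
#' each cell by its strictness rank (the number of grid cells whose
#' thresholds are both >= the cell's own) and takes layer k as the union of
#' all cells with rank >= k. Consecutive identical layers are collapsed in
#' both modes.
#'
#' @param grid a `core_grid` from [compute_core_grid()].
#' @param mode `"diagonal"` or `"union-rank"`.
#' @return an object of class `core_layers`: list with `mode` and `layers`,
#'   each layer a list with `rank` (1 = innermost), `p`, `d` (thresholds of
#'   the defining cell; `NA` for union-rank layers, which pool cells),
#'   `members` and `occupancy`.
#' @export
build_core_layers <- function(grid, mode = c("diagonal", "union-rank")) {
  stopifnot(inherits(grid, "core_grid"))
  mode <- match.arg(mode)
  np <- length(grid$p_grid); nd <- length(grid$d_grid)
  if (mode == "diagonal") {
    n_layers <- max(np, nd)
    # k = 1 is strictest: largest p paired with largest d
    map_idx <- function(k, n_from, n_to) {
      if (n_from == 1) return(1L)
      as.integer(round((k - 1) * (n_to - 1) / (n_from - 1))) + 1L
    }
    layers <- lapply(seq_len(n_layers), function(k) {
      ip <- if (np >= nd) np - k + 1L else np - map_idx(k, n_layers, np) + 1L
      id <- if (nd >= np) nd - k + 1L else nd - map_idx(k, n_layers, nd) + 1L
      cell <- grid$cells[[ip, id]]
      list(rank = k, p = cell$p, d = cell$d,
           members = cell$members, occupancy = cell$occupancy)
    })
  } else {
    # strictness rank of cell (i, j): the number of grid cells it dominates
    # (both thresholds <= the cell's own), i * j — the strictest cell has the
    # highest rank. Layer k pools every cell with rank >= the k-th highest
    # rank value; the pooled family grows as the rank cutoff drops, so the
    # unions form a nested chain from innermost outwards.
    rank_of <- outer(seq_len(np), seq_len(nd))
    cutoffs <- sort(unique(as.vector(rank_of)), decreasing = TRUE)
    layers <- lapply(seq_along(cutoffs), function(k) {
      sel <- which(rank_of >= cutoffs[k], arr.ind = TRUE)
      occ <- numeric(0)
      for (r in seq_len(nrow(sel))) {
        cell <- grid$cells[[sel[r, 1], sel[r, 2]]]
        new <- setdiff(cell$members, names(occ))
        occ <- c(occ, cell$occupancy[new])
      }
      list(rank = k, p = NA_real_, d = NA_real_,
           members = names(occ), occupancy = occ)
    })
  }
  # collapse consecutive layers with identical member sets
  keep <- rep(TRUE, length(layers))
  for (k in seq_along(layers)[-1])
    if (setequal(layers[[k]]$members, layers[[k - 1]]$members))
      keep[k] <- FALSE
  layers <- layers[keep]
  layers <- lapply(seq_along(layers), function(k) {
    l <- layers[[k]]; l$rank <- k; l
  })
  structure(list(mode = mode, layers = layers), class = "core_layers")
}

#' @export
print.core_layers <- function(x, ...) {
  cat(sprintf("core layers (%s mode), innermost first:\n", x$mode))
  for (l in x$layers)
    cat(sprintf("  layer %d%s: %d taxa\n", l$rank,
                if (!is.na(l$p)) sprintf(" (p=%.2f, d=%.4g)", l$p, l$d)
                else "",
                length(l$members)))
  invisible(x)
}

#' Innermost non-empty core of a grid
#'
#' Returns the cell with lexicographically highest (prevalence, detection)
#' thresholds whose member set is non-empty — prevalence is compared first,
#' the leading parameter of the core definition — together with the maximum
#' per-taxon occupancy among its members. When every cell is empty the
#' result has no members and `max_prevalence` 0.
#'
#' @param grid a `core_grid`.
#' @return list with `core` (a `core_set`) and `max_prevalence`.
#' @export
innermost_core <- function(grid) {
  stopifnot(inherits(grid, "core_grid"))
  np <- length(grid$p_grid); nd <- length(grid$d_grid)
  for (i in rev(seq_len(np))) {
    for (j in rev(seq_len(nd))) {
      cell <- grid$cells[[i, j]]
      if (length(cell$members))
        return(list(core = cell, max_prevalence = max(cell$occupancy)))
    }
  }
  list(core = structure(list(p = NA_real_, d = NA_real_,
                             members = character(0), occupancy = numeric(0)),
                        class = "core_set"),
       max_prevalence = 0)
}

#' Export core layers as JSON
#'
#' Writes a machine-readable listing of the nested layers (mode, thresholds,
#' members, occupancies) suitable for external Venn-diagram rendering.
#' [read_core_sets()] round-trips it.
#'
#' @param layers a `core_layers` object.
#' @param path output path (`.json`).
#' @export
export_core_sets <- function(layers, path) {
  stopifnot(inherits(layers, "core_layers"))
  payload <- list(
    mode = layers$mode,
    layers = lapply(layers$layers, function(l)
      list(rank = l$rank, p = l$p, d = l$d,
           members = as.list(l$members),
           occupancy = as.list(unname(l$occupancy)))))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' Read core layers back from JSON
#' @param path file written by [export_core_sets()].
#' @return a `core_layers` object.
#' @export
read_core_sets <- function(path) {
  payload <- jsonlite::read_json(path)
  layers <- lapply(payload$layers, function(l) {
    members <- unlist(l$members) %||% character(0)
    occ <- as.numeric(unlist(l$occupancy) %||% numeric(0))
    names(occ) <- members
    list(rank = l$rank,
         p = if (is.null(l$p)) NA_real_ else as.numeric(l$p),
         d = if (is.null(l$d)) NA_real_ else as.numeric(l$d),
         members = as.character(members), occupancy = occ)
  })
  structure(list(mode = payload$mode, layers = layers),
            class = "core_layers")
}

#' Export the full core grid as TSV
#'
#' One row per (prevalence, detection, taxon) triple with the taxon's
#' occupancy at that detection threshold.
#' @param grid a `core_grid`.
#' @param path output path.
#' @export
write_core_grid <- function(grid, path) {
  stopifnot(inherits(grid, "core_grid"))
  rows <- list()
  for (i in seq_along(grid$p_grid))
    for (j in seq_along(grid$d_grid)) {
      cell <- grid$cells[[i, j]]
      if (length(cell$members))
        rows[[length(rows) + 1L]] <- data.frame(
          prevalence = cell$p, detection = cell$d,
          taxon = cell$members, occupancy = unname(cell$occupancy),
          stringsAsFactors = FALSE)
    }
  out <- if (length(rows)) do.call(rbind, rows)
  else data.frame(prevalence = numeric(0), detection = numeric(0),
                  taxon = character(0), occupancy = numeric(0))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
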