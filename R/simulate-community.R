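#' Default planted core structure for the synthetic study
#'
#' Emulates the qualitative structure of a morel-associated bacteriome
#' study: a dominant, high-occupancy Pseudomonas-like genus in mycelium and
#' sclerotia (plus a secondary Ralstonia-like taxon), and a diffuse,
#' low-occupancy, low-abundance core (Pedobacter/Bradyrhizobium-like) in
#' fruiting bodies.
#' @return data.frame with columns `taxon_id`, `sample_type`, `occupancy`,
#'   `mean_abundance`.
#' @export
default_planted_core <- function() {
  data.frame(
    taxon_id = c("ASV_Pseudomonas", "ASV_Ralstonia",
                 "ASV_Pseudomonas", "ASV_Ralstonia", "ASV_Methylobacterium",
                 "ASV_Pedobacter", "ASV_Bradyrhizobium"),
    sample_type = c("mycelium", "mycelium",
                    "sclerotia", "sclerotia", "sclerotia",
                    "fruiting_body", "fruiting_body"),
    occupancy = c(0.95, 0.70, 1.00, 0.60, 0.50, 0.55, 0.55),
    mean_abundance = c(0.20, 0.05, 0.25, 0.03, 0.02, 0.02, 0.02),
    stringsAsFactors = FALSE)
}

#' Configuration for the synthetic amplicon community generator
#'
#' Defaults mirror the study design this package targets: 26 mycelium, 8
#' sclerotia and 10 fruiting-body samples plus 2 no-template controls;
#' planted genus-level core structure per [default_planted_core()]; 120
#' background taxa with heavy-tailed (log-normal, sdlog 3) shares redrawn
#' per sample to model sample-to-sample turnover; sequencing depth uniform
#' in 2000--5000 reads.
#'
#' @param n_samples_per_type named integer vector over sample types
#'   (control counts come from `n_controls`).
#' @param n_background_taxa number of background taxa.
#' @param planted_core data.frame with `taxon_id`, `sample_type`,
#'   `occupancy` (presence probability per sample, in \[0,1\]) and
#'   `mean_abundance` (target relative abundance conditional on presence,
#'   in (0,1)).
#' @param background_lognormal `c(mean, sd)` of the log background shares.
#' @param depth_range `c(min, max)` integer sequencing depth.
#' @param n_controls number of no-template control samples.
#' @param contaminant_taxa taxon ids guaranteed present (count > 0) in every
#'   control and carried at trace abundance in real samples.
#' @param dirichlet_concentration concentration of the per-sample Dirichlet
#'   perturbation around the target composition (larger = less noise).
#' @param seed integer seed; one seed drives all randomness.
#' @return validated list of class `community_sim_config`.
#' @export
community_sim_config <- function(
    n_samples_per_type = c(mycelium = 26, sclerotia = 8, fruiting_body = 10),
    n_background_taxa = 120,
    planted_core = default_planted_core(),
    background_lognormal = c(mean = 0, sd = 3),
    depth_range = c(2000, 5000),
    n_controls = 2,
    contaminant_taxa = c("ASV_contam_1", "ASV_contam_2"),
    dirichlet_concentration = 100,
    seed = 1) {
  cfg <- list(n_samples_per_type = n_samples_per_type,
              n_background_taxa = as.integer(n_background_taxa),
              planted_core = planted_core,
              background_lognormal = unname(background_lognormal),
              depth_range = as.integer(unname(depth_range)),
              n_controls = as.integer(n_controls),
              contaminant_taxa = as.character(contaminant_taxa),
              dirichlet_concentration = dirichlet_concentration,
              seed = as.integer(seed))
  validate_community_sim_config(cfg)
  structure(cfg, class = "community_sim_config")
}

validate_community_sim_config <- function(cfg) {
  types <- names(cfg$n_samples_per_type)
  if (is.null(types) || !all(types %in% setdiff(SAMPLE_TYPES, "control")))
    stop("n_samples_per_type: must be named with non-control sample types")
  if (any(cfg$n_samples_per_type < 0))
    stop("n_samples_per_type: counts must be >= 0")
  pc <- cfg$planted_core
  if (nrow(pc)) {
    if (!all(c("taxon_id", "sample_type", "occupancy", "mean_abundance")
             %in% names(pc)))
      stop("planted_core: needs taxon_id, sample_type, occupancy, ",
           "mean_abundance")
    if (any(!pc$sample_type %in% setdiff(SAMPLE_TYPES, "control")))
      stop("planted_core: sample_type must be a non-control type")
    if (any(pc$occupancy < 0 | pc$occupancy > 1))
      stop("planted_core: occupancy must lie in [0, 1]")
    if (any(pc$mean_abundance <= 0 | pc$mean_abundance >= 1))
      stop("planted_core: mean_abundance must lie in (0, 1)")
    mu_sums <- tapply(pc$mean_abundance, pc$sample_type, sum)
    if (any(mu_sums >= 1))
      stop("planted_core: mean_abundance must sum to < 1 per sample type")
    if (anyDuplicated(pc[c("taxon_id", "sample_type")]))
      stop("planted_core: duplicate (taxon_id, sample_type) row")
  }
  if (length(cfg$background_lognormal) != 2 ||
      cfg$background_lognormal[2] < 0)
    stop("background_lognormal: must be c(mean, sd) with sd >= 0")
  if (length(cfg$depth_range) != 2 || cfg$depth_range[1] < 1 ||
      cfg$depth_range[2] < cfg$depth_range[1])
    stop("depth_range: need 1 <= min <= max")
  if (cfg$n_background_taxa < 1)
    stop("n_background_taxa: must be >= 1")
  if (cfg$n_controls < 0) stop("n_controls: must be >= 0")
  if (cfg$n_controls > 0 && length(cfg$contaminant_taxa) >= cfg$depth_range[1])
    stop("depth_range: minimum depth must exceed the number of ",
         "contaminant_taxa")
  if (cfg$dirichlet_concentration <= 0)
    stop("dirichlet_concentration: must be positive")
  invisible(cfg)
}

#' Read a community simulation config from YAML or JSON
#' @param path `.yaml`/`.yml` or `.json` file whose keys match the
#'   [community_sim_config()] arguments (`planted_core` as a list of
#'   records).
#' @return a `community_sim_config`.
#' @export
read_community_sim_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (!is.null(raw$planted_core)) {
    pc <- raw$planted_core
    raw$planted_core <- if (is.data.frame(pc)) pc
    else do.call(rbind, lapply(pc, function(r)
      as.data.frame(r, stringsAsFactors = FALSE)))
  }
  if (!is.null(raw$n_samples_per_type))
    raw$n_samples_per_type <- unlist(raw$n_samples_per_type)
  do.call(community_sim_config, raw)
}

rdirichlet1 <- function(alpha) {
  g <- stats::setNames(stats::rgamma(length(alpha), shape = alpha, rate = 1),
                       names(alpha))
  if (sum(g) == 0) { # pathological all-zero alpha guard
    g <- rep(1, length(alpha))
  }
  g / sum(g)
}

# trace share carried by each contaminant taxon in real samples
CONTAMINANT_TRACE_SHARE <- 0.002
# share of a control sample's composition taken by contaminants overall
CONTROL_CONTAMINANT_SHARE <- 0.8

#' Generate a synthetic amplicon community
#'
#' Draws, for every sample, a target composition (planted taxa of the
#' sample's type present independently with their configured occupancy at
#' their configured mean abundance; contaminants at trace level; background
#' shares log-normal, renormalised into the remaining mass), perturbs it
#' with a Dirichlet draw, and samples counts from a multinomial at a
#' uniform-random depth. Contaminant taxa are guaranteed at least one read
#' in every control sample. Fully deterministic under the config seed.
#'
#' @param config a [community_sim_config()].
#' @return list with `table` (an [asv_table()]), `taxonomy`
#'   (a [taxonomy_table()]), `metadata` (a [sample_metadata()]), and
#'   `truth` (planted structure and contaminant ids, for tests).
#' @export
generate_community <- function(config) {
  stopifnot(inherits(config, "community_sim_config"))
  validate_community_sim_config(config)
  cfg <- config
  with_seed(cfg$seed, {
    planted_ids <- unique(cfg$planted_core$taxon_id)
    bg_ids <- sprintf("ASV_bg_%03d", seq_len(cfg$n_background_taxa))
    feature_ids <- c(planted_ids, cfg$contaminant_taxa, bg_ids)
    n_feat <- length(feature_ids)

    type_prefix <- c(mycelium = "M", sclerotia = "S", fruiting_body = "F")
    sample_ids <- character(0); sample_types <- character(0)
    for (t in names(cfg$n_samples_per_type)) {
      nt <- cfg$n_samples_per_type[[t]]
      if (nt > 0) {
        sample_ids <- c(sample_ids, sprintf("%s%02d", type_prefix[[t]],
                                            seq_len(nt)))
        sample_types <- c(sample_types, rep(t, nt))
      }
    }
    if (cfg$n_controls > 0) {
      sample_ids <- c(sample_ids, sprintf("NTC%02d", seq_len(cfg$n_controls)))
      sample_types <- c(sample_types, rep("control", cfg$n_controls))
    }

    counts <- matrix(0L, n_feat, length(sample_ids),
                     dimnames = list(feature_ids, sample_ids))
    meanlog <- cfg$background_lognormal[1]
    sdlog <- cfg$background_lognormal[2]
    n_contam <- length(cfg$contaminant_taxa)

    for (s in seq_along(sample_ids)) {
      t <- sample_types[s]
      target <- stats::setNames(numeric(n_feat), feature_ids)
      if (t == "control") {
        if (n_contam > 0)
          target[cfg$contaminant_taxa] <- CONTROL_CONTAMINANT_SHARE / n_contam
      } else {
        pc <- cfg$planted_core[cfg$planted_core$sample_type == t, ,
                               drop = FALSE]
        if (nrow(pc)) {
          present <- stats::runif(nrow(pc)) < pc$occupancy
          target[pc$taxon_id[present]] <- pc$mean_abundance[present]
        }
        if (n_contam > 0)
          target[cfg$contaminant_taxa] <- CONTAMINANT_TRACE_SHARE
      }
      remaining <- 1 - sum(target)
      w <- stats::rlnorm(cfg$n_background_taxa, meanlog, sdlog)
      target[bg_ids] <- remaining * w / sum(w)
      p <- rdirichlet1(cfg$dirichlet_concentration * target)
      depth <- sample(seq(cfg$depth_range[1], cfg$depth_range[2]), 1)
      if (t == "control" && n_contam > 0) {
        # reserve one read per contaminant so presence is guaranteed while
        # total depth stays inside depth_range
        draw <- stats::rmultinom(1, depth - n_contam, p)[, 1]
        draw[cfg$contaminant_taxa] <- draw[cfg$contaminant_taxa] + 1L
        counts[, s] <- as.integer(draw)
      } else {
        counts[, s] <- as.integer(stats::rmultinom(1, depth, p)[, 1])
      }
    }

    genus_of <- function(id) sub("^ASV_", "", id)
    lineage_for <- function(ids, kind) {
      if (!length(ids))
        return(matrix(character(0), 0, 7,
                      dimnames = list(NULL, TAXONOMY_RANKS)))
      g <- genus_of(ids)
      cbind(kingdom = "Bacteria", phylum = paste0("Phylum_", kind),
            class = UNASSIGNED, order = UNASSIGNED, family = UNASSIGNED,
            genus = g, species = UNASSIGNED)
    }
    ranks <- rbind(lineage_for(planted_ids, "planted"),
                   lineage_for(cfg$contaminant_taxa, "contaminant"),
                   lineage_for(bg_ids, "background"))
    taxonomy <- taxonomy_table(feature_ids, ranks)

    n_real <- sum(sample_types != "control")
    clade <- ifelse(sample_types == "control", "unknown",
                    ifelse(seq_along(sample_types) %% 3 == 0, "Elata",
                           "Esculenta"))
    metadata <- sample_metadata(sample_ids, sample_types, clade = clade)

    list(table = asv_table(counts),
         taxonomy = taxonomy,
         metadata = metadata,
         truth = list(planted = cfg$planted_core,
                      contaminants = cfg$contaminant_taxa,
                      background = bg_ids,
                      n_real_samples = n_real))
  })
}
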