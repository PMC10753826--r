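#' Bray-Curtis dissimilarity matrix
#'
#' For TSS proportion vectors x and y the Bray-Curtis dissimilarity is
#' `1 - sum(pmin(x, y))`, equivalent to the count formulation
#' `sum|x-y| / sum(x+y)` once samples are normalised to unit sum.
#'
#' @param rel a [rel_abundance()] table (taxa x samples) with at least two
#'   samples.
#' @return symmetric numeric matrix of class `dist_matrix` with zero
#'   diagonal and values in \[0, 1\], sample ids as dimnames.
#' @export
bray_curtis <- function(rel) {
  stopifnot(inherits(rel, "rel_abundance"))
  n <- ncol(rel)
  if (n < 2) stop("need at least 2 samples for a dissimilarity matrix")
  m <- unclass(rel)
  d <- matrix(0, n, n, dimnames = list(colnames(m), colnames(m)))
  for (i in seq_len(n - 1))
    for (j in (i + 1):n)
      d[i, j] <- d[j, i] <- 1 - sum(pmin(m[, i], m[, j]))
  d[d < 0] <- 0  # guard tiny negative rounding
  class(d) <- c("dist_matrix", class(d))
  d
}

as_dist_matrix <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || max(abs(d - t(d))) > 1e-8)
    stop("distance matrix must be square and symmetric")
  diag(d) <- 0
  d
}

# Kruskal stress-1 for a configuration against a dissimilarity vector.
# Disparities are the isotonic (pool-adjacent-violators) regression of the
# configuration distances onto the rank order of the dissimilarities.
stress1 <- function(delta, ord) {
  dhat <- numeric(length(delta))
  dhat[ord] <- stats::isoreg(delta[ord])$yf
  denom <- sum(delta^2)
  if (denom == 0) return(list(stress = 0, dhat = dhat))
  list(stress = sqrt(sum((delta - dhat)^2) / denom), dhat = dhat)
}

config_dist_vec <- function(x) as.vector(stats::dist(x))

#' Recompute Kruskal stress-1 for a configuration
#'
#' Utility used both internally and to verify a reported stress from the
#' returned coordinates.
#'
#' @param d distance matrix (any object coercible by `as.matrix`).
#' @param coords samples x k coordinate matrix.
#' @return stress-1 value.
#' @export
nmds_stress <- function(d, coords) {
  d <- as_dist_matrix(d)
  dvec <- d[lower.tri(d)]
  ord <- order(dvec, config_dist_vec(coords))
  stress1(config_dist_vec(coords), ord)$stress
}

#' Nonmetric multidimensional scaling (NMDS)
#'
#' Kruskal's nonmetric MDS: find a k-dimensional configuration whose
#' inter-point distances best preserve the rank order of the input
#' dissimilarities, minimising stress-1
#' `sqrt(sum((delta - dhat)^2) / sum(delta^2))`, where `delta` are
#' configuration distances and `dhat` their monotone (pool-adjacent-
#' violators) regression onto the dissimilarity ranks. Optimisation uses the
#' Guttman/SMACOF majorisation update with the disparities as targets; the
#' first start is the classical metric-scaling solution, the remaining
#' starts random. Stress is non-increasing within a run (an update that
#' would increase it terminates the run).
#'
#' @param d symmetric dissimilarity matrix.
#' @param k number of dimensions (default 2).
#' @param n_starts number of restarts, classical-scaling start included
#'   (default 20).
#' @param seed integer seed for the random restarts.
#' @param max_iter maximum majorisation iterations per start (default 300).
#' @param tol convergence tolerance on the stress change (default 1e-7).
#' @return object of class `nmds_result`: `coordinates` (samples x k),
#'   `stress`, `n_iterations`, `converged`, `seed`.
#' @export
nmds <- function(d, k = 2, n_starts = 20, seed = 1, max_iter = 300,
                 tol = 1e-7) {
  d <- as_dist_matrix(d)
  n <- nrow(d)
  stopifnot(k >= 1, n >= 2)
  dvec <- d[lower.tri(d)]
  pair_i <- row(d)[lower.tri(d)]
  pair_j <- col(d)[lower.tri(d)]

  run_from <- function(x0) {
    x <- scale(x0, center = TRUE, scale = FALSE)
    delta <- config_dist_vec(x)
    ord <- order(dvec, delta)
    st <- stress1(delta, ord)
    n_it <- 0L
    converged <- FALSE
    repeat {
      if (n_it >= max_iter) break
      # Guttman transform towards the current disparities
      w <- ifelse(delta > 0, st$dhat / delta, 0)
      b <- matrix(0, n, n)
      b[cbind(pair_i, pair_j)] <- -w
      b[cbind(pair_j, pair_i)] <- -w
      diag(b) <- -rowSums(b)
      x_new <- b %*% x / n
      delta_new <- config_dist_vec(x_new)
      ord_new <- order(dvec, delta_new)
      st_new <- stress1(delta_new, ord_new)
      n_it <- n_it + 1L
      if (st_new$stress > st$stress + 1e-12) break  # keep monotone descent
      improved <- st$stress - st_new$stress
      x <- x_new; delta <- delta_new; st <- st_new
      if (improved < tol) { converged <- TRUE; break }
    }
    list(x = x, stress = st$stress, n_it = n_it, converged = converged)
  }

  with_seed(seed, {
    # start 1: classical metric scaling (pad with zeros if rank-deficient)
    cm <- suppressWarnings(stats::cmdscale(d, k = k))
    if (ncol(cm) < k)
      cm <- cbind(cm, matrix(0, n, k - ncol(cm)))
    starts <- c(list(cm), lapply(seq_len(max(0, n_starts - 1)), function(s)
      matrix(stats::runif(n * k, -1, 1), n, k)))
    best <- NULL
    for (x0 in starts) {
      res <- run_from(x0)
      if (is.null(best) || res$stress < best$stress) best <- res
    }
    coords <- best$x
    dimnames(coords) <- list(rownames(d), paste0("NMDS", seq_len(k)))
    structure(list(coordinates = coords,
                   stress = best$stress,
                   n_iterations = best$n_it,
                   converged = best$converged,
                   seed = seed),
              class = "nmds_result")
  })
}

#' @export
print.nmds_result <- function(x, ...) {
  cat(sprintf("NMDS: %d points in %d dimensions, stress-1 = %.5f (%s)\n",
              nrow(x$coordinates), ncol(x$coordinates), x$stress,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' PERMANOVA (Adonis-style permutation test on a distance matrix)
#'
#' One-factor permutational multivariate analysis of variance. With N
#' samples in a groups, sums of squares are computed directly from squared
#' dissimilarities: `SS_total = sum_{i<j} d_ij^2 / N`,
#' `SS_within = sum_g (1/n_g) sum_{i<j in g} d_ij^2`,
#' `SS_between = SS_total - SS_within`, and
#' `pseudo-F = (SS_between/(a-1)) / (SS_within/(N-a))`. The p-value is
#' `(1 + #{F* >= F}) / (1 + n_permutations)` over uniform random label
#' permutations.
#'
#' @param d symmetric dissimilarity matrix with sample ids.
#' @param groups factor/character vector of group labels, one per sample
#'   (matrix order), or a named vector matched by sample id.
#' @param n_permutations number of label permutations (default 999).
#' @param seed integer seed for the permutations.
#' @return object of class `permanova_result` with `pseudo_F`, `p_value`,
#'   `n_permutations`, `group_sizes`, `SS_total`, `SS_within`,
#'   `SS_between`, `df_between`, `df_within`.
#' @export
permanova <- function(d, groups, n_permutations = 999, seed = 1) {
  d <- as_dist_matrix(d)
  n <- nrow(d)
  if (!is.null(names(groups)) && !is.null(rownames(d)))
    groups <- groups[rownames(d)]
  if (length(groups) != n)
    stop("groups must give one label per sample")
  groups <- as.factor(as.character(groups))
  a <- nlevels(groups)
  if (a < 2) stop("need at least 2 groups")
  sizes <- table(groups)
  if (any(sizes == n)) stop("one group absorbs all samples")
  if (n_permutations < 1) stop("n_permutations must be >= 1")

  d2 <- d^2
  ss_total <- sum(d2[lower.tri(d2)]) / n
  g_idx <- split(seq_len(n), groups)
  ss_within_for <- function(idx_list) {
    s <- 0
    for (idx in idx_list)
      s <- s + sum(d2[idx, idx]) / (2 * length(idx))
    s
  }
  ss_within <- ss_within_for(g_idx)
  ss_between <- ss_total - ss_within
  f_stat <- function(ssw) {
    ssb <- ss_total - ssw
    (ssb / (a - 1)) / (ssw / (n - a))
  }
  f_obs <- f_stat(ss_within)
  sizes_v <- as.integer(sizes)
  ends <- cumsum(sizes_v)
  starts <- c(1L, head(ends, -1L) + 1L)
  with_seed(seed, {
    exceed <- 0L
    for (b in seq_len(n_permutations)) {
      perm <- sample.int(n)
      idx_list <- lapply(seq_along(sizes_v), function(g)
        perm[starts[g]:ends[g]])
      f_perm <- f_stat(ss_within_for(idx_list))
      if (f_perm >= f_obs) exceed <- exceed + 1L
    }
    structure(list(pseudo_F = f_obs,
                   p_value = (1 + exceed) / (1 + n_permutations),
                   n_permutations = n_permutations,
                   group_sizes = sizes,
                   SS_total = ss_total,
                   SS_within = ss_within,
                   SS_between = ss_between,
                   df_between = a - 1L,
                   df_within = n - a,
                   seed = seed),
              class = "permanova_result")
  })
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf(
    "PERMANOVA: pseudo-F(%d, %d) = %.4g, p = %.4g (%d permutations)\n",
    x$df_between, x$df_within, x$pseudo_F, x$p_value, x$n_permutations))
  cat(sprintf("  SS between = %.4g, SS within = %.4g, SS total = %.4g\n",
              x$SS_between, x$SS_within, x$SS_total))
  invisible(x)
}
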