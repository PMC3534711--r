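#' Bray-Curtis dissimilarity
#'
#' `BC(x, y) = sum|x_i - y_i| / sum(x_i + y_i)` between the rows of an
#' abundance (or relative-intensity) matrix. Identical rows give 0, rows
#' with disjoint support give 1; on rows normalized to equal sums the
#' identity `BC = 1 - sum min(x_i, y_i) / rowsum` holds.
#'
#' @param m numeric matrix, samples in rows, non-negative, no zero rows.
#' @return a `dist` object of pairwise dissimilarities.
#' @export
bray_curtis <- function(m) {
  m <- as.matrix(m)
  if (any(m < 0)) stop("abundances must be non-negative")
  zero <- rowSums(m) <= 0
  if (any(zero)) stop("zero-sum row(s): ",
                      paste(rownames(m)[zero] %||% which(zero), collapse = ", "))
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d[i, j] <- d[j, i] <- sum(abs(m[i, ] - m[j, ])) / sum(m[i, ] + m[j, ])
  }
  stats::as.dist(d)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' NMDS ordination of a dissimilarity matrix
#'
#' Non-metric multidimensional scaling: finds a k-dimensional configuration
#' whose inter-point distances are, in rank order, as close as possible to
#' the input dissimilarities, minimizing Kruskal's stress-1 by monotone
#' regression (primary tie treatment). Runs [vegan::monoMDS()] from
#' `n_starts` random starting configurations and keeps the lowest-stress
#' solution; reproducible given `seed`.
#'
#' @param d a `dist` (e.g. from [bray_curtis()]) or symmetric matrix, n >= 3.
#' @param k ordination dimensions (default 2).
#' @param n_starts random starts (default 20).
#' @param seed integer seed.
#' @return list of class `nmds_result`: `points` (n x k), `stress`
#'   (Kruskal stress-1, 0-1 scale), `converged` starts count, `degenerate`
#'   (TRUE when all dissimilarities are equal and any symmetric
#'   configuration fits with zero effective structure).
#' @export
nmds_ordination <- function(d, k = 2, n_starts = 20, seed = NULL) {
  d <- stats::as.dist(d)
  n <- attr(d, "Size")
  if (n < 3) stop("need at least 3 samples for an ordination")
  degenerate <- max(d) - min(d) < 1e-12
  with_seed(seed, {
    best <- NULL
    for (i in seq_len(n_starts)) {
      init <- matrix(rnorm(n * k), n, k)
      sol <- vegan::monoMDS(d, y = init, k = k, model = "global")
      if (is.null(best) || sol$stress < best$stress) best <- sol
    }
    pts <- best$points
    rownames(pts) <- attr(d, "Labels")
    structure(list(points = pts, stress = best$stress,
                   n_starts = n_starts, degenerate = degenerate),
              class = "nmds_result")
  })
}

#' @export
print.nmds_result <- function(x, ...) {
  cat("<nmds_result>", nrow(x$points), "points,", ncol(x$points),
      "dimensions, stress =", format(x$stress, digits = 4),
      if (x$degenerate) "(degenerate: all dissimilarities equal)", "\n")
  invisible(x)
}

# ANOSIM R for one grouping given the rank vector of all pairwise
# dissimilarities. within: logical vector per pair.
anosim_R <- function(rank_d, within, M) {
  (mean(rank_d[!within]) - mean(rank_d[within])) / (M / 2)
}

# all distinct permutations of a label multiset (for exhaustive enumeration)
multiset_perms <- function(labels) {
  labels <- sort(labels)
  n <- length(labels)
  out <- list()
  rec <- function(prefix, rest) {
    if (!length(rest)) {
      out[[length(out) + 1]] <<- prefix
      return(invisible(NULL))
    }
    for (u in unique(rest)) {
      i <- match(u, rest)
      rec(c(prefix, u), rest[-i])
    }
  }
  rec(character(0), as.character(labels))
  out
}

#' Analysis of similarity (ANOSIM)
#'
#' Rank-based permutation test for differences between a-priori groups of
#' samples. All pairwise dissimilarities are ranked (average ranks for ties)
#' and the statistic is
#' `R = (mean between-group rank - mean within-group rank) / (M/2)` with
#' `M = n(n-1)/2`; R is 1 when all between-group dissimilarities exceed all
#' within-group ones and near 0 under no group structure. The p-value is the
#' permutation tail probability with the add-one correction
#' `p = (1 + #(R_perm >= R_obs)) / (1 + n_perm)`; with
#' `exhaustive = TRUE` all distinct label permutations are enumerated
#' instead and `p = #(R_perm >= R_obs) / #perms` (feasible for n <= ~8).
#'
#' @param d a `dist` or symmetric dissimilarity matrix.
#' @param groups group labels, one per sample; >= 2 groups of >= 2 members.
#' @param n_perm random permutations (default 999).
#' @param seed integer seed.
#' @param exhaustive enumerate all distinct label permutations.
#' @return list of class `anosim_result`: `statistic` (R), `p_value`,
#'   `n_perm` (or number of enumerated permutations), `groups`,
#'   `perm_R` (permutation distribution).
#' @export
anosim_test <- function(d, groups, n_perm = wf_config()$n_perm, seed = NULL,
                        exhaustive = FALSE) {
  d <- stats::as.dist(d)
  n <- attr(d, "Size")
  groups <- as.character(groups)
  stopifnot(length(groups) == n)
  sizes <- table(groups)
  if (length(sizes) < 2) stop("need at least two groups")
  if (any(sizes < 2)) stop("every group needs at least 2 members: ",
                           paste(names(sizes)[sizes < 2], collapse = ", "))
  M <- n * (n - 1) / 2
  rank_d <- rank(as.numeric(d))
  pair_i <- pair_j <- integer(M)
  k <- 1L
  for (i in 1:(n - 1)) for (j in (i + 1):n) {  # dist order: (1,2)..(1,n),(2,3),...
    pair_i[k] <- i; pair_j[k] <- j; k <- k + 1L
  }
  within_of <- function(g) g[pair_i] == g[pair_j]
  R_obs <- anosim_R(rank_d, within_of(groups), M)
  if (exhaustive) {
    perms <- multiset_perms(groups)
    perm_R <- vapply(perms, function(g) anosim_R(rank_d, within_of(g), M),
                     numeric(1))
    p <- mean(perm_R >= R_obs - 1e-12)
    n_perm <- length(perms)
  } else {
    perm_R <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
      anosim_R(rank_d, within_of(sample(groups)), M)
    }, numeric(1)))
    p <- (1 + sum(perm_R >= R_obs - 1e-12)) / (1 + n_perm)
  }
  structure(list(statistic = R_obs, p_value = p, n_perm = n_perm,
                 groups = groups, perm_R = perm_R),
            class = "anosim_result")
}

#' @export
print.anosim_result <- function(x, ...) {
  cat("<anosim_result> R =", format(x$statistic, digits = 4),
      ", p =", format(x$p_value, digits = 4),
      "(", x$n_perm, "permutations )\n")
  invisible(x)
}

#' Bonferroni correction
#'
#' `min(1, p * m)` for each p-value; the standard conservative adjustment
#' for `m` simultaneous tests.
#'
#' @param p p-values.
#' @param m number of tests (default `length(p)`).
#' @return corrected p-values.
#' @export
bonferroni <- function(p, m = length(p)) {
  stopifnot(m >= 1, all(p >= 0 & p <= 1))
  pmin(1, p * m)
}

#' Remove singleton OTUs
#'
#' Drops OTUs whose total count across all samples is exactly 1 (sequences
#' occurring once in the whole dataset carry no sharing information and
#' inflate richness).
#'
#' @param tab a [tag_table()] (OTUs x samples).
#' @return the filtered table with attributes `n_removed` and
#'   `fraction_removed` (fraction of OTUs that were singletons).
#' @export
remove_singletons <- function(tab) {
  tot <- rowSums(tab)
  single <- tot == 1
  if (all(single)) stop("all OTUs are singletons; nothing left after filtering")
  out <- tag_table(unclass(tab)[!single, , drop = FALSE],
                   taxonomy = attr(tab, "taxonomy"))
  attr(out, "n_removed") <- sum(single)
  attr(out, "fraction_removed") <- mean(single)
  out
}

# subsample a count vector without replacement to `depth` reads
# (multivariate hypergeometric draw)
rarefy_counts <- function(counts, depth) {
  n <- sum(counts)
  if (depth >= n) return(counts)
  picked <- sample.int(n, depth)
  cum <- cumsum(counts)
  tabulate(findInterval(picked - 1L, c(0L, cum), left.open = FALSE),
           nbins = length(counts))
}

#' Shared and unique OTUs under repeated resampling
#'
#' Sequencing depth differs between samples, so OTU sharing is assessed on
#' repeated random subsamples: in each of `n_resample` iterations every
#' sample is subsampled without replacement to the depth of the smallest
#' sample, and the pooled OTU list of that iteration is partitioned into
#' OTUs present in all samples (shared), in exactly one (unique) and the
#' remainder (partially shared). Reported percentages are means over
#' iterations. Singleton filtering ([remove_singletons()]) should be applied
#' beforehand.
#'
#' @param tab a [tag_table()] (OTUs x samples).
#' @param samples columns to compare (default all).
#' @param n_resample iterations (default 1000).
#' @param seed integer seed.
#' @return list of class `shared_otu_result` (all percentages):
#'   `shared_pct` of pooled OTUs present in all samples;
#'   `unique_pct` named per sample; `partial_pct`;
#'   `shared_seq_pct` fraction of resampled sequences in shared OTUs;
#'   `unique_seq_pct` fraction of resampled sequences in unique OTUs;
#'   `shared_seq_full_pct` the same sequence fraction computed on the full
#'   (unresampled) counts with the per-iteration shared OTU sets;
#'   `depth` resampling depth; `n_resample`.
#' @export
shared_otus <- function(tab, samples = colnames(tab),
                        n_resample = wf_config()$n_resample, seed = NULL) {
  m <- unclass(tab)[, samples, drop = FALSE]
  if (length(samples) < 2) stop("need at least two samples")
  tot <- colSums(m)
  if (any(tot == 0)) stop("empty sample(s): ",
                          paste(samples[tot == 0], collapse = ", "))
  depth <- min(tot)
  S <- ncol(m)
  full_tot <- sum(m)
  with_seed(seed, {
    acc <- list(shared = 0, partial = 0, unique = numeric(S),
                seq_shared = 0, seq_unique = 0, seq_shared_full = 0)
    for (it in seq_len(n_resample)) {
      sub <- vapply(seq_len(S), function(s) rarefy_counts(m[, s], depth),
                    integer(nrow(m)))
      pres <- sub > 0
      npres <- rowSums(pres)
      pooled <- npres > 0
      n_pool <- sum(pooled)
      shared <- npres == S
      uniq <- npres == 1
      acc$shared <- acc$shared + sum(shared) / n_pool
      acc$partial <- acc$partial + sum(pooled & !shared & !uniq) / n_pool
      acc$unique <- acc$unique + colSums(pres & uniq) / n_pool
      acc$seq_shared <- acc$seq_shared + sum(sub[shared, ]) / sum(sub)
      acc$seq_unique <- acc$seq_unique + sum(sub[uniq, ]) / sum(sub)
      acc$seq_shared_full <- acc$seq_shared_full + sum(m[shared, ]) / full_tot
    }
    structure(list(
      shared_pct = 100 * acc$shared / n_resample,
      partial_pct = 100 * acc$partial / n_resample,
      unique_pct = setNames(100 * acc$unique / n_resample, samples),
      shared_seq_pct = 100 * acc$seq_shared / n_resample,
      unique_seq_pct = 100 * acc$seq_unique / n_resample,
      shared_seq_full_pct = 100 * acc$seq_shared_full / n_resample,
      depth = depth, n_resample = n_resample),
      class = "shared_otu_result")
  })
}

#' @export
print.shared_otu_result <- function(x, ...) {
  cat("<shared_otu_result> shared", format(x$shared_pct, digits = 3),
      "% of pooled OTUs (", format(x$shared_seq_pct, digits = 3),
      "% of sequences ), depth", x$depth, ",", x$n_resample, "iterations\n")
  invisible(x)
}

#' Pairwise shared-OTU fraction
#'
#' The shared fraction of the pooled OTU list of one sample pair, under the
#' same resampling scheme as [shared_otus()].
#'
#' @param tab a [tag_table()].
#' @param pair character vector of two sample names.
#' @inheritParams shared_otus
#' @return shared percentage (scalar), with the full `shared_otu_result` as
#'   attribute `detail`.
#' @export
pairwise_shared_fraction <- function(tab, pair, n_resample = wf_config()$n_resample,
                                     seed = NULL) {
  stopifnot(length(pair) == 2)
  res <- shared_otus(tab, samples = pair, n_resample = n_resample, seed = seed)
  structure(res$shared_pct, detail = res)
}

#' Taxonomic composition at a given rank
#'
#' Aggregates per-sample relative sequence abundances at a taxonomy rank and
#' ranks taxa per sample. Taxonomy paths are semicolon-separated
#' `domain;phylum;class;order;family;genus`. With `assigned_only = TRUE`,
#' OTUs lacking an assignment at the requested rank are excluded before
#' normalization (the "only sequences assigned up to genus level" rule).
#'
#' @param tab a [tag_table()] with a `taxonomy` attribute.
#' @param rank one of "phylum", "class", "genus".
#' @param top_n length of the ranked per-sample list (default 30).
#' @param assigned_only drop OTUs unassigned at `rank`.
#' @return list: `composition` (taxa x samples relative abundances),
#'   `top` (list of ranked character vectors per sample).
#' @export
taxon_composition <- function(tab, rank = c("phylum", "class", "genus"),
                              top_n = 30, assigned_only = FALSE) {
  rank <- match.arg(rank)
  lvl <- c(phylum = 2L, class = 3L, genus = 6L)[[rank]]
  tax <- attr(tab, "taxonomy")
  if (is.null(tax)) stop("tag table has no taxonomy attribute")
  parts <- strsplit(tax[rownames(tab)], ";", fixed = TRUE)
  taxon <- vapply(parts, function(p)
    if (length(p) >= lvl && nzchar(p[lvl])) p[lvl] else NA_character_, "")
  if (all(is.na(taxon))) stop("no OTU is assigned at rank ", rank)
  m <- unclass(tab)
  if (assigned_only) {
    m <- m[!is.na(taxon), , drop = FALSE]
    taxon <- taxon[!is.na(taxon)]
  } else {
    taxon[is.na(taxon)] <- "unassigned"
  }
  agg <- rowsum(m, group = taxon)
  tot <- colSums(agg)
  if (any(tot == 0)) stop("sample(s) with no assigned sequences at rank ", rank)
  comp <- sweep(agg, 2, tot, "/")
  top <- lapply(colnames(comp), function(s) {
    ord <- order(comp[, s], decreasing = TRUE)
    head(rownames(comp)[ord][comp[ord, s] > 0], top_n)
  })
  names(top) <- colnames(comp)
  list(composition = comp, top = top)
}
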