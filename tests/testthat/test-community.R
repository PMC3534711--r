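test_that("bray_curtis matches its definition and the vegan oracle", {
  m <- rbind(a = c(0.3, 0.7), b = c(0.5, 0.5), c = c(0.3, 0.7))
  d <- as.matrix(bray_curtis(m))
  expect_equal(d["a", "b"], 0.2)
  expect_equal(d["a", "c"], 0)                     # identical rows
  expect_equal(as.numeric(bray_curtis(rbind(c(1, 0), c(0, 1))))[1], 1)  # disjoint

  set.seed(12)
  x <- matrix(rexp(60), 6)
  expect_equal(as.numeric(bray_curtis(x)),
               as.numeric(vegan::vegdist(x, method = "bray")),
               tolerance = 1e-12)

  # identity on normalized rows: BC = 1 - sum min(x_i, y_i)
  rel <- sweep(x, 1, rowSums(x), "/")
  d <- as.matrix(bray_curtis(rel))
  for (i in 1:5) for (j in (i + 1):6) {
    expect_equal(d[i, j], 1 - sum(pmin(rel[i, ], rel[j, ])), tolerance = 1e-12)
  }

  expect_error(bray_curtis(rbind(c(1, 2), c(0, 0))), "zero")
})

test_that("nmds_ordination recovers planar configurations and flags degeneracy", {
  # 3 equidistant points embed exactly
  d3 <- stats::as.dist(matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3))
  res <- nmds_ordination(d3, n_starts = 10, seed = 1)
  expect_lt(res$stress, 1e-3)
  expect_true(res$degenerate)      # all dissimilarities equal

  # points drawn on a plane: Euclidean distances embed with low stress
  set.seed(2)
  pts <- matrix(rnorm(24), 12, 2)
  res <- nmds_ordination(dist(pts), n_starts = 20, seed = 3)
  expect_lt(res$stress, 0.05)
  expect_false(res$degenerate)

  # two tight clusters: every between-cluster ordination distance exceeds
  # every within-cluster one
  y <- rbind(matrix(rnorm(10, 0, 0.05), 5), matrix(rnorm(10, 5, 0.05), 5))
  res <- nmds_ordination(bray_curtis(abs(y) + 0.1), n_starts = 10, seed = 4)
  dd <- as.matrix(dist(res$points))
  within <- c(dd[1:5, 1:5][upper.tri(diag(5))], dd[6:10, 6:10][upper.tri(diag(5))])
  between <- dd[1:5, 6:10]
  expect_gt(min(between), max(within))
})

test_that("anosim_test gives R = 1 for perfect separation and matches vegan", {
  sep <- two_groups(sep = 20, seed = 5)
  res <- anosim_test(sep$d, sep$groups, n_perm = 99, seed = 1)
  expect_equal(res$statistic, 1)
  expect_lt(res$p_value, 0.05)

  mixed <- two_groups(sep = 0.5, seed = 6)
  mine <- anosim_test(mixed$d, mixed$groups, n_perm = 999, seed = 2)
  veg <- vegan::anosim(mixed$d, factor(mixed$groups), permutations = 99)
  expect_equal(mine$statistic, unname(veg$statistic), tolerance = 1e-12)
  expect_gte(mine$statistic, -1)
  expect_lte(mine$statistic, 1)

  expect_error(anosim_test(mixed$d, rep("a", 10)), "two groups")
  expect_error(anosim_test(mixed$d, c(rep("a", 9), "b")), "2 members")
})

test_that("anosim permutation distribution matches exhaustive enumeration", {
  # n = 6, two groups of 3: all C(6,3) = 20 label arrangements
  g <- two_groups(n_per = 3, sep = 1, seed = 7)
  exh <- anosim_test(g$d, g$groups, exhaustive = TRUE)
  expect_equal(exh$n_perm, 20)

  # oracle: enumerate subset assignments directly
  rank_d <- rank(as.numeric(g$d))
  M <- 15
  pairs <- t(combn(6, 2))
  brute <- apply(combn(6, 3), 2, function(set) {
    grp <- ifelse(seq_len(6) %in% set, "a", "b")
    within <- grp[pairs[, 1]] == grp[pairs[, 2]]
    (mean(rank_d[!within]) - mean(rank_d[within])) / (M / 2)
  })
  expect_equal(sort(exh$perm_R), sort(brute), tolerance = 1e-12)
  expect_equal(exh$p_value, mean(brute >= exh$statistic - 1e-12))

  # exhaustive p agrees with a large random-permutation p
  rnd <- anosim_test(g$d, g$groups, n_perm = 1999, seed = 8)
  expect_lt(abs(rnd$p_value - exh$p_value), 0.03)
})

test_that("bonferroni caps at 1 and is identity for m = 1", {
  expect_equal(bonferroni(0.01, 3), 0.03)
  expect_equal(bonferroni(0.5, 3), 1)
  expect_equal(bonferroni(0.2, 1), 0.2)
  expect_equal(bonferroni(c(0.01, 0.5)), c(0.02, 1))
})

test_that("remove_singletons drops total-count-1 OTUs and reports the fraction", {
  m <- matrix(0L, 100, 2, dimnames = list(paste0("O", 1:100), c("a", "b")))
  m[1:64, 1] <- 5L
  m[1:36 + 64, 2] <- 1L   # 36 singletons of 100 OTUs
  tab <- tag_table(m)
  filt <- remove_singletons(tab)
  expect_equal(attr(filt, "fraction_removed"), 0.36)
  expect_equal(nrow(filt), 64)

  no_single <- tag_table(matrix(5L, 4, 2))
  expect_equal(attr(remove_singletons(no_single), "n_removed"), 0)

  all_single <- tag_table(matrix(c(1L, 0L, 0L, 1L), 2))
  expect_error(remove_singletons(all_single), "singleton")
})

test_that("shared_otus: identical samples share everything; equal depths are exact", {
  m <- matrix(rep(c(10L, 5L, 2L), 3), ncol = 3,
              dimnames = list(c("A", "B", "C"), c("s1", "s2", "s3")))
  res <- shared_otus(tag_table(m), n_resample = 5, seed = 1)
  expect_equal(res$shared_pct, 100)
  expect_equal(unname(res$unique_pct), c(0, 0, 0))
  expect_equal(res$shared_seq_pct, 100)

  # equal column sums: resampling is a no-op, result is the exhaustive one
  tab <- tiny_tag_table()
  expect_equal(colSums(tab), c(s1 = 10, s2 = 10, s3 = 10))
  res <- shared_otus(tab, n_resample = 7, seed = 2)
  # pooled 5 OTUs: 1 shared, 3 unique, 1 partial
  expect_equal(res$shared_pct, 20)
  expect_equal(res$partial_pct, 20)
  expect_equal(unname(res$unique_pct), c(20, 20, 20))
  expect_equal(res$shared_seq_pct, 100 * 15 / 30)
  expect_equal(res$depth, 10)

  # disjoint pair -> 0%, identical pair -> 100%
  dis <- tag_table(matrix(c(5L, 0L, 0L, 7L), 2,
                          dimnames = list(c("A", "B"), c("x", "y"))))
  expect_equal(pairwise_shared_fraction(dis, c("x", "y"), n_resample = 3,
                                        seed = 1)[1], 0)
  expect_equal(pairwise_shared_fraction(tag_table(matrix(c(5L, 3L, 5L, 3L), 2,
               dimnames = list(NULL, c("x", "y")))), c("x", "y"),
               n_resample = 3, seed = 1)[1], 100)
})

test_that("shared_otus means are seed-stable and tighten with more iterations", {
  base <- remove_singletons(gen_tag_table(community_spec(reads_per_sample = 800),
                                          seed = 9))
  # unequal depths so subsampling actually randomizes
  m <- unclass(base)
  m[, 1] <- m[, 1] * 3L
  tab <- tag_table(m, taxonomy = attr(base, "taxonomy"))
  a <- shared_otus(tab, n_resample = 200, seed = 1)$shared_pct
  b <- shared_otus(tab, n_resample = 200, seed = 2)$shared_pct
  expect_equal(a, b, tolerance = 0.05)   # Monte-Carlo error only

  # SE of the mean scales ~ 1/sqrt(n_resample): 4x iterations ~ half the SE
  se_of <- function(n_it) sd(vapply(1:12, function(s)
    shared_otus(tab, n_resample = n_it, seed = 100 + s)$shared_pct, numeric(1)))
  ratio <- se_of(10) / se_of(40)
  expect_gt(ratio, 1.2)
  expect_lt(ratio, 3.5)
})

test_that("taxon_composition aggregates ranks and applies the genus filter", {
  m <- matrix(c(60L, 30L, 10L, 7L), 4, 1, dimnames = list(paste0("O", 1:4), "s1"))
  tax <- c(O1 = "Bacteria;Proteobacteria;Gammaproteobacteria;Alteromonadales;Alteromonadaceae;Pseudoalteromonas",
           O2 = "Bacteria;Proteobacteria;Deltaproteobacteria;Desulfobacterales;Desulfobulbaceae;Desulforhopalus",
           O3 = "Bacteria;Actinobacteria;Actinobacteria;Micrococcales;Demequinaceae;Demequina",
           O4 = "Bacteria;Firmicutes;Clostridia")
  tab <- tag_table(m, taxonomy = tax)

  cls <- taxon_composition(tab, "class")
  expect_equal(sum(cls$composition[, "s1"]), 1)
  expect_equal(cls$composition["Gammaproteobacteria", "s1"], 60 / 107)
  expect_equal(cls$top$s1[1], "Gammaproteobacteria")

  # class counts 60/30/10(+7): ranking follows abundance
  expect_equal(cls$top$s1,
               c("Gammaproteobacteria", "Deltaproteobacteria", "Actinobacteria",
                 "Clostridia")[order(c(60, 30, 10, 7), decreasing = TRUE)])

  # genus filter: O4 has no genus level, denominator shrinks to 100
  gen <- taxon_composition(tab, "genus", assigned_only = TRUE)
  expect_equal(sum(gen$composition[, "s1"]), 1)
  expect_equal(gen$composition["Pseudoalteromonas", "s1"], 0.6)
  expect_false("unassigned" %in% rownames(gen$composition))

  # without the filter the unassigned mass is kept
  gen2 <- taxon_composition(tab, "genus", assigned_only = FALSE)
  expect_equal(gen2$composition["unassigned", "s1"], 7 / 107)

  expect_error(taxon_composition(tag_table(m), "class"), "assigned")
})

test_that("anosim null p-values are well-calibrated (scaled-down)", {
  # 100-dataset version of the 500-dataset acceptance property
  rejections <- vapply(1:100, function(s) {
    g <- two_groups(n_per = 5, sep = 0, seed = 1000 + s)
    anosim_test(g$d, g$groups, n_perm = 99, seed = s)$p_value <= 0.05
  }, logical(1))
  # binomial 99% upper bound around 0.05 for n = 100
  expect_lte(mean(rejections), 0.05 + 2.58 * sqrt(0.05 * 0.95 / 100))
})
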