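test_that("gen_profile stores the designed gradient and flux as ground truth", {
  # 250 uM at the interface falling to 0 at 6.7 mm
  p <- gen_profile(o2_spec(6.7), seed = 1)
  tr <- attr(p, "truth")
  expect_equal(tr$steepest_gradient, -250 / 6.7)
  expect_equal(abs(tr$flux), 0.65 * 8.9e-10 * (250 / 6.7) * 8.64e7)

  # flat profile: zero flux
  flat <- profile_spec("O2", data.frame(depth_mm = c(0, 10), value = c(100, 100)),
                       porosity = 0.65)
  expect_equal(attr(gen_profile(flat, 1), "truth")$flux, 0)

  # sulfide rising 0 -> 800 uM between 30 and 50 mm, phi 0.95:
  # J = 0.95 * 6.4e-10 * 40 * 8.64e7 ~ 2.10 mmol m-2 d-1
  sul <- profile_spec("H2S",
                      data.frame(depth_mm = c(0, 30, 50), value = c(0, 0, 800)),
                      porosity = 0.95)
  expect_equal(attr(gen_profile(sul, 1), "truth")$flux_up,
               0.95 * 6.4e-10 * 40 * 8.64e7, tolerance = 1e-12)
  expect_equal(attr(gen_profile(sul, 1), "truth")$flux_up, 2.101248)
})

test_that("generators are reproducible for a fixed (spec, seed) and leave the RNG alone", {
  spec <- o2_spec(noise_sd = 3)
  a <- gen_profile(spec, seed = 42)
  b <- gen_profile(spec, seed = 42)
  expect_identical(a$value, b$value)
  expect_false(identical(a$value, gen_profile(spec, seed = 43)$value))

  set.seed(99)
  before <- runif(1)
  set.seed(99)
  invisible(gen_tag_table(community_spec(reads_per_sample = 100), seed = 1))
  expect_identical(runif(1), before)

  t1 <- gen_tag_table(community_spec(), seed = 7)
  t2 <- gen_tag_table(community_spec(), seed = 7)
  expect_identical(unclass(t1)[, ], unclass(t2)[, ])
})

test_that("gen_chamber encodes slope = -TOU/(24 h) and supports curvature", {
  ch <- gen_chamber(24, water_height = 0.1, noise_sd = 0, seed = 1)
  expect_equal(attr(ch, "truth")$slope, -10)   # 24/(24*0.1) uM/h
  fit <- lm(ch$O2_uM ~ ch$time_h)
  expect_equal(unname(coef(fit)[2]), -10, tolerance = 1e-10)

  expect_equal(sd(gen_chamber(0, noise_sd = 0)$O2_uM), 0)  # constant series

  bent <- gen_chamber(24, 0.1, duration_h = 10, curvature_after_h = 4,
                      noise_sd = 0)
  early <- bent$time_h <= 4
  expect_equal(diff(bent$O2_uM[early]) / diff(bent$time_h[early]),
               rep(-10, sum(early) - 1), tolerance = 1e-9)
  late_slope <- diff(tail(bent$O2_uM, 2)) / diff(tail(bent$time_h, 2))
  expect_gt(late_slope, -10 / 2)  # decline flattened well below initial rate
})

test_that("gen_arisa respects jitter, dropout and ground-truth bookkeeping", {
  spec0 <- arisa_spec(c(121, 205, 333), c(0.5, 0.3, 0.2),
                      size_call_sd = 0, dropout_prob = 0)
  pk <- gen_arisa(spec0, seed = 1)
  expect_equal(nrow(pk), 9)                               # 3 peaks x 3 replicates
  expect_equal(sort(unique(pk$size_bp)), c(121, 205, 333))  # identical to truth
  expect_equal(attr(pk, "truth")$true_size_bp, spec0$lengths[attr(pk, "truth")$otu])

  # jitter 0.4 bp: >= 95% of peaks within +-1 bp of truth (2.5 sigma tail)
  spec_j <- arisa_spec(seq(101, 999, by = 26), size_call_sd = 0.4)
  pk <- gen_arisa(arisa_spec(rep(500, 340), size_call_sd = 0.4),
                  seed = 2)  # ~1000 draws of one fragment
  expect_gte(mean(abs(pk$size_bp - 500) <= 1), 0.95)

  # dropout 0.3 with 3 replicates: P(present in >= 1) = 1 - 0.3^3 = 0.973
  spec_d <- arisa_spec(seq(101, 999, by = 2), size_call_sd = 0, dropout_prob = 0.3)
  pk <- gen_arisa(spec_d, seed = 3)
  present <- length(unique(attr(pk, "truth")$otu)) / length(spec_d$lengths)
  expect_equal(present, 1 - 0.3^3, tolerance = 0.02)
})

test_that("gen_tag_table realizes the designed community structure", {
  # no unique OTUs, identical abundance vectors: designed sharing is total
  all_core <- gen_tag_table(community_spec(n_unique = 0, singleton_rate = 0),
                            seed = 1)
  expect_equal(attr(all_core, "truth")$designed_shared_fraction, 1)

  # default design: 18 core + 3 x 27 unique = 18/99 of the pooled OTU list
  tab <- gen_tag_table(community_spec(), seed = 2)
  expect_equal(attr(tab, "truth")$designed_shared_fraction, 18 / 99)
  tr <- attr(tab, "truth")
  expect_true(all(rowSums(unclass(tab)[tr$core, ] > 0) == 3))  # core in all samples

  # singleton construction: ~36% of all OTUs carry exactly one read
  singles <- rowSums(tab) == 1
  expect_equal(mean(singles), 0.36, tolerance = 0.03)

  # column sums ~ reads per sample (+ the hosted singletons)
  n_single <- length(attr(tab, "truth")$singletons)
  expect_true(all(colSums(tab) >= 5000))
  expect_true(all(colSums(tab) <= 5000 + n_single))
})

test_that("gen_tracer truth matches the layer-rate arithmetic", {
  d <- gen_tracer(n_layers = 10, fraction_top = 0.002, decay = 0.7,
                  noise_cv = 0, seed = 1)
  rates <- layer_rate(d$fraction, d$pool, d$porosity, d$time_h)
  expect_equal(nmol_cm2_to_mmol_m2(sum(rates)),
               attr(d, "truth")$integrated_mmol_m2_d)
})
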