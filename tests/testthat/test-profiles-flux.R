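test_that("speciate_sulfide follows the first dissociation equilibrium", {
  z <- 0:5
  h2s <- concentration_profile(z, rep(100, 6), "H2S", porosity = 0.95)
  mk_ph <- function(ph) concentration_profile(z, rep(ph, 6), "pH")

  expect_equal(speciate_sulfide(h2s, mk_ph(6.98), pK1 = 6.98)$value,
               rep(200, 6))                                 # pH = pK1 doubles
  expect_equal(speciate_sulfide(h2s, mk_ph(3), pK1 = 6.98)$value,
               rep(100, 6), tolerance = 1e-3)               # fully protonated limit
  expect_equal(speciate_sulfide(h2s, mk_ph(7.48), pK1 = 6.98)$value,
               rep(100 * (1 + 10^0.5), 6))                  # ~416.2 uM
})

test_that("speciate_sulfide aligns grids and is monotone in pH", {
  h2s <- concentration_profile(c(0, 2, 4, 6), c(50, 100, 150, 200), "H2S",
                               porosity = 0.95)
  ph <- concentration_profile(c(0, 3, 6), c(7.6, 7.2, 6.8), "pH")
  tot <- speciate_sulfide(h2s, ph)
  expect_equal(tot$depth_mm, h2s$depth_mm)
  expect_true(all(tot$value >= h2s$value))    # total sulfide >= measured H2S

  # depths outside the pH span are dropped with a warning
  ph_short <- concentration_profile(c(0, 4), c(7.2, 7.2), "pH")
  expect_warning(out <- speciate_sulfide(h2s, ph_short), "dropped")
  expect_equal(out$depth_mm, c(0, 2, 4))

  # property: increasing pH never decreases total sulfide
  ph_vals <- seq(6, 8.5, by = 0.25)
  tots <- vapply(ph_vals, function(p) {
    speciate_sulfide(concentration_profile(0, 100, "H2S", porosity = 0.9),
                     concentration_profile(0, p, "pH"))$value
  }, numeric(1))
  expect_true(all(diff(tots) > 0))
})

test_that("steepest_gradient matches brute-force window enumeration", {
  # exact line: every window has the same slope, shallowest window reported
  p <- gen_profile(o2_spec(6.7), seed = 1)
  g <- steepest_gradient(p, window_pts = 2)
  expect_equal(g$slope, -250 / 6.7)
  expect_equal(unname(g$window["top"]), 0)

  expect_equal(steepest_gradient(
    concentration_profile(0:9, rep(5, 10), "O2", porosity = 0.5))$slope, 0)
  expect_true(steepest_gradient(
    concentration_profile(0:9, rep(5, 10), "O2", porosity = 0.5))$degenerate)

  # random profiles of <= 50 points vs the lm() oracle over all windows
  set.seed(31)
  for (rep in 1:10) {
    n <- sample(10:50, 1)
    prof <- concentration_profile(seq(0, n - 1), cumsum(rnorm(n)), "pH")
    for (w in c(2, 3, 5)) {
      for (dir in c("both", "up", "down")) {
        got <- steepest_gradient(prof, w, dir)$slope
        expect_equal(got, brute_gradient(prof, w, dir), tolerance = 1e-9)
      }
    }
  }

  # V-shaped profile with direction = both: up and down gradients bracket peak
  pk <- peak_profile(peak_mm = 30)
  up <- steepest_gradient(pk, 3, "up")
  down <- steepest_gradient(pk, 3, "down")
  expect_gt(up$slope, 0)
  expect_lt(down$slope, 0)
  expect_lte(unname(up$window["bottom"]), 30 + 2)
  expect_gte(unname(down$window["top"]), 30 - 2)
})

test_that("steepest_gradient ignores the diffusive boundary layer above 0 mm", {
  # a huge artificial slope above the interface must not win
  prof <- concentration_profile(c(-2, -1, 0, 1, 2, 3), c(500, 250, 240, 230, 220, 210),
                                "O2", porosity = 0.65)
  expect_equal(steepest_gradient(prof, 2)$slope, -10)
})

test_that("fick_flux applies J = phi * D * dc/dz with the uM/mm convention", {
  expect_equal(fick_flux(50, 0.65, 8.9e-10)$magnitude,
               0.65 * 8.9e-10 * 50 * 8.64e7)       # 2.4991 mmol m-2 d-1
  expect_equal(round(fick_flux(50, 0.65, 8.9e-10)$magnitude, 2), 2.50)
  expect_equal(fick_flux(0, 0.95, 6.4e-10)$J_diff, 0)
  # DOC: 1800 uM over 25 mm, phi 0.95, D 6.2e-11 -> ~0.37
  expect_equal(round(fick_flux(1800 / 25, 0.95, 6.2e-11)$magnitude, 2), 0.37)
  expect_error(fick_flux(1, 0, 1e-9), "porosity")
})

test_that("oracle equivalence: fick_flux recovers generator truth exactly when noise-free", {
  specs <- list(
    o2_spec(6.7),
    o2_spec(5.0),
    profile_spec("H2S", data.frame(depth_mm = c(0, 30, 50), value = c(0, 0, 800)),
                 porosity = 0.95),
    profile_spec("DOC", data.frame(depth_mm = c(0, 25), value = c(2100, 300)),
                 porosity = 0.95)
  )
  for (spec in specs) {
    p <- gen_profile(spec, seed = 1)
    g <- steepest_gradient(p, window_pts = 2)
    f <- fick_flux(g, spec$porosity, spec$D_sed)
    expect_equal(f$J_diff, attr(p, "truth")$flux, tolerance = 1e-9)
  }
})

test_that("sulfide_flux_total sums the up and down fluxes around the maximum", {
  pk <- peak_profile(peak_mm = 30, peak_uM = 800, bottom_mm = 60, bottom_uM = 200)
  res <- sulfide_flux_total(pk, porosity = 0.95, window_pts = 2)
  expect_false(res$monotone)
  expect_equal(res$peak_depth_mm, 30)
  up <- 0.95 * 6.4e-10 * (800 / 30) * 8.64e7
  down <- 0.95 * 6.4e-10 * (600 / 30) * 8.64e7
  expect_equal(res$total, up + down, tolerance = 1e-9)
  expect_equal(res$total, res$J_up$magnitude + res$J_down$magnitude)

  # monotone increasing profile: single flux, flagged
  mono <- concentration_profile(seq(0, 20, 2), seq(0, 400, 40), "totalS",
                                porosity = 0.95)
  res <- sulfide_flux_total(mono, porosity = 0.95, window_pts = 2)
  expect_true(res$monotone)
  expect_equal(res$total, 0.95 * 6.4e-10 * 20 * 8.64e7, tolerance = 1e-9)
})

test_that("oxygen_penetration_depth interpolates, censors, and warns", {
  p <- gen_profile(o2_spec(6.7), seed = 1)
  opd <- oxygen_penetration_depth(p, detection_limit = 1)
  expect_equal(opd$opd_mm, 6.7 * 249 / 250, tolerance = 1e-9)
  expect_false(opd$censored)

  oxic <- concentration_profile(seq(0, 32), rep(250, 33), "O2", porosity = 0.65)
  opd <- oxygen_penetration_depth(oxic)
  expect_true(opd$censored)
  expect_equal(opd$opd_mm, 32)                      # reported as "> 32 mm"
  expect_output(print(opd), ">")

  anoxic <- concentration_profile(0:5, c(1, 0, 0, 0, 0, 0), "O2", porosity = 0.65)
  expect_warning(opd <- oxygen_penetration_depth(anoxic), "detection limit")
  expect_equal(opd$opd_mm, 0)
})

test_that("integrate_depth sums layers and interpolates gaps", {
  expect_equal(integrate_depth(0:9, rep(1e9, 10))$inventory, 1e10)
  # layers 10..1 nmol cm-3 d-1 -> 55 nmol cm-2 d-1 = 0.55 mmol m-2 d-1
  inv <- integrate_depth(0:9, 10:1)
  expect_equal(inv$inventory, 55)
  expect_equal(nmol_cm2_to_mmol_m2(inv$inventory), 0.55)
  # a missing layer between equal neighbours integrates as if present
  gap <- integrate_depth(c(0:3, 5:9), rep(7, 9))
  expect_equal(gap$inventory, 70)
  expect_equal(gap$filled, 1)
  expect_error(integrate_depth(0:9, 10:1, range = c(5, 5)), "range")
})

test_that("noisy-profile flux recovery stays within 10% median error", {
  # scaled-down version of the 500-seed acceptance property (50 seeds here)
  errs <- vapply(1:50, function(s) {
    p <- gen_profile(o2_spec(noise_sd = 2), seed = s)
    g <- steepest_gradient(p, window_pts = 3)
    f <- fick_flux(g, 0.65, 8.9e-10)
    abs(f$J_diff - attr(p, "truth")$flux) / abs(attr(p, "truth")$flux)
  }, numeric(1))
  expect_lt(median(errs), 0.10)
})
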