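# Synthetic-data generators. Every generator takes a spec object and a seed,
# is bit-reproducible for a given (spec, seed), and records its ground truth
# as a "truth" attribute so downstream recovery tests can compare against the
# designed values while reading only the observable part.

#' Specification of a synthetic microsensor profile
#'
#' Describes a piecewise-linear concentration-vs-depth profile with additive
#' i.i.d. Gaussian sensor noise, emulating ex situ microprofiles measured at
#' 1 mm resolution.
#'
#' @param analyte profile analyte (see [concentration_profile()]).
#' @param breakpoints data.frame with columns `depth_mm` (strictly
#'   increasing) and `value` defining the noise-free profile.
#' @param porosity matrix porosity.
#' @param noise_sd sensor noise sd, uM (>= 0).
#' @param points_per_mm sampling density (default 1, i.e. 1 mm resolution).
#' @param D_sed diffusion coefficient used for the ground-truth flux; default
#'   chosen per analyte from [wf_config()].
#' @return list of class `profile_spec`.
#' @export
profile_spec <- function(analyte, breakpoints, porosity, noise_sd = 0,
                         points_per_mm = 1, D_sed = NULL) {
  stopifnot(is.data.frame(breakpoints),
            all(c("depth_mm", "value") %in% names(breakpoints)),
            nrow(breakpoints) >= 2, noise_sd >= 0, points_per_mm > 0)
  if (is.unsorted(breakpoints$depth_mm, strictly = TRUE))
    stop("breakpoint depths must be strictly increasing")
  if (is.null(D_sed)) {
    cfg <- wf_config()
    D_sed <- switch(analyte, O2 = cfg$D_O2, H2S = , totalS = cfg$D_H2S,
                    DOC = cfg$D_DOC, 1e-9)
  }
  structure(list(analyte = analyte, breakpoints = breakpoints,
                 porosity = porosity, noise_sd = noise_sd,
                 points_per_mm = points_per_mm, D_sed = D_sed),
            class = "profile_spec")
}

#' Generate a synthetic microsensor profile
#'
#' Samples the piecewise-linear profile of a [profile_spec()] on a regular
#' depth grid and adds Gaussian noise. The ground truth stored in
#' `attr(x, "truth")` holds the segment slopes, the steepest positive and
#' negative gradients (uM/mm) restricted to depths >= 0, and the
#' corresponding Fick fluxes (mmol m-2 d-1) using the spec's porosity and
#' diffusion coefficient.
#'
#' @param spec a [profile_spec()].
#' @param seed integer seed (reproducible; the caller's RNG is untouched).
#' @return a [concentration_profile()] with attribute `truth`.
#' @export
gen_profile <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "profile_spec"))
  bp <- spec$breakpoints
  zmax <- bp$depth_mm[nrow(bp)]
  z <- seq(bp$depth_mm[1], zmax, by = 1 / spec$points_per_mm)
  if (z[length(z)] < zmax) z <- c(z, zmax)  # always sample the last breakpoint
  v0 <- approx(bp$depth_mm, bp$value, xout = z)$y
  v <- v0 + with_seed(seed, rnorm(length(z), 0, spec$noise_sd))
  if (spec$analyte != "pH") v <- pmax(v, 0)  # sensors report >= 0
  slopes <- diff(bp$value) / diff(bp$depth_mm)
  sub <- bp$depth_mm[-1] > 0                 # segments reaching below interface
  s_sub <- slopes[sub]
  up <- if (any(s_sub > 0)) max(s_sub) else 0
  down <- if (any(s_sub < 0)) min(s_sub) else 0
  flux_of <- function(g) if (g == 0) 0 else
    fick_flux(g, spec$porosity, spec$D_sed)$J_diff
  truth <- list(segment_slopes = slopes,
                gradient_up = up, gradient_down = down,
                steepest_gradient = if (abs(up) >= abs(down)) up else down,
                flux_up = flux_of(up), flux_down = flux_of(down),
                flux = flux_of(if (abs(up) >= abs(down)) up else down),
                porosity = spec$porosity, D_sed = spec$D_sed)
  out <- concentration_profile(z, v, spec$analyte, porosity = spec$porosity,
                               noise_tolerance_uM = Inf)
  attr(out, "truth") <- truth
  out
}

#' Generate a synthetic benthic chamber record
#'
#' A linear O2 drawdown with slope `-tou_true / (24 * water_height)` uM/h
#' plus Gaussian noise. With `curvature_after_h` set, the decline flattens
#' exponentially after that time (relaxation towards the concentration
#' reached then), emulating late-time chamber artefacts and exercising the
#' initial-window selection of [fit_initial_decline()].
#'
#' @param tou_true designed total oxygen uptake, mmol m-2 d-1.
#' @param water_height enclosed water height, m (chambers typically enclose
#'   0.10-0.15 m).
#' @param duration_h record length, h.
#' @param noise_sd sensor noise sd, uM.
#' @param dt_h sampling interval, h.
#' @param o2_start starting O2, uM (bottom-water default 250).
#' @param curvature_after_h optional onset time of late-time flattening, h.
#' @param seed integer seed.
#' @return a [chamber_series()] with attribute `truth` (`tou`, `slope`).
#' @export
gen_chamber <- function(tou_true, water_height = 0.12, duration_h = 8,
                        noise_sd = 0, dt_h = 0.1, o2_start = 250,
                        curvature_after_h = NULL, seed = NULL) {
  stopifnot(water_height > 0, duration_h > 0, noise_sd >= 0)
  t <- seq(0, duration_h, by = dt_h)
  slope <- -tou_true / (24 * water_height)
  y <- o2_start + slope * t
  if (!is.null(curvature_after_h)) {
    late <- t > curvature_after_h
    y0 <- o2_start + slope * curvature_after_h
    tau <- max(duration_h / 4, dt_h)
    y[late] <- y0 + slope * tau * (1 - exp(-(t[late] - curvature_after_h) / tau))
  }
  y <- y + with_seed(seed, rnorm(length(t), 0, noise_sd))
  out <- chamber_series(t, y, height_m = water_height)
  attr(out, "truth") <- list(tou = tou_true, slope = slope)
  out
}

#' Specification of a synthetic ARISA community
#'
#' True fragment lengths and relative intensities of a fingerprint, the PCR
#' replicate structure, the size-calling jitter of the capillary sequencer
#' and a per-replicate peak dropout probability.
#'
#' @param lengths true fragment lengths, bp (within the analytical range).
#' @param intensities true relative intensities (normalized to sum 1).
#' @param n_replicates PCR replicates per sample (default 3, amplified in
#'   triplicate).
#' @param size_call_sd Gaussian size-calling jitter sd, bp.
#' @param dropout_prob probability a true peak is missed in one replicate.
#' @return list of class `arisa_spec`.
#' @export
arisa_spec <- function(lengths, intensities = NULL, n_replicates = 3,
                       size_call_sd = 0.4, dropout_prob = 0) {
  if (is.null(intensities)) intensities <- rep(1 / length(lengths), length(lengths))
  stopifnot(length(lengths) == length(intensities), all(intensities > 0),
            size_call_sd >= 0, dropout_prob >= 0, dropout_prob < 1,
            n_replicates >= 1)
  if (any(lengths < 100 | lengths > 1000))
    stop("true fragment lengths must lie in [100, 1000] bp")
  structure(list(lengths = lengths, intensities = intensities / sum(intensities),
                 n_replicates = n_replicates, size_call_sd = size_call_sd,
                 dropout_prob = dropout_prob), class = "arisa_spec")
}

#' Generate synthetic ARISA peak profiles
#'
#' Draws per-replicate peak tables from an [arisa_spec()]: each true fragment
#' is retained with probability `1 - dropout_prob`, its called size is the
#' true length plus Gaussian jitter, and its area is the true relative
#' intensity scaled to a total of 10^5 fluorescence units. The ground truth
#' (`attr(x, "truth")`) records the true OTU id of every emitted peak.
#'
#' @param spec an [arisa_spec()].
#' @param sample_id sample label for the emitted peaks.
#' @param seed integer seed.
#' @return data.frame with columns `sample`, `replicate`, `size_bp`, `area`,
#'   plus attribute `truth` (data.frame with the true `otu` index and
#'   `true_size_bp` per peak).
#' @export
gen_arisa <- function(spec, sample_id = "S1", seed = NULL) {
  stopifnot(inherits(spec, "arisa_spec"))
  with_seed(seed, {
    rows <- lapply(seq_len(spec$n_replicates), function(r) {
      keep <- runif(length(spec$lengths)) >= spec$dropout_prob
      if (!any(keep)) return(NULL)
      data.frame(sample = sample_id, replicate = r,
                 size_bp = spec$lengths[keep] +
                   rnorm(sum(keep), 0, spec$size_call_sd),
                 area = spec$intensities[keep] * 1e5,
                 otu = which(keep))
    })
    d <- do.call(rbind, rows)
    truth <- d[c("otu")]
    truth$true_size_bp <- spec$lengths[d$otu]
    peaks <- d[c("sample", "replicate", "size_bp", "area")]
    attr(peaks, "truth") <- truth
    peaks
  })
}

#' Specification of a synthetic tag-sequence community
#'
#' A multi-sample community with a designed shared core: `n_core` OTUs
#' present in every sample, `n_unique` OTUs private to each sample, and
#' additional singleton OTUs (total count 1 in the whole dataset) at a
#' designed rate. Within each class, relative abundances follow a geometric
#' rank-abundance series with ratio `decay`, and the core receives a fixed
#' share (`core_mass`) of each sample's reads, emulating a dominant shared
#' community. Counts are multinomial draws.
#'
#' @param n_samples number of samples.
#' @param n_core shared-core OTUs (present in all samples by design).
#' @param n_unique private OTUs per sample.
#' @param reads_per_sample sequencing depth per sample.
#' @param core_mass expected fraction of reads in core OTUs.
#' @param decay geometric rank-abundance ratio in (0, 1].
#' @param singleton_rate designed fraction of all OTUs that are singletons.
#' @param taxonomy_pool character vector of taxonomy paths to draw from.
#' @return list of class `community_spec`. The designed shared fraction of
#'   the pooled OTU list (ignoring singletons) is
#'   `n_core / (n_core + n_samples * n_unique)`.
#' @export
community_spec <- function(n_samples = 3, n_core = 18, n_unique = 27,
                           reads_per_sample = 5000, core_mass = 0.72,
                           decay = 0.9, singleton_rate = 0.36,
                           taxonomy_pool = wf_taxonomy_pool()) {
  stopifnot(n_samples >= 1, n_core >= 0, n_unique >= 0, reads_per_sample >= 1,
            core_mass > 0, core_mass <= 1, decay > 0, decay <= 1,
            singleton_rate >= 0, singleton_rate < 1)
  structure(list(n_samples = n_samples, n_core = n_core, n_unique = n_unique,
                 reads_per_sample = reads_per_sample, core_mass = core_mass,
                 decay = decay, singleton_rate = singleton_rate,
                 taxonomy_pool = taxonomy_pool), class = "community_spec")
}

#' Default taxonomy pool for synthetic communities
#'
#' Class-level paths of taxa typical for wood-fall and deep-sea sediment
#' bacterial communities; purely synthetic assignments for generated OTUs.
#'
#' @return character vector of semicolon-separated taxonomy paths.
#' @export
wf_taxonomy_pool <- function() {
  classes <- c("Gammaproteobacteria", "Alphaproteobacteria", "Deltaproteobacteria",
               "Betaproteobacteria", "Epsilonproteobacteria", "Flavobacteria",
               "Actinobacteria", "Clostridia", "Sphingobacteria", "Bacteroidia",
               "Planctomycetacia", "Acidobacteria", "Holophagae", "Bacilli",
               "Verrucomicrobiae")
  phyla <- c(rep("Proteobacteria", 5), "Bacteroidetes", "Actinobacteria",
             "Firmicutes", "Bacteroidetes", "Bacteroidetes", "Planctomycetes",
             "Acidobacteria", "Acidobacteria", "Firmicutes", "Verrucomicrobia")
  paste("Bacteria", phyla, classes, sep = ";")
}

#' Generate a synthetic tag-sequence OTU table
#'
#' Draws per-sample counts multinomially from the designed abundance vectors
#' of a [community_spec()], then appends singleton OTUs (one read each,
#' assigned to random samples) so that the designed fraction of all OTUs are
#' singletons. `attr(x, "truth")` records the core and private OTU ids and
#' the designed shared fraction.
#'
#' @param spec a [community_spec()].
#' @param seed integer seed.
#' @return a [tag_table()] (OTUs x samples) with attributes `taxonomy` and
#'   `truth`.
#' @export
gen_tag_table <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "community_spec"))
  S <- spec$n_samples
  core_ids <- if (spec$n_core) paste0("OTU_core_", seq_len(spec$n_core)) else character()
  uniq_ids <- lapply(seq_len(S), function(s)
    if (spec$n_unique) paste0("OTU_s", s, "_", seq_len(spec$n_unique)) else character())
  n_design <- spec$n_core + S * spec$n_unique
  n_single <- round(spec$singleton_rate / (1 - spec$singleton_rate) * n_design)
  single_ids <- if (n_single) paste0("OTU_single_", seq_len(n_single)) else character()
  ids <- c(core_ids, unlist(uniq_ids), single_ids)
  geom <- function(n) if (n) spec$decay^(seq_len(n) - 1) else numeric()
  core_w <- geom(spec$n_core)
  uniq_w <- geom(spec$n_unique)
  with_seed(seed, {
    counts <- matrix(0L, nrow = length(ids), ncol = S,
                     dimnames = list(ids, paste0("sample", seq_len(S))))
    for (s in seq_len(S)) {
      p <- numeric(length(ids))
      names(p) <- ids
      if (spec$n_core) {
        cm <- if (spec$n_unique) spec$core_mass else 1
        p[core_ids] <- cm * core_w / sum(core_w)
      }
      if (spec$n_unique)
        p[uniq_ids[[s]]] <- (1 - if (spec$n_core) spec$core_mass else 0) *
          uniq_w / sum(uniq_w)
      counts[, s] <- as.integer(rmultinom(1, spec$reads_per_sample, p))
    }
    if (n_single) {
      hosts <- sample.int(S, n_single, replace = TRUE)
      for (k in seq_len(n_single))
        counts[single_ids[k], hosts[k]] <- 1L
    }
    tax <- setNames(sample(spec$taxonomy_pool, length(ids), replace = TRUE), ids)
    out <- tag_table(counts, taxonomy = tax)
    attr(out, "truth") <- list(
      core = core_ids, unique = uniq_ids, singletons = single_ids,
      designed_shared_fraction = if (n_design) spec$n_core / n_design else NA_real_,
      designed_core_mass = spec$core_mass)
    out
  })
}

#' Generate a synthetic radiotracer incubation table
#'
#' Layer-wise tracer fractions declining geometrically from a surface
#' maximum, with constant pool, porosity and incubation time; the ground
#' truth records the designed depth-integrated rate.
#'
#' @param n_layers number of 1-cm layers.
#' @param fraction_top tracer product fraction of the top layer.
#' @param decay geometric decline per layer.
#' @param pool_mM substrate pool, mM.
#' @param porosity porosity.
#' @param time_h incubation time, h.
#' @param alpha fractionation factor.
#' @param noise_cv multiplicative lognormal noise CV on fractions.
#' @param seed integer seed.
#' @return data.frame in [read_tracer()] layout with attribute `truth`
#'   (`integrated_mmol_m2_d`).
#' @export
gen_tracer <- function(n_layers = 10, fraction_top = 0.002, decay = 0.7,
                       pool_mM = 30, porosity = 0.8, time_h = 12,
                       alpha = wf_config()$alpha_SR, noise_cv = 0, seed = NULL) {
  f0 <- fraction_top * decay^(seq_len(n_layers) - 1)
  f <- with_seed(seed, f0 * exp(rnorm(n_layers, 0, noise_cv)))
  d <- data.frame(depth_cm = seq_len(n_layers) - 1, fraction = f,
                  pool = pool_mM, porosity = porosity, time_h = time_h)
  true_rates <- layer_rate(f0, pool_mM, porosity, time_h, alpha)
  attr(d, "truth") <- list(
    integrated_mmol_m2_d = nmol_cm2_to_mmol_m2(sum(true_rates)))
  d
}
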