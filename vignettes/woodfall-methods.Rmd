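---
title: "Methods: biogeochemistry and bacterial communities of deep-sea wood falls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: biogeochemistry and bacterial communities of deep-sea wood falls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(woodfall)
```

## The system

A wood log sunk to the deep seafloor is a concentrated pulse of organic
carbon in an otherwise starved environment. Wood-boring bivalves
(*Xylophaga*) shred it into chips and fecal matter that blanket the
surrounding sediment; microbial degradation of this material draws down
oxygen, and once the chip layer turns anoxic, sulfate reducers take over and
a sulfidic niche develops — the kind of habitat that chemosynthetic fauna
(e.g. *Idas* mussels) colonize. This package implements the quantitative
chain of such a study: microsensor fluxes, chamber respiration, radiotracer
rates, a carbon persistence budget, ARISA fingerprint processing, and
community statistics, plus synthetic-data generators that make the whole
chain testable without any field data.

Unit conventions are fixed package-wide: concentrations in µM, depths in mm
positive downward with the interface at 0, fluxes in mmol m⁻² d⁻¹, layer
rates in nmol cm⁻³ d⁻¹. Conversion constants live in `wf_units` and are
tested; a gradient of 1 µM/mm is numerically 1 mol/m⁴, so Fick's law needs
only the single factor 8.64×10⁷ (s/d × mmol/mol) to come out in
mmol m⁻² d⁻¹.

## Diffusive fluxes from microsensor profiles

Fluxes follow Fick's first law, $J = \varphi\, D_{sed}\, \frac{dc}{dz}$,
evaluated on the *steepest porewater gradient* below the interface.
`steepest_gradient()` slides a $k$-point least-squares window (default
$k = 3$; $k = 2$ reproduces finite differences) over the sub-interface
points only — the diffusive boundary layer above 0 mm is excluded because
the quantity of interest is the porewater gradient in the sediment. Ties are
resolved toward the shallower window (within a 10⁻⁹ relative slope
tolerance, so exactly linear profiles report their shallowest window).

Default diffusion coefficients are 8.9×10⁻¹⁰ m² s⁻¹ for O₂ and
6.4×10⁻¹⁰ m² s⁻¹ for sulfide; for DOC, 6.2×10⁻¹¹ m² s⁻¹ under the
assumption that wood-derived DOC is of high molecular weight. Porosities
default to 0.95 for wood-chip layers and 0.65 for sediment.

**Sulfide speciation.** The amperometric sensor sees only H₂S; the ambient
pool also contains HS⁻. `speciate_sulfide()` applies
$\Sigma H_2S = [H_2S]\,(1 + 10^{pH - pK_1})$ on the H₂S depth grid
(pH interpolated when grids differ). S²⁻ is neglected — pK₂ lies far above
seawater pH. The underlying study cites a seawater pK₁ formulation without
printing a number, so pK₁ is a configuration parameter (default 6.98, a
typical seawater value at the study's 13 °C and high salinity); every
speciated profile records the value used.

**Total sulfide flux.** Sulfide produced at depth diffuses both up and down
from the concentration maximum; `sulfide_flux_total()` reports the sum of
the steepest upward flux above the peak and downward flux below it.
Monotone profiles return the single flux, flagged.

**Oxygen penetration depth** is the linearly interpolated first crossing
below a 1 µM detection limit (configurable); profiles that never cross
return the deepest depth as an open bound ("> 32 mm"-style), matching how
fully oxygenated reference sediments are reported.

**Replicate handling.** Cores are typically profiled in triplicate. Whether
the original workflow averaged profiles before or after gradient extraction
is not stated; this package computes per-profile fluxes and reports mean ±
sd across replicates (the order matters for noisy profiles because the
steepest-window search is a maximum, hence biased slightly upward by noise).

## Chamber oxygen uptake

Total oxygen uptake (TOU) integrates the respiration of the whole benthic
community: a chamber encloses 284 cm² of sediment under 10–15 cm of bottom
water and O₂ is logged over hours. Only the *initial linear decrease*
carries the flux; `fit_initial_decline()` takes the longest prefix window
whose least-squares fit reaches R² ≥ 0.98 with at least 10 points (both
configurable — the source describes the rule only qualitatively, so the
thresholds are explicit parameters), falling back to the first 10 points
with a warning when nothing qualifies. Then
$TOU = -\text{slope} \times h \times 24$ with the water height $h$ in m
(supplied, not inferred — it is determined visually in the field). A
positive slope is reported as a negative TOU flagged "efflux" rather than
silently clipped.

## Radiotracer turnover rates

Whole-core incubations inject ³⁵S-sulfate (or ¹⁴CH₄) in 1-cm intervals; the
measured quantity per layer is the fraction $a$ of tracer recovered in the
product pool. The cited rate formula is not printed in the study, so the
standard whole-core turnover form is implemented with every parameter
explicit:
$rate = a \cdot C \cdot \varphi \cdot \alpha / t$, pools in mM
(1 mM = 1000 nmol cm⁻³), times in hours, rates in nmol cm⁻³ d⁻¹.
Fractionation defaults: α = 1.06 for sulfate reduction, 1.0 for AOM. A zero
tracer fraction (no AOM detected — the study's actual outcome) is a
first-class input producing rate 0. `integrate_rates()` integrates layers
over 0–10 cm (interior gaps interpolated and flagged) and summarizes
triplicate subcores as mean ± sd.

## The carbon persistence budget

The budget is static: a one-time carbon stock divided by the sum of annual
sinks. Defaults describe one experiment: 120,000 cm³ of Douglas fir (dry
density 0.51 g cm⁻³, carbon fraction 0.5 → 30.6 kg C), sinks over the
~5.5 m² chip-covered seafloor:

* **Mineralization** — TOU of 25 mmol m⁻² d⁻¹ with a respiratory quotient
  of 1 (1 mol O₂ ≡ 1 mol C; the printed 25 → 600 g C yr⁻¹ arithmetic
  implies it; configurable), ≈ 603 g C yr⁻¹.
* **DOC export** — fluxes 0.38–1.31 mmol m⁻² d⁻¹ → ≈ 9.2–31.6 g C yr⁻¹.
  The source prints 11 and 33 g C yr⁻¹ for the same fluxes; the computed
  values are reported and the discrepancy documented rather than tuned away.
* **Bacterial biomass** — mean cell density on the one-year woods
  (8.2, 3.0, 3.0 ×10⁸ cells g⁻¹) × wood mass × 0.07 µm³ per cell ×
  3×10⁻¹³ g C µm⁻³ ≈ 0.61 g C yr⁻¹.
* **Faunal biomass** — the wood-borer allometry behind the published
  estimate is not reproducible from printed values, so it enters as a
  user-supplied range, default 60–427 g C yr⁻¹.

Ranges contribute midpoints to the central scenario, endpoints to the
low-/high-sink scenarios. The central scenario gives ≈ 35 years.

```{r budget}
carbon_budget()
```

**Chip-area geometry.** The ~5.5 m² chip footprint is reconstructed as a
stadium of radius $d/2 + w$ around the log axis minus the log's own stadium
footprint: $L(d + 2w) + \pi(d/2 + w)^2 - Ld - \pi(d/2)^2$. An alternative
reconstruction omits the $\pi(d/2)^2$ term, but then the band would not vanish as
$w \to 0$; the implemented form satisfies that limit and still reproduces
5.5 m² (it gives 5.47) from $L = 2$ m, $d = 0.3$ m, $w = 0.75$ m. Both are
reconstructions; the original text states only the radius and the result.

**Station geometry.** Distances use the haversine on a 6371 km sphere —
the printed separations carry 2 significant figures, so ellipsoid accuracy
would be spurious precision. The packaged station table reproduces the
printed 410 m between wood#1 and wood#5; it also implies ~96 m between
wood#2 and wood#6 where the source prints 31 m. The table is kept verbatim
and the inconsistency documented, not "fixed".

## ARISA fingerprints

Capillary electrophoresis calls the same 16S–23S spacer fragment at
slightly different lengths between runs. `bin_peaks()` applies the
fixed-window strategy: half-open 2-bp bins over the 100–1000 bp analytical
range (the internal size standard's span), boundary peaks joining the
higher bin, co-binned peaks summed. `replicate_consensus()` applies the
inclusive presence rule — an OTU is present if it appears in ≥ 1 of the 3
PCR replicates — with the consensus intensity the mean over replicates
where present. `relative_intensities()` divides each bin by the profile
total.

The bin *frame* matters: a fragment sitting on a bin boundary is split
between bins by sub-bp jitter no matter the bin width. By default the frame
anchors at the low edge of the range; `arisa_otu_table(scan_offset = TRUE)`
scans offsets in 0.1-bp steps and picks the one maximizing mean
between-replicate similarity (1 − Bray–Curtis), which recovers a
deliberately shifted frame in tests. The exact objective of the original
interactive binning tool is not published; both modes are provided. No
relative-intensity floor is applied by default.

## Community statistics

`bray_curtis()` implements
$BC(x,y) = \sum_i |x_i - y_i| / \sum_i (x_i + y_i)$ (tested against the
vegan implementation and the $1 - \sum \min$ identity on normalized rows).
ARISA consensus vectors enter as relative intensities and tag tables as
relative counts through the same code path.

`nmds_ordination()` wraps `vegan::monoMDS` (global NMDS, Kruskal stress-1,
primary tie treatment) in an explicit best-of-*n* random-start loop
(default 20) so results are reproducible from a seed. An all-equal
dissimilarity matrix is flagged degenerate.

`anosim_test()` is implemented in-package:
$R = (\bar r_{between} - \bar r_{within}) / (M/2)$ on the average-ranked
dissimilarities, $M = n(n-1)/2$. Random-permutation p-values use the
add-one correction $p = (1 + \#\{R_\pi \ge R\})/(1 + n_\pi)$ (default 999
permutations) so p is never 0; `exhaustive = TRUE` enumerates all distinct
label permutations instead (feasible to n ≈ 8) and then uses the exact tail
fraction. The statistic matches `vegan::anosim` to machine precision in
tests, and the permutation distribution matches brute-force subset
enumeration. `bonferroni()` provides the multiple-testing correction used
with grouped ANOSIM tables.

**Shared OTUs.** Sequencing depth differs between samples, so sharing is
assessed by repeated subsampling *without replacement* to the smallest
sample's depth (the source says only "re-samplings based on the smallest
dataset"; without replacement is standard rarefaction practice). Per
iteration the pooled OTU list is partitioned into shared-by-all, unique-to-
one and partially shared; reported percentages are means over 1000
iterations. Because it is ambiguous whether the published
fraction-of-sequences-in-shared-OTUs was computed on resampled or full
counts, both are reported (`shared_seq_pct`, `shared_seq_full_pct`).
Singletons (total count 1 in the whole dataset) are removed first via
`remove_singletons()`, which reports the removed fraction.
`pairwise_shared_fraction()` applies the same scheme to sample pairs, and
`taxon_composition()` aggregates relative abundances at phylum/class/genus
rank with an optional assigned-at-rank-only filter for genus lists.

## What the synthetic generators emulate — and what they do not

Each generator states a ground truth and adds the simplest noise model
consistent with the instrument:

* `gen_profile()` — piecewise-linear reaction-diffusion profiles at 1 mm
  resolution with i.i.d. Gaussian sensor noise (default designs use the
  observed bottom-water O₂ of 250 µM and oxygen penetration of a few mm).
  Real profiles have curvature from distributed reaction terms and
  correlated sensor drift; a green recovery test establishes correct
  gradient/flux arithmetic, not robustness to model misspecification.
* `gen_chamber()` — linear drawdown with slope −TOU/(24 h) plus Gaussian
  noise, optional late-time exponential flattening to exercise window
  selection. No electrode drift or stirring artefacts.
* `gen_arisa()` — true fragment lengths with Gaussian size-calling jitter
  (default σ = 0.4 bp) and per-replicate dropout. No raw electropherogram
  simulation: peaks arrive already called. The binning-robustness
  acceptance property uses mid-bin (odd-integer) fragment lengths: with
  σ = 0.4 bp a boundary-straddling fragment cannot stay in one bin ≥ 90%
  of the time, so the stated robustness presumes a well-chosen frame — which
  is exactly what the offset scan provides and what is tested separately.
* `gen_tag_table()` — multinomial counts over designed per-sample abundance
  vectors: 18 core OTUs shared by all 3 samples plus 27 private OTUs each
  (designed shared fraction 18/99 ≈ 18%), the core carrying 72% of reads
  via a geometric rank-abundance series (ratio 0.9), 5000 reads per sample,
  plus singletons at a designed 36% of all OTUs — numbers chosen to mirror
  the observed community structure. No partially-shared design class, no
  taxonomic correlation structure, no chimeras/sequencing error.

All generators are pure functions of (spec, seed) and restore the caller's
RNG state.

## Numerical choices and degenerate inputs

* Constant profiles yield gradient 0 with a `degenerate` flag; all-singleton
  tables raise an error; zero-sum community rows are an error naming the
  sample; zero total sinks yield `Inf` persistence, flagged.
* Molar mass of carbon 12.011 g/mol (printed values use 12 within
  rounding); 365-day year.
* Acceptance tolerances follow the printed precision of each target value
  (e.g. 410 m at 10-m rounding, 5.5 m² at one decimal, 0.6 g C yr⁻¹ at one
  decimal).

## Known limitations

* No sensor calibration, 2-D/3-D transport, or wood-decay kinetics: the
  budget is static, first-order-free.
* The tracer-rate formula is the standard whole-core form with explicit
  parameters; if the (uncited, unprinted) original differs in porosity
  placement, adjust inputs accordingly — every factor is exposed.
* NMDS relies on vegan's monotone regression; only the start strategy and
  seeding are owned by this package.
* The CLI covers the documented subcommands with flat key:value configs; it
  is a thin layer over the exported functions and is tested through them.
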