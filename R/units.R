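# Unit conventions (fixed package-wide):
#   concentration uM, depth mm (positive downward), flux mmol m-2 d-1,
#   layer rate nmol cm-3 d-1, pool concentration mM, time h, distance m.
# A gradient of 1 uM/mm equals 1 mol/m4 exactly (1e-3 mol m-3 / 1e-3 m),
# so the only conversion in Fick's law is mol m-2 s-1 -> mmol m-2 d-1.

#' Unit conversion constants and helpers
#'
#' Centralized conversion constants used throughout the package, exposed so
#' that every flux and rate computation shares one tested set of factors.
#'
#' @format `wf_units` is a named list with elements:
#' \describe{
#'   \item{flux_mol_s_to_mmol_d}{86400 s/d x 1000 mmol/mol = 8.64e7; converts
#'     mol m-2 s-1 to mmol m-2 d-1.}
#'   \item{grad_uM_mm_to_mol_m4}{1; a uM/mm gradient is numerically a mol/m4
#'     gradient.}
#'   \item{mM_to_nmol_cm3}{1000; 1 mM = 1 umol/cm3 = 1000 nmol/cm3.}
#'   \item{nmol_cm2_to_mmol_m2}{0.01; 1e4 cm2/m2 x 1e-6 mmol/nmol.}
#'   \item{earth_radius_m}{6.371e6; spherical Earth radius.}
#' }
#' @export
wf_units <- list(
  flux_mol_s_to_mmol_d = 86400 * 1000,
  grad_uM_mm_to_mol_m4 = 1,
  mM_to_nmol_cm3       = 1000,
  nmol_cm2_to_mmol_m2  = 1e4 * 1e-6,
  earth_radius_m       = 6371e3
)

#' @rdname wf_units
#' @param x numeric vector of areal rates in nmol cm-2 d-1.
#' @return `nmol_cm2_to_mmol_m2()`: the same rates in mmol m-2 d-1.
#' @export
nmol_cm2_to_mmol_m2 <- function(x) x * wf_units$nmol_cm2_to_mmol_m2

#' @rdname wf_units
#' @param conc_mM numeric vector of pool concentrations in mM.
#' @return `mM_to_nmol_cm3()`: concentrations in nmol cm-3.
#' @export
mM_to_nmol_cm3 <- function(conc_mM) conc_mM * wf_units$mM_to_nmol_cm3

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. seed = NULL evaluates code with the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  env <- globalenv()
  has_old <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  code
}
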