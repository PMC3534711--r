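#' Default run configuration
#'
#' Returns the named list of package-wide defaults. Every value can be
#' overridden by argument; defaults follow the study design this package
#' supports (Eastern Mediterranean wood-fall experiments at 1690 m, 13 degC).
#'
#' @param ... named overrides; unknown names are an error.
#' @return named list of parameters:
#' \describe{
#'   \item{D_O2, D_H2S, D_DOC}{sediment diffusion coefficients, m2 s-1
#'     (8.9e-10, 6.4e-10 and 6.2e-11 respectively; the DOC value assumes
#'     high-molecular-weight wood leachate).}
#'   \item{porosity_sediment, porosity_woodchip}{0.65 and 0.95.}
#'   \item{pK1}{first dissociation constant of H2S in seawater, default 6.98
#'     (typical at 13 degC, salinity ~39).}
#'   \item{detection_limit_uM}{O2 microsensor detection limit for penetration
#'     depth, 1 uM.}
#'   \item{gradient_window}{points per least-squares window in the steepest
#'     gradient search, 3.}
#'   \item{r2_min, min_points}{chamber initial-linear-decline fit controls.}
#'   \item{alpha_SR, alpha_AOM}{radiotracer fractionation factors (1.06 for
#'     35S sulfate reduction, 1.0 for 14C AOM).}
#'   \item{chamber_area_cm2}{benthic chamber footprint, 284 cm2.}
#'   \item{bin_size_bp, size_range_bp}{ARISA fixed-window bin width (2 bp) and
#'     analytical range (100-1000 bp, MapMarker 1000 standard).}
#'   \item{n_resample, n_perm}{shared-OTU resampling iterations (1000) and
#'     ANOSIM permutations (999).}
#'   \item{respiratory_quotient}{mol C mineralized per mol O2 consumed, 1.}
#'   \item{molar_mass_C}{12.011 g/mol.}
#' }
#' @export
wf_config <- function(...) {
  cfg <- list(
    D_O2 = 8.9e-10, D_H2S = 6.4e-10, D_DOC = 6.2e-11,
    porosity_sediment = 0.65, porosity_woodchip = 0.95,
    pK1 = 6.98,
    detection_limit_uM = 1,
    gradient_window = 3,
    r2_min = 0.98, min_points = 10,
    alpha_SR = 1.06, alpha_AOM = 1.0,
    chamber_area_cm2 = 284,
    bin_size_bp = 2, size_range_bp = c(100, 1000),
    n_resample = 1000, n_perm = 999,
    respiratory_quotient = 1,
    molar_mass_C = 12.011
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad)) stop("unknown config parameter(s): ", paste(bad, collapse = ", "))
    cfg[names(dots)] <- dots
  }
  cfg
}

#' Read / write a flat key-value configuration file
#'
#' The file format is one `key: value` pair per line (YAML-style scalars
#' only); `#` starts a comment. Values are parsed as numeric where possible,
#' comma-separated numerics become vectors. Keys must be known config
#' parameters (see [wf_config()]).
#'
#' @param path file path.
#' @return `read_config()`: a full config list with file overrides applied.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  overrides <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9_]+)\\s*:\\s*(.+)$", ln))[[1]]
    if (length(m) != 3) stop("malformed config line: ", sQuote(ln))
    val <- trimws(strsplit(m[3], ",")[[1]])
    num <- suppressWarnings(as.numeric(val))
    overrides[[m[2]]] <- if (anyNA(num)) val else num
  }
  do.call(wf_config, overrides)
}

#' @rdname read_config
#' @param cfg a config list from [wf_config()].
#' @return `write_config()`: `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  fmt <- vapply(cfg, function(v) paste(format(v, digits = 15), collapse = ", "), "")
  writeLines(paste0(names(cfg), ": ", fmt), path)
  invisible(path)
}

# Short hex digest of a config (or any R object) for replayable logging.
config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}

wf_log_level <- new.env(parent = emptyenv())
wf_log_level$level <- "info"

#' Set package log verbosity
#' @param level one of "debug", "info", "warn", "quiet".
#' @export
wf_set_log_level <- function(level = c("info", "debug", "warn", "quiet")) {
  wf_log_level$level <- match.arg(level)
  invisible(wf_log_level$level)
}

wf_log <- function(..., level = "info") {
  order <- c(debug = 1, info = 2, warn = 3, quiet = 4)
  if (order[[level]] >= order[[wf_log_level$level]] && wf_log_level$level != "quiet")
    message("[woodfall ", level, "] ", ...)
  invisible(NULL)
}
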