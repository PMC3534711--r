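#' Concentration-vs-depth microsensor profile
#'
#' The basic substrate of all flux computations: analyte values on a strictly
#' increasing depth grid in mm below the sediment-water (or chip-water)
#' interface, positive downward; points above the interface (diffusive
#' boundary layer) carry negative depths.
#'
#' @param depth_mm strictly increasing numeric depths, mm.
#' @param value concentrations in uM (pH profiles: pH units).
#' @param analyte one of "O2", "H2S", "pH", "DOC", "totalS".
#' @param porosity scalar or per-point porosity in (0, 1].
#' @param temperature,salinity optional context (degC, PSU).
#' @param noise_tolerance_uM small negative excursions down to minus this
#'   value are tolerated as sensor noise for non-pH analytes (default 5 uM).
#' @return object of class `concentration_profile` (a list with the fields
#'   above).
#' @export
concentration_profile <- function(depth_mm, value, analyte = c("O2", "H2S", "pH", "DOC", "totalS"),
                                  porosity = NA_real_, temperature = NULL,
                                  salinity = NULL, noise_tolerance_uM = 5) {
  analyte <- match.arg(analyte)
  stopifnot(length(depth_mm) == length(value), length(depth_mm) >= 1)
  if (is.unsorted(depth_mm, strictly = TRUE)) stop("depths must be strictly increasing")
  if (!all(is.na(porosity)) && (any(porosity <= 0, na.rm = TRUE) || any(porosity > 1, na.rm = TRUE)))
    stop("porosity must lie in (0, 1]")
  if (analyte != "pH" && any(value < -noise_tolerance_uM))
    stop(analyte, " concentrations below noise tolerance (", -noise_tolerance_uM, " uM)")
  structure(list(depth_mm = as.numeric(depth_mm), value = as.numeric(value)),
            analyte = analyte, porosity = porosity,
            temperature = temperature, salinity = salinity,
            class = "concentration_profile")
}

#' @export
print.concentration_profile <- function(x, ...) {
  cat("<concentration_profile> ", attr(x, "analyte"), ": ",
      length(x$depth_mm), " points, ",
      format(min(x$depth_mm)), " to ", format(max(x$depth_mm)), " mm\n", sep = "")
  invisible(x)
}

#' Total sulfide from measured H2S and pH
#'
#' Amperometric microsensors measure only the protonated H2S species; the
#' ambient pool also contains HS-. At each depth the total is
#' `sum H2S = [H2S] * (1 + 10^(pH - pK1))` from the first dissociation
#' equilibrium; S2- is neglected (pK2 far above seawater pH).
#'
#' pH values are linearly interpolated onto the H2S depth grid when the grids
#' differ; H2S depths outside the pH profile's span are dropped with a
#' warning.
#'
#' @param h2s_profile,ph_profile [concentration_profile()]s of analyte "H2S"
#'   and "pH".
#' @param pK1 first dissociation constant of H2S in seawater (default from
#'   [wf_config()]).
#' @return a `concentration_profile` of analyte "totalS" in uM.
#' @examples
#' h2s <- concentration_profile(0:5, rep(100, 6), "H2S", porosity = 0.95)
#' ph  <- concentration_profile(0:5, rep(6.98, 6), "pH")
#' speciate_sulfide(h2s, ph, pK1 = 6.98)$value  # 200 uM everywhere
#' @export
speciate_sulfide <- function(h2s_profile, ph_profile, pK1 = wf_config()$pK1) {
  stopifnot(inherits(h2s_profile, "concentration_profile"),
            inherits(ph_profile, "concentration_profile"), pK1 > 0)
  if (attr(h2s_profile, "analyte") != "H2S" || attr(ph_profile, "analyte") != "pH")
    stop("expected an H2S profile and a pH profile")
  z <- h2s_profile$depth_mm
  if (identical(z, ph_profile$depth_mm)) {
    ph <- ph_profile$value
  } else {
    ph <- approx(ph_profile$depth_mm, ph_profile$value, xout = z, rule = 1)$y
  }
  keep <- !is.na(ph)
  if (!any(keep)) stop("pH and H2S depth grids cannot be aligned")
  if (!all(keep))
    warning(sum(!keep), " depth(s) outside the pH profile span dropped")
  tot <- h2s_profile$value[keep] * (1 + 10^(ph[keep] - pK1))
  out <- concentration_profile(z[keep], tot, "totalS",
                               porosity = attr(h2s_profile, "porosity"),
                               temperature = attr(h2s_profile, "temperature"),
                               salinity = attr(h2s_profile, "salinity"))
  attr(out, "pK1") <- pK1
  out
}

# least-squares slope of y on x (exact for 2 points); x strictly increasing
ls_slope <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sum((x - mx)^2)
}

#' Steepest porewater gradient of a profile
#'
#' Slides a `window_pts`-point window over the sub-interface part of the
#' profile (depth >= 0; the diffusive boundary layer is excluded) and returns
#' the least-squares slope of maximal magnitude, restricted to the requested
#' sign. Direction "up" selects positive slopes (concentration increasing
#' with depth, hence an upward-diffusing analyte), "down" negative slopes;
#' "both" returns the single steepest of either sign. Ties are broken in
#' favour of the shallower window.
#'
#' @param profile a [concentration_profile()].
#' @param window_pts points per window, >= 2 (default 3; 2 reproduces finite
#'   differences).
#' @param direction "up", "down" or "both".
#' @return list of class `gradient_result`: `slope` (uM/mm), `window`
#'   (top/bottom depth, mm), `n`, `direction`, `degenerate` (TRUE when the
#'   profile is constant and the slope 0).
#' @export
steepest_gradient <- function(profile, window_pts = wf_config()$gradient_window,
                              direction = c("both", "up", "down")) {
  direction <- match.arg(direction)
  stopifnot(inherits(profile, "concentration_profile"), window_pts >= 2)
  sub <- profile$depth_mm >= 0
  z <- profile$depth_mm[sub]
  v <- profile$value[sub]
  n <- length(z)
  if (n < window_pts)
    stop("need at least ", window_pts, " points below the interface, have ", n)
  slopes <- vapply(seq_len(n - window_pts + 1), function(i) {
    idx <- i:(i + window_pts - 1)
    ls_slope(z[idx], v[idx])
  }, numeric(1))
  cand <- switch(direction,
    up   = which(slopes > 0),
    down = which(slopes < 0),
    both = seq_along(slopes))
  degenerate <- FALSE
  if (!length(cand) || all(slopes[cand] == 0)) {
    best <- 1L
    slope <- 0
    degenerate <- TRUE
  } else {
    amax <- max(abs(slopes[cand]))
    # shallowest window wins ties (within floating-point wobble)
    best <- cand[abs(slopes[cand]) >= amax * (1 - 1e-9)][1]
    slope <- slopes[best]
  }
  structure(list(slope = slope,
                 window = c(top = z[best], bottom = z[best + window_pts - 1]),
                 n = window_pts, direction = direction, degenerate = degenerate),
            class = "gradient_result")
}

#' Diffusive flux by Fick's first law
#'
#' `J_diff = phi * D_sed * dc/dz`, with the gradient in uM/mm (numerically
#' equal to mol/m4) and the result converted to mmol m-2 d-1. The sign of
#' `J_diff` follows the sign of the gradient; `magnitude` gives `|J_diff|`,
#' which is what flux tables usually report.
#'
#' @param gradient slope in uM/mm, or a `gradient_result` from
#'   [steepest_gradient()].
#' @param porosity sediment/matrix porosity in (0, 1].
#' @param D_sed sediment diffusion coefficient, m2 s-1 (defaults per analyte
#'   in [wf_config()]: O2 8.9e-10, sulfide 6.4e-10, DOC 6.2e-11).
#' @param analyte optional label stored in the result.
#' @return list of class `flux_result`: `J_diff` and `magnitude`
#'   (mmol m-2 d-1), `gradient` (uM/mm = mol/m4), `porosity`, `D_sed`,
#'   `window` (mm, when a `gradient_result` was supplied), `analyte`.
#' @examples
#' fick_flux(50, porosity = 0.65, D_sed = 8.9e-10)$magnitude # 2.50 mmol m-2 d-1
#' @export
fick_flux <- function(gradient, porosity, D_sed, analyte = NULL) {
  window <- c(top = NA_real_, bottom = NA_real_)
  if (inherits(gradient, "gradient_result")) {
    window <- gradient$window
    gradient <- gradient$slope
  }
  stopifnot(is.numeric(gradient), length(gradient) == 1,
            porosity > 0, porosity <= 1, D_sed > 0)
  grad_mol_m4 <- gradient * wf_units$grad_uM_mm_to_mol_m4
  J <- porosity * D_sed * grad_mol_m4 * wf_units$flux_mol_s_to_mmol_d
  structure(list(J_diff = J, magnitude = abs(J), gradient = grad_mol_m4,
                 porosity = porosity, D_sed = D_sed, window = window,
                 analyte = analyte),
            class = "flux_result")
}

#' @export
print.flux_result <- function(x, ...) {
  cat("<flux_result>", if (!is.null(x$analyte)) x$analyte else "",
      format(x$J_diff, digits = 4), "mmol m-2 d-1 (phi =", x$porosity,
      ", D_sed =", format(x$D_sed), ")\n")
  invisible(x)
}

#' Total sulfide flux around a subsurface maximum
#'
#' Sulfide produced at depth diffuses both upward and downward away from the
#' concentration maximum; the total source flux is the sum of the steepest
#' upward and downward fluxes bracketing the maximum. Monotone profiles yield
#' a single flux, flagged `monotone = TRUE`.
#'
#' @param profile a "totalS" (or "H2S") [concentration_profile()].
#' @param porosity matrix porosity.
#' @param D_sed diffusion coefficient for sulfide, m2 s-1.
#' @param window_pts window size passed to [steepest_gradient()].
#' @return list of class `sulfide_flux`: `total` (mmol m-2 d-1), `J_up`,
#'   `J_down` (`flux_result`s or NULL), `peak_depth_mm`, `monotone`.
#' @export
sulfide_flux_total <- function(profile, porosity, D_sed = wf_config()$D_H2S,
                               window_pts = wf_config()$gradient_window) {
  stopifnot(inherits(profile, "concentration_profile"))
  sub <- profile$depth_mm >= 0
  z <- profile$depth_mm[sub]
  v <- profile$value[sub]
  ipk <- which.max(v)
  above <- ipk >= window_pts                  # room for a window above the peak
  below <- (length(z) - ipk + 1) >= window_pts
  clip <- function(i1, i2) concentration_profile(z[i1:i2], v[i1:i2],
                                                 attr(profile, "analyte"),
                                                 porosity = attr(profile, "porosity"))
  J_up <- if (above) {
    g <- steepest_gradient(clip(1, ipk), window_pts, "up")
    if (!g$degenerate) fick_flux(g, porosity, D_sed, "totalS") else NULL
  }
  J_down <- if (below) {
    g <- steepest_gradient(clip(ipk, length(z)), window_pts, "down")
    if (!g$degenerate) fick_flux(g, porosity, D_sed, "totalS") else NULL
  }
  monotone <- is.null(J_up) || is.null(J_down)
  total <- sum(c(if (!is.null(J_up)) J_up$magnitude,
                 if (!is.null(J_down)) J_down$magnitude))
  if (monotone)
    wf_log("monotone sulfide profile: reporting the single steepest flux")
  structure(list(total = total, J_up = J_up, J_down = J_down,
                 peak_depth_mm = z[ipk], monotone = monotone),
            class = "sulfide_flux")
}

#' Oxygen penetration depth
#'
#' Depth of the first crossing of the O2 profile below the detection limit,
#' linearly interpolated between samples. Profiles that never cross return
#' the deepest measured depth with `censored = TRUE` (reported as
#' "> depth mm", matching the open-ended entries of flux summary tables).
#'
#' @param o2_profile an "O2" [concentration_profile()].
#' @param detection_limit sensor detection limit, uM (default 1).
#' @return list of class `opd_result`: `opd_mm`, `censored`.
#' @export
oxygen_penetration_depth <- function(o2_profile,
                                     detection_limit = wf_config()$detection_limit_uM) {
  stopifnot(inherits(o2_profile, "concentration_profile"))
  sub <- o2_profile$depth_mm >= 0
  z <- o2_profile$depth_mm[sub]
  v <- o2_profile$value[sub]
  if (v[1] <= detection_limit) {
    warning("profile already at/below the detection limit at the interface")
    return(structure(list(opd_mm = 0, censored = FALSE), class = "opd_result"))
  }
  idx <- which(v <= detection_limit)
  if (!length(idx))
    return(structure(list(opd_mm = max(z), censored = TRUE), class = "opd_result"))
  i <- idx[1]
  # linear interpolation between the bracketing points
  opd <- z[i - 1] + (v[i - 1] - detection_limit) / (v[i - 1] - v[i]) * (z[i] - z[i - 1])
  structure(list(opd_mm = opd, censored = FALSE), class = "opd_result")
}

#' @export
print.opd_result <- function(x, ...) {
  cat("<opd_result> OPD", if (x$censored) paste0("> ", format(x$opd_mm))
      else format(x$opd_mm, digits = 3), "mm\n")
  invisible(x)
}

#' Depth-integrated areal inventory
#'
#' Sums per-layer values times layer thickness over contiguous 1-cm layers.
#' Interior gaps are filled by linear interpolation of the neighbouring
#' layers and flagged. Input units per cm3 yield output per cm2 (e.g. cells
#' cm-3 -> cells cm-2, nmol cm-3 d-1 -> nmol cm-2 d-1; use
#' [nmol_cm2_to_mmol_m2()] to convert rate inventories to mmol m-2 d-1).
#'
#' @param depth_cm numeric vector of layer tops (0 = the 0-1 cm layer).
#' @param values per-layer values (per cm3 units).
#' @param range depth range to integrate, cm (default 0-10).
#' @param layer_cm layer thickness, cm.
#' @return list: `inventory` (per cm2), `filled` (number of interpolated
#'   layers), `range`.
#' @export
integrate_depth <- function(depth_cm, values, range = c(0, 10), layer_cm = 1) {
  stopifnot(length(depth_cm) == length(values), range[2] > range[1])
  tops <- seq(range[1], range[2] - layer_cm, by = layer_cm)
  if (!length(tops)) stop("empty depth range")
  v <- values[match(tops, depth_cm)]
  filled <- sum(is.na(v))
  if (filled) {
    if (sum(!is.na(v)) < 2) stop("too few layers to interpolate the range")
    v <- approx(tops[!is.na(v)], v[!is.na(v)], xout = tops, rule = 2)$y
    wf_log(filled, " missing layer(s) filled by interpolation")
  }
  list(inventory = sum(v * layer_cm), filled = filled, range = range)
}
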