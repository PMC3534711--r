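#' Benthic chamber O2 time series
#'
#' O2 concentration in the water enclosed by a benthic chamber, sampled since
#' closure. The standard chamber encloses 284 cm2 of sediment under 10-15 cm
#' of bottom water (the height is determined visually and must be supplied).
#'
#' @param time_h strictly increasing times since closure, h.
#' @param O2_uM O2 concentrations, uM.
#' @param area_cm2 chamber footprint, cm2.
#' @param height_m overlying water height, m.
#' @return object of class `chamber_series`.
#' @export
chamber_series <- function(time_h, O2_uM, area_cm2 = wf_config()$chamber_area_cm2,
                           height_m) {
  stopifnot(length(time_h) == length(O2_uM), area_cm2 > 0, height_m > 0)
  if (is.unsorted(time_h, strictly = TRUE)) stop("times must be strictly increasing")
  structure(list(time_h = as.numeric(time_h), O2_uM = as.numeric(O2_uM)),
            area_cm2 = area_cm2, height_m = height_m, class = "chamber_series")
}

#' @export
print.chamber_series <- function(x, ...) {
  cat("<chamber_series>", length(x$time_h), "points over",
      format(max(x$time_h) - min(x$time_h), digits = 3), "h, height",
      attr(x, "height_m"), "m\n")
  invisible(x)
}

#' Initial linear O2 decline of a chamber incubation
#'
#' The flux-bearing part of a chamber record is the initial linear decrease,
#' before O2 depletion or chamber artefacts bend the curve. This takes the
#' longest prefix window (starting at the first sample) whose least-squares
#' fit reaches `r2_min`, and returns its slope. If no prefix of at least
#' `min_points` qualifies, the first `min_points` are used with a warning.
#' An exactly constant prefix is a perfect fit (slope 0).
#'
#' @param series a [chamber_series()].
#' @param min_points minimum window length (default 10).
#' @param r2_min minimum R-squared for an acceptable window (default 0.98).
#' @return list: `slope` (uM/h), `n` (points used), `r2`, `fallback`.
#' @export
fit_initial_decline <- function(series, min_points = wf_config()$min_points,
                                r2_min = wf_config()$r2_min) {
  stopifnot(inherits(series, "chamber_series"), min_points >= 2)
  t <- series$time_h
  y <- series$O2_uM
  n <- length(t)
  if (n < min_points) stop("need at least ", min_points, " samples, have ", n)
  fit_prefix <- function(m) {
    tt <- t[1:m]; yy <- y[1:m]
    b <- ls_slope(tt, yy)
    res <- yy - (mean(yy) + b * (tt - mean(tt)))
    sst <- sum((yy - mean(yy))^2)
    r2 <- if (sst == 0) 1 else 1 - sum(res^2) / sst
    list(slope = b, r2 = r2)
  }
  for (m in n:min_points) {
    f <- fit_prefix(m)
    if (f$r2 >= r2_min)
      return(list(slope = f$slope, n = m, r2 = f$r2, fallback = FALSE))
  }
  warning("no prefix window reached R2 >= ", r2_min,
          "; falling back to the first ", min_points, " points")
  f <- fit_prefix(min_points)
  list(slope = f$slope, n = min_points, r2 = f$r2, fallback = TRUE)
}

#' Total oxygen uptake from a chamber slope
#'
#' Converts the initial O2 decline to an areal uptake:
#' `TOU = -slope * height * 24` with slope in uM/h (= mmol m-3 h-1) and
#' height in m, giving mmol m-2 d-1. A positive slope (O2 increase) yields a
#' negative TOU flagged as an efflux.
#'
#' @param slope O2 slope, uM/h (typically negative).
#' @param water_height enclosed water height, m.
#' @return list: `tou` (mmol m-2 d-1), `efflux` (logical).
#' @examples
#' tou_from_slope(-10, 0.1)$tou  # 24 mmol m-2 d-1
#' @export
tou_from_slope <- function(slope, water_height) {
  stopifnot(water_height > 0)
  tou <- -slope * water_height * 24
  if (slope > 0) wf_log("positive O2 slope: reporting a negative TOU (efflux)")
  list(tou = tou, efflux = slope > 0)
}

#' @rdname tou_from_slope
#' @param series a [chamber_series()].
#' @param ... passed to [fit_initial_decline()].
#' @return `total_oxygen_uptake()`: list with `tou`, `efflux`, `slope`, `n`,
#'   `r2`, `fallback`.
#' @export
total_oxygen_uptake <- function(series, ...) {
  fit <- fit_initial_decline(series, ...)
  res <- tou_from_slope(fit$slope, attr(series, "height_m"))
  c(res, fit)
}
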