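#' Parse a degrees-decimal-minutes coordinate
#'
#' Converts strings like `"N 32°32.0496"` to signed decimal degrees
#' (`degrees + minutes/60`, negative for S/W hemispheres). Vectorized.
#'
#' @param coord_text character vector, hemisphere letter followed by integer
#'   degrees and decimal minutes; the degree sign may be a space.
#' @return numeric decimal degrees.
#' @examples
#' parse_ddm("N 32°32.0496") # 32.53416
#' parse_ddm("S 10°30.0")    # -10.5
#' @export
parse_ddm <- function(coord_text) {
  vapply(coord_text, function(txt) {
    m <- regmatches(txt, regexec(
      "^\\s*([NSEWnsew])\\s*([0-9]+)\\s*(?:°|d|\\s)\\s*([0-9]+(?:\\.[0-9]+)?)\\s*'?\\s*$",
      txt))[[1]]
    if (length(m) != 4)
      stop("cannot parse degrees-decimal-minutes coordinate: ", sQuote(txt))
    hemi <- toupper(m[2])
    deg <- as.numeric(m[3])
    minutes <- as.numeric(m[4])
    if (minutes >= 60) stop("minutes out of range [0, 60) in ", sQuote(txt))
    max_deg <- if (hemi %in% c("N", "S")) 90 else 180
    if (deg > max_deg) stop("degrees out of range for hemisphere ", hemi, " in ", sQuote(txt))
    sign <- if (hemi %in% c("S", "W")) -1 else 1
    sign * (deg + minutes / 60)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Great-circle distance between stations
#'
#' Haversine distance on a sphere of radius 6371 km. Accepts either two
#' station rows (data frames with `lat`/`lon` decimal-degree columns, as
#' returned by [read_stations()]) or four bare coordinates via `haversine()`.
#'
#' @param a,b single station rows with numeric `lat` and `lon` columns.
#' @return distance in metres.
#' @examples
#' st <- woodfall_stations()
#' station_distance(st[st$id == "wood#1", ], st[st$id == "wood#5", ]) # ~409 m
#' @export
station_distance <- function(a, b) {
  stopifnot(is.data.frame(a), is.data.frame(b),
            all(c("lat", "lon") %in% names(a)), all(c("lat", "lon") %in% names(b)))
  haversine(a$lat[1], a$lon[1], b$lat[1], b$lon[1])
}

#' @rdname station_distance
#' @param lat1,lon1,lat2,lon2 decimal degrees.
#' @param radius sphere radius in metres.
#' @export
haversine <- function(lat1, lon1, lat2, lon2, radius = wf_units$earth_radius_m) {
  stopifnot(abs(lat1) <= 90, abs(lat2) <= 90, abs(lon1) <= 180, abs(lon2) <= 180)
  to <- pi / 180
  dlat <- (lat2 - lat1) * to
  dlon <- (lon2 - lon1) * to
  a <- sin(dlat / 2)^2 + cos(lat1 * to) * cos(lat2 * to) * sin(dlon / 2)^2
  2 * radius * asin(pmin(1, sqrt(a)))
}

#' Station table of the wood colonization experiments
#'
#' Reads a tab-separated station table with columns `id`, `location`,
#' `latitude`, `longitude` (degrees-decimal-minutes text), `deployed`,
#' `recovered`; adds parsed decimal-degree `lat`/`lon` columns and validates
#' dates. `woodfall_stations()` returns the packaged fixture with the four
#' wood experiments of the Nile deep-sea fan study area.
#'
#' Note: the packaged coordinates imply a wood#2 to wood#6 separation of about
#' 96 m, while the originating survey reports 31 m; the table is kept verbatim
#' and the discrepancy documented rather than corrected.
#'
#' @param path path to a stations TSV.
#' @return data.frame of stations with `lat`/`lon` in decimal degrees.
#' @export
read_stations <- function(path) {
  st <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("id", "location", "latitude", "longitude", "deployed", "recovered")
  miss <- setdiff(need, names(st))
  if (length(miss)) stop("stations table missing column(s): ", paste(miss, collapse = ", "))
  st$lat <- parse_ddm(st$latitude)
  st$lon <- parse_ddm(st$longitude)
  dep <- as.Date(st$deployed)
  rec <- as.Date(st$recovered)
  if (anyNA(dep) || anyNA(rec)) stop("unparseable deployment/recovery dates")
  if (any(rec < dep)) stop("recovery date precedes deployment for: ",
                           paste(st$id[rec < dep], collapse = ", "))
  st
}

#' @rdname read_stations
#' @export
woodfall_stations <- function() {
  read_stations(system.file("extdata", "stations.tsv", package = "woodfall",
                            mustWork = TRUE))
}

# ---- tabular readers/writers -------------------------------------------------
# Dialect: UTF-8, tab-separated, one header row, '.' decimal separator.
# Metadata travel as leading '# key=value' lines.

read_meta_header <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines)
  meta <- list()
  for (ln in lines[hdr]) {
    m <- regmatches(ln, regexec("^#\\s*([A-Za-z0-9_]+)\\s*=\\s*(.*?)\\s*$", ln))[[1]]
    if (length(m) == 3) {
      num <- suppressWarnings(as.numeric(m[3]))
      meta[[m[2]]] <- if (is.na(num)) m[3] else num
    }
  }
  list(meta = meta, skip = length(hdr))
}

#' Read / write a microsensor profile table
#'
#' Profile files are tab-separated with columns `depth_mm`, `value` and an
#' optional `replicate`, preceded by metadata lines `# analyte=`,
#' `# porosity=`, `# temperature_C=`, `# salinity=`. Depths are mm below the
#' interface, positive downward.
#'
#' @param path file path.
#' @param sep field separator, `"\t"` by default (use `","` for CSV input).
#' @return a [concentration_profile()] (a list of profiles if `replicate`
#'   is present, one per replicate).
#' @export
read_profile <- function(path, sep = "\t") {
  h <- read_meta_header(path)
  d <- read.delim(path, skip = h$skip, sep = sep, stringsAsFactors = FALSE)
  if (!all(c("depth_mm", "value") %in% names(d)))
    stop("profile table needs columns depth_mm, value")
  mk <- function(dd) concentration_profile(
    depth_mm = dd$depth_mm, value = dd$value,
    analyte = if (is.null(h$meta$analyte)) "O2" else h$meta$analyte,
    porosity = if (is.null(h$meta$porosity)) NA_real_ else h$meta$porosity,
    temperature = h$meta$temperature_C, salinity = h$meta$salinity)
  if ("replicate" %in% names(d)) lapply(split(d, d$replicate), mk) else mk(d)
}

#' @rdname read_profile
#' @param profile a [concentration_profile()].
#' @export
write_profile <- function(profile, path) {
  meta <- attributes(profile)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(
    paste0("# analyte=", meta$analyte),
    paste0("# porosity=", format(meta$porosity, digits = 15)),
    if (!is.null(meta$temperature)) paste0("# temperature_C=", meta$temperature),
    if (!is.null(meta$salinity)) paste0("# salinity=", meta$salinity)
  ), con)
  write.table(as.data.frame(unclass(profile)[c("depth_mm", "value")]), con,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a benthic chamber time series
#'
#' Chamber files are comma-separated with columns `time_h`, `O2_uM`, preceded
#' by `# area_cm2=` and `# height_m=` metadata lines.
#'
#' @param path file path.
#' @return a [chamber_series()].
#' @export
read_chamber <- function(path) {
  h <- read_meta_header(path)
  d <- read.delim(path, skip = h$skip, sep = ",", stringsAsFactors = FALSE)
  if (!all(c("time_h", "O2_uM") %in% names(d)))
    stop("chamber table needs columns time_h, O2_uM")
  chamber_series(time_h = d$time_h, O2_uM = d$O2_uM,
                 area_cm2 = if (is.null(h$meta$area_cm2)) 284 else h$meta$area_cm2,
                 height_m = h$meta$height_m)
}

#' @rdname read_chamber
#' @param series a [chamber_series()].
#' @export
write_chamber <- function(series, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(paste0("# area_cm2=", attr(series, "area_cm2")),
               paste0("# height_m=", attr(series, "height_m"))), con)
  write.table(as.data.frame(unclass(series)[c("time_h", "O2_uM")]), con,
              sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a radiotracer incubation table
#'
#' Tab-separated with columns `depth_cm`, `fraction`, `pool`, `porosity`,
#' `time_h` and optionally `replicate`. `pool` is the substrate pool
#' concentration (sulfate in mM for sulfate reduction; CH4 in uM for AOM —
#' the unit interpretation is chosen by [layer_rate()]'s caller).
#'
#' @param path file path.
#' @return data.frame of incubation layers.
#' @export
read_tracer <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("depth_cm", "fraction", "pool", "porosity", "time_h")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("tracer table missing column(s): ", paste(miss, collapse = ", "))
  d
}

#' Read / write ARISA peak tables
#'
#' Size-caller export style CSV with columns `sample`, `replicate`,
#' `size_bp`, `area`.
#'
#' @param path file path.
#' @return data.frame of peaks.
#' @export
read_peaks <- function(path) {
  d <- read.delim(path, sep = ",", stringsAsFactors = FALSE)
  need <- c("sample", "replicate", "size_bp", "area")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("peak table missing column(s): ", paste(miss, collapse = ", "))
  if (any(d$area <= 0)) stop("peak areas must be positive")
  d
}

#' @rdname read_peaks
#' @param peaks a peak data.frame.
#' @export
write_peaks <- function(peaks, path) {
  write.table(peaks, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a tag-sequence OTU table
#'
#' Tab-separated; rows are OTU ids, columns are samples, and a final
#' `taxonomy` column holds semicolon-separated paths
#' (`"Bacteria;Proteobacteria;Gammaproteobacteria;..."`). In memory the table
#' is an integer matrix (OTUs x samples) with a `taxonomy` attribute.
#'
#' @param path file path.
#' @return integer matrix with attribute `taxonomy` (named character).
#' @export
read_tag_table <- function(path) {
  d <- read.delim(path, row.names = 1, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"taxonomy" %in% names(d)) stop("tag table needs a final taxonomy column")
  tax <- setNames(d$taxonomy, rownames(d))
  m <- as.matrix(d[setdiff(names(d), "taxonomy")])
  storage.mode(m) <- "integer"
  if (any(m < 0)) stop("tag counts must be non-negative")
  tag_table(m, taxonomy = tax)
}

#' @rdname read_tag_table
#' @param tab a tag table matrix.
#' @export
write_tag_table <- function(tab, path) {
  d <- as.data.frame(unclass(tab))
  d$taxonomy <- attr(tab, "taxonomy")[rownames(tab)]
  d <- cbind(otu = rownames(tab), d)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_tag_table
#' @param counts integer matrix, OTUs in rows, samples in columns.
#' @param taxonomy named character vector of taxonomy paths per OTU
#'   (missing OTUs get "unassigned").
#' @export
tag_table <- function(counts, taxonomy = NULL) {
  stopifnot(is.matrix(counts))
  if (is.null(rownames(counts))) rownames(counts) <- paste0("OTU", seq_len(nrow(counts)))
  if (any(counts < 0) || any(counts != round(counts)))
    stop("tag counts must be non-negative integers")
  if (is.null(taxonomy)) taxonomy <- setNames(rep("unassigned", nrow(counts)), rownames(counts))
  tax <- setNames(rep("unassigned", nrow(counts)), rownames(counts))
  tax[intersect(names(taxonomy), rownames(counts))] <-
    taxonomy[intersect(names(taxonomy), rownames(counts))]
  structure(counts, taxonomy = tax, class = c("tag_table", class(counts)))
}
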