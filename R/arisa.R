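#' Fixed-window binning of ARISA peaks
#'
#' Capillary electrophoresis calls the same intergenic-spacer fragment at
#' slightly different sizes between runs; a fixed-window binning with 2-bp
#' bins absorbs these shifts. Bins are half-open intervals
#' `[low + offset + k*bin_size, low + offset + (k+1)*bin_size)`; every peak
#' inside the analytical range falls in exactly one bin (a peak exactly on a
#' boundary joins the higher, lower-closed bin), peaks outside the range are
#' dropped (count logged), and multiple peaks of one replicate in the same
#' bin have their areas summed.
#'
#' @param peaks data.frame with columns `sample`, `replicate`, `size_bp`,
#'   `area` (see [read_peaks()]).
#' @param bin_size bin width, bp (default 2).
#' @param frame_offset shift of the bin frame, bp (default 0).
#' @param size_range analytical range `c(low, high)`, bp (default 100-1000).
#' @return numeric matrix of summed areas, one row per `sample|replicate`
#'   combination, one column per occupied bin (labels `bin_0400_0402`),
#'   with attributes `sample`, `replicate` (row metadata), `bins`
#'   (data.frame of bin bounds) and `n_dropped`.
#' @export
bin_peaks <- function(peaks, bin_size = wf_config()$bin_size_bp,
                      frame_offset = 0, size_range = wf_config()$size_range_bp) {
  stopifnot(bin_size > 0, size_range[1] < size_range[2],
            all(c("sample", "replicate", "size_bp", "area") %in% names(peaks)))
  inside <- peaks$size_bp >= size_range[1] & peaks$size_bp < size_range[2]
  n_dropped <- sum(!inside)
  if (n_dropped) wf_log(n_dropped, " peak(s) outside [",
                        size_range[1], ", ", size_range[2], ") bp dropped")
  p <- peaks[inside, , drop = FALSE]
  if (!nrow(p)) stop("no peaks inside the analytical range")
  k <- floor((p$size_bp - size_range[1] - frame_offset) / bin_size)
  lo <- size_range[1] + frame_offset + k * bin_size
  fmt <- function(x) ifelse(x == round(x), sprintf("%04d", as.integer(round(x))),
                            sprintf("%06.1f", x))
  lab <- sprintf("bin_%s_%s", fmt(lo), fmt(lo + bin_size))
  rep_id <- paste(p$sample, p$replicate, sep = "|")
  lows <- sort(unique(lo))
  bins <- sprintf("bin_%s_%s", fmt(lows), fmt(lows + bin_size))
  rows <- sort(unique(rep_id))
  m <- matrix(0, nrow = length(rows), ncol = length(bins),
              dimnames = list(rows, bins))
  agg <- tapply(p$area, list(rep_id, lab), sum)
  m[rownames(agg), colnames(agg)] <- ifelse(is.na(agg), 0, agg)
  meta <- do.call(rbind, strsplit(rows, "|", fixed = TRUE))
  structure(m, sample = meta[, 1], replicate = meta[, 2],
            bins = data.frame(label = bins, low = lows, high = lows + bin_size,
                              stringsAsFactors = FALSE),
            n_dropped = n_dropped)
}

#' Replicate consensus of binned ARISA profiles
#'
#' An OTU (bin) counts as present in a sample if it appears in at least
#' `min_present` of the PCR replicates (default 1 of 3, the inclusive rule);
#' its consensus intensity is the mean area over the replicates in which it
#' is present. `min_present = n` recovers the strict intersection,
#' `min_present = 1` the union.
#'
#' @param binned matrix from [bin_peaks()] (rows = sample|replicate).
#' @param min_present presence threshold, replicates.
#' @param expected_replicates warn when a sample has a different replicate
#'   count (default 3; NULL disables the check).
#' @return matrix samples x bins of consensus areas (0 = absent).
#' @export
replicate_consensus <- function(binned, min_present = 1, expected_replicates = 3) {
  samples <- attr(binned, "sample")
  stopifnot(!is.null(samples), min_present >= 1)
  out <- do.call(rbind, lapply(split(seq_len(nrow(binned)), samples), function(idx) {
    if (!is.null(expected_replicates) && length(idx) != expected_replicates)
      warning("sample ", samples[idx[1]], " has ", length(idx),
              " replicate(s), expected ", expected_replicates)
    sub <- binned[idx, , drop = FALSE]
    npres <- colSums(sub > 0)
    cons <- ifelse(npres >= min_present, colSums(sub) / pmax(npres, 1), 0)
    cons
  }))
  rownames(out) <- names(split(seq_len(nrow(binned)), samples))
  out
}

#' Relative fluorescence intensities
#'
#' Divides each peak (bin) area by the total area of its profile, so each
#' profile sums to 1.
#'
#' @param x numeric vector (one profile) or matrix (profiles in rows).
#' @return normalized vector/matrix.
#' @export
relative_intensities <- function(x) {
  if (is.matrix(x)) {
    tot <- rowSums(x)
    if (any(tot <= 0)) stop("profile(s) with zero total area: ",
                            paste(rownames(x)[tot <= 0], collapse = ", "))
    return(sweep(x, 1, tot, "/"))
  }
  tot <- sum(x)
  if (tot <= 0) stop("profile with zero total area")
  x / tot
}

#' ARISA pipeline: peaks to a sample x OTU relative-intensity table
#'
#' Chains [bin_peaks()], [replicate_consensus()] and
#' [relative_intensities()]. With `scan_offset = TRUE` the bin-frame offset
#' is scanned in 0.1-bp steps over one bin width and the offset maximizing
#' the mean between-replicate similarity (1 - mean pairwise Bray-Curtis
#' within samples) is chosen and logged; by default the frame is anchored at
#' the low edge of the analytical range.
#'
#' @inheritParams bin_peaks
#' @inheritParams replicate_consensus
#' @param scan_offset scan the bin frame instead of using `frame_offset`.
#' @param min_intensity optional relative-intensity floor applied after
#'   normalization (default 0 = keep all, as in the standard protocol).
#' @return samples x bins matrix of relative intensities (rows sum to 1),
#'   with attributes `frame_offset` and `n_dropped`.
#' @export
arisa_otu_table <- function(peaks, bin_size = wf_config()$bin_size_bp,
                            frame_offset = 0, size_range = wf_config()$size_range_bp,
                            min_present = 1, expected_replicates = NULL,
                            scan_offset = FALSE, min_intensity = 0) {
  if (scan_offset) {
    offsets <- seq(0, bin_size - 0.1, by = 0.1)
    score <- vapply(offsets, function(off) {
      b <- bin_peaks(peaks, bin_size, off, size_range)
      mean_replicate_similarity(b)
    }, numeric(1))
    frame_offset <- offsets[which.max(score)]
    wf_log("scan-offset: chose frame offset ", frame_offset, " bp (similarity ",
           format(max(score), digits = 4), ")")
  }
  b <- bin_peaks(peaks, bin_size, frame_offset, size_range)
  cons <- replicate_consensus(b, min_present, expected_replicates)
  rel <- relative_intensities(cons)
  if (min_intensity > 0) {
    rel[rel < min_intensity] <- 0
    rel <- relative_intensities(rel)
  }
  structure(rel, frame_offset = frame_offset, n_dropped = attr(b, "n_dropped"))
}

# mean between-replicate similarity (1 - Bray-Curtis) within samples
mean_replicate_similarity <- function(binned) {
  samples <- attr(binned, "sample")
  sims <- unlist(lapply(split(seq_len(nrow(binned)), samples), function(idx) {
    if (length(idx) < 2) return(NULL)
    rel <- relative_intensities(binned[idx, , drop = FALSE])
    d <- bray_curtis(rel)
    1 - as.numeric(d)
  }))
  if (!length(sims)) return(NA_real_)
  mean(sims)
}
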