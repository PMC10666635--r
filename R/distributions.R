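# Distance-distribution summaries: per-nucleotide histograms, window
# accounting (the −8..+6 reinitiation window), and phase-split histograms.

distances_of <- function(pairs) {
  if (is.data.frame(pairs)) {
    if (!"distance" %in% names(pairs)) {
      stop("pair table has no 'distance' column; run intergenic_distance()",
           call. = FALSE)
    }
    pairs$distance
  } else {
    as.integer(pairs)
  }
}

#' Histogram of intergenic distances
#'
#' Counts serial pairs at every integer distance in `[lo, hi]`. Pairs
#' outside the range are tallied (below/above), not discarded, so the total
#' stays auditable: `sum(counts) + out_of_range = total_pairs`.
#'
#' @param pairs serial pair table with a `distance` column, or an integer
#'   vector of distances.
#' @param lo,hi integer range of the histogram (inclusive).
#' @return object of class `distance_histogram`: list with `bins` (tibble of
#'   `distance`, `count`), `out_of_range_low`, `out_of_range_high`,
#'   `total_pairs`.
#' @export
distance_histogram <- function(pairs, lo = -20L, hi = 200L) {
  if (lo > hi) stop("lo must be <= hi", call. = FALSE)
  d <- distances_of(pairs)
  lo <- as.integer(lo); hi <- as.integer(hi)
  in_range <- d >= lo & d <= hi
  counts <- tabulate(d[in_range] - lo + 1L, nbins = hi - lo + 1L)
  structure(
    list(
      bins = tibble::tibble(distance = lo:hi, count = counts),
      out_of_range_low = sum(d < lo),
      out_of_range_high = sum(d > hi),
      total_pairs = length(d)
    ),
    class = "distance_histogram"
  )
}

#' @export
print.distance_histogram <- function(x, ...) {
  cat(sprintf(
    "distance histogram [%d, %d]: %d pairs (%d below, %d above range)\n",
    min(x$bins$distance), max(x$bins$distance), x$total_pairs,
    x$out_of_range_low, x$out_of_range_high))
  nz <- x$bins[x$bins$count > 0, ]
  if (nrow(nz) > 0) {
    top <- nz[order(-nz$count), ][seq_len(min(5, nrow(nz))), ]
    cat("top bins:", paste(sprintf("%+d:%d", top$distance, top$count),
                           collapse = "  "), "\n")
  }
  invisible(x)
}

#' Count and fraction of serial pairs in a distance window
#'
#' Window accounting of the kind used for the reinitiation-permissive region
#' (e.g., −8 to +6 nt).
#'
#' @param pairs serial pair table or distance vector.
#' @param lo,hi inclusive window bounds.
#' @return list with `count` and `fraction` (of all serial pairs).
#' @export
window_fraction <- function(pairs, lo, hi) {
  d <- distances_of(pairs)
  n <- sum(d >= lo & d <= hi)
  list(count = n, fraction = if (length(d) > 0) n / length(d) else NA_real_)
}

#' Distance histograms split by overlap phase
#'
#' Three histograms keyed by phase 0/1/2; their bin-wise sum equals the
#' plain [distance_histogram()] on the same input.
#'
#' @param pairs serial pair table (needs `distance`; `phase` is computed if
#'   absent) or distance vector.
#' @param lo,hi histogram range.
#' @return named list of `distance_histogram` objects (`"0"`, `"1"`, `"2"`).
#' @export
phase_split_histogram <- function(pairs, lo = -20L, hi = 200L) {
  d <- distances_of(pairs)
  p <- overlap_phase(d)
  out <- lapply(0:2, function(ph) distance_histogram(d[p == ph], lo, hi))
  names(out) <- as.character(0:2)
  out
}

#' Write a histogram (optionally phase-split) as per-bin TSV
#'
#' Thin output layer: columns `distance`, `count` and, for a phase-split
#' list, `phase`. Out-of-range tallies are appended as comment lines.
#'
#' @param h a `distance_histogram` or the list returned by
#'   [phase_split_histogram()].
#' @param path output path.
#' @export
write_histogram_tsv <- function(h, path) {
  if (inherits(h, "distance_histogram")) {
    df <- h$bins
    oob <- sprintf("# out_of_range_low=%d out_of_range_high=%d total=%d",
                   h$out_of_range_low, h$out_of_range_high, h$total_pairs)
  } else {
    df <- dplyr::bind_rows(lapply(names(h), function(ph) {
      dplyr::mutate(h[[ph]]$bins, phase = as.integer(ph))
    }))
    oob <- sprintf("# total=%d", sum(vapply(h, function(x) x$total_pairs, 0)))
  }
  readr::write_tsv(df, path, progress = FALSE)
  cat(oob, "\n", file = path, append = TRUE, sep = "")
  invisible(path)
}
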