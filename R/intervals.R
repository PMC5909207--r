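#' Convert an interval segmentation to a two-state sequence
#'
#' Turns a list of "body" intervals over a genomic (or other) region into a
#' binned two-state string: one character per bin across
#' `[region_start, region_end)`, labelled `"D"` when the bin midpoint falls
#' inside a body interval and `"B"` (boundary) otherwise. This is the
#' standard encoding for comparing topologically associating domain (TAD)
#' calls, where each caller's domain bodies partition a region into
#' body/boundary runs. Membership by bin midpoint is deterministic: with
#' half-open intervals a midpoint cannot sit on an interval edge ambiguously.
#'
#' @param bodies Two-column matrix or data.frame of `[start, end)` body
#'   intervals (columns `start`, `end`, or the first two columns), in the
#'   same unit as the region coordinates. May have zero rows.
#' @param region_start,region_end Region bounds, half-open.
#' @param bin_size Positive bin width; the sequence has
#'   `ceiling((region_end - region_start) / bin_size)` positions.
#' @param body_label,boundary_label Single-character labels; defaults
#'   `"D"` and `"B"`.
#'
#' @return A `state_sequence` over the two labels.
#'
#' @examples
#' b <- data.frame(start = c(0, 60), end = c(50, 100))
#' as.character(intervals_to_states(b, 0, 100, 10))  # "DDDDDBDDDD"
#' @export
intervals_to_states <- function(bodies, region_start, region_end, bin_size,
                                body_label = "D", boundary_label = "B") {
  if (region_end <= region_start) {
    stop("region_end must exceed region_start", call. = FALSE)
  }
  if (!is.numeric(bin_size) || length(bin_size) != 1L || bin_size <= 0) {
    stop("bin_size must be a single positive number", call. = FALSE)
  }
  bodies <- as.data.frame(bodies)
  if (nrow(bodies) > 0L) {
    cols <- if (all(c("start", "end") %in% names(bodies))) {
      bodies[, c("start", "end")]
    } else {
      stats::setNames(bodies[, 1:2], c("start", "end"))
    }
    bodies <- cols[order(cols$start), , drop = FALSE]
    if (any(bodies$end <= bodies$start)) {
      stop("body intervals must satisfy start < end", call. = FALSE)
    }
    if (any(bodies$start < region_start) || any(bodies$end > region_end)) {
      stop("body intervals must lie within [region_start, region_end)",
           call. = FALSE)
    }
    if (nrow(bodies) > 1L &&
        any(bodies$start[-1L] < bodies$end[-nrow(bodies)])) {
      stop("body intervals must not overlap", call. = FALSE)
    }
  }
  n_bins <- ceiling((region_end - region_start) / bin_size)
  mids <- region_start + (seq_len(n_bins) - 0.5) * bin_size
  in_body <- rep(FALSE, n_bins)
  for (k in seq_len(nrow(bodies))) {
    in_body <- in_body | (mids >= bodies$start[k] & mids < bodies$end[k])
  }
  state_sequence(ifelse(in_body, body_label, boundary_label))
}

#' Read BED-like body intervals for one region
#'
#' Reads a 3+ column tab-separated file (`chrom`, `start`, `end`; 0-based
#' half-open, no header) and returns the intervals overlapping-contained in
#' the requested region. The chromosome column is only used for filtering
#' when `chrom` is given.
#'
#' @param path Path to the interval file.
#' @param chrom Optional chromosome name to filter on.
#' @param region_start,region_end Optional region bounds; intervals are
#'   dropped if disjoint from the region and clipped to it otherwise.
#'
#' @return A `data.frame` with columns `start`, `end`, sorted by start.
#'
#' @export
read_bed_intervals <- function(path, chrom = NULL,
                               region_start = NULL, region_end = NULL) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)[, 1:3]
  names(tab) <- c("chrom", "start", "end")
  tab$start <- as.numeric(tab$start)
  tab$end <- as.numeric(tab$end)
  if (!is.null(chrom)) tab <- tab[tab$chrom == chrom, , drop = FALSE]
  if (!is.null(region_start) && !is.null(region_end)) {
    tab <- tab[tab$end > region_start & tab$start < region_end, , drop = FALSE]
    tab$start <- pmax(tab$start, region_start)
    tab$end <- pmin(tab$end, region_end)
  }
  out <- tab[order(tab$start), c("start", "end"), drop = FALSE]
  row.names(out) <- NULL
  out
}
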