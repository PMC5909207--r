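#' Decompose a state sequence into maximal segments
#'
#' A segment is a maximal run of consecutive identical labels. The returned
#' segments tile the sequence exactly: in order, without gaps or overlaps.
#' Coordinates are 0-based half-open, so a segment covers positions
#' `start, ..., end - 1` and `length = end - start`.
#'
#' @param seq A `state_sequence` or anything [state_sequence()] accepts.
#'
#' @return A `data.frame` with one row per segment and columns `state`,
#'   `start`, `end`, `length`.
#'
#' @examples
#' extract_segments("CHHHHHHHHHHC")
#' @export
extract_segments <- function(seq) {
  seq <- state_sequence(seq)
  runs <- rle(seq$states)
  end <- cumsum(runs$lengths)
  data.frame(state = runs$values,
             start = end - runs$lengths,
             end = end,
             length = runs$lengths,
             stringsAsFactors = FALSE)
}

#' Pair overlapping same-state segments
#'
#' For one state, matches every reference segment against every predicted
#' segment of that state that shares at least one position with it. Each
#' overlapping `(reference, predicted)` combination yields one pair with its
#' intersection size `minov` and union size `maxov`. Reference segments of
#' the state overlapped by no predicted segment are returned separately as
#' `unmatched`; they enter the score normalizer with zero contribution to
#' the numerator. A reference segment overlapped by several predicted
#' segments yields several pairs (and is weighted once per pair).
#'
#' @param ref_segs,pred_segs Segment tables as returned by
#'   [extract_segments()], for the reference and predicted sequences.
#' @param state Single state label to pair on; rows of other states are
#'   ignored, so whole segment tables may be passed.
#'
#' @return A list with `pairs` (data.frame: `state`, `ref_start`, `ref_end`,
#'   `ref_len`, `pred_start`, `pred_end`, `pred_len`, `minov`, `maxov`) and
#'   `unmatched` (data.frame of reference segment rows).
#'
#' @examples
#' r <- extract_segments("CHHHHHHHHHHC")
#' p <- extract_segments("CHCHCHCHCHCC")
#' build_overlap_sets(r, p, "H")
#' @export
build_overlap_sets <- function(ref_segs, pred_segs, state) {
  stopifnot(is.character(state), length(state) == 1L)
  r <- ref_segs[ref_segs$state == state, , drop = FALSE]
  p <- pred_segs[pred_segs$state == state, , drop = FALSE]

  empty_pairs <- data.frame(state = character(), ref_start = integer(),
                            ref_end = integer(), ref_len = integer(),
                            pred_start = integer(), pred_end = integer(),
                            pred_len = integer(), minov = integer(),
                            maxov = integer(), stringsAsFactors = FALSE)
  if (nrow(r) == 0L) {
    return(list(pairs = empty_pairs, unmatched = r))
  }
  if (nrow(p) == 0L) {
    return(list(pairs = empty_pairs, unmatched = r))
  }

  # all ref x pred combinations, keep those sharing >= 1 position
  idx <- expand.grid(i = seq_len(nrow(r)), j = seq_len(nrow(p)))
  minov <- pmin(r$end[idx$i], p$end[idx$j]) - pmax(r$start[idx$i], p$start[idx$j])
  keep <- minov > 0L
  idx <- idx[keep, , drop = FALSE]
  if (nrow(idx) == 0L) {
    row.names(r) <- NULL
    return(list(pairs = empty_pairs, unmatched = r))
  }
  minov <- minov[keep]
  maxov <- pmax(r$end[idx$i], p$end[idx$j]) - pmin(r$start[idx$i], p$start[idx$j])

  ord <- order(idx$i, idx$j)
  idx <- idx[ord, , drop = FALSE]
  pairs <- data.frame(state = state,
                      ref_start = r$start[idx$i], ref_end = r$end[idx$i],
                      ref_len = r$length[idx$i],
                      pred_start = p$start[idx$j], pred_end = p$end[idx$j],
                      pred_len = p$length[idx$j],
                      minov = minov[ord], maxov = maxov[ord],
                      stringsAsFactors = FALSE)
  row.names(pairs) <- NULL
  unmatched <- r[!(seq_len(nrow(r)) %in% idx$i), , drop = FALSE]
  row.names(unmatched) <- NULL
  list(pairs = pairs, unmatched = unmatched)
}
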