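#' Total allowance budget for a reference sequence
#'
#' SOV_refine assigns each reference sequence a total boundary-allowance
#' budget
#' \deqn{\delta(all) = \lambda \frac{N_C}{\sum_j (len(s_j)/len(s_r))^2}}
#' where \eqn{N_C} is the number of distinct states occurring in the
#' reference, the sum runs over all its segments \eqn{s_j}, and
#' \eqn{len(s_r)} is the sequence length. The budget grows with the number
#' of states and with fragmentation (many short segments mean many
#' boundaries), both of which make a segmentation harder to predict.
#' \eqn{\lambda} scales the budget: smaller values score more stringently.
#'
#' @param ref Reference `state_sequence` (or string).
#' @param lambda Positive scale parameter; default 1.
#'
#' @return The non-negative budget \eqn{\delta(all)}.
#'
#' @examples
#' delta_all("CHHHHHHHHHHC")          # 2 / (102/144) = 2.8235...
#' delta_all("AABBBBBBCCCCCCDD")      # 4 / 0.3125 = 12.8
#' @export
delta_all <- function(ref, lambda = 1) {
  if (!is.numeric(lambda) || length(lambda) != 1L || is.na(lambda) ||
      lambda <= 0) {
    stop("lambda must be a single positive number", call. = FALSE)
  }
  ref <- state_sequence(ref)
  segs <- extract_segments(ref)
  n_c <- length(ref$alphabet)
  lambda * n_c / sum((segs$length / ref$length)^2)
}

#' Refined per-pair allowance
#'
#' The budget from [delta_all()] is apportioned to each overlapping segment
#' pair in proportion to the reference segment's share of the sequence and
#' to the pair's overlap quality:
#' \deqn{\delta(s_1,s_2) = \delta(all) \times \frac{len(s_1)}{len(s_r)}
#'   \times \frac{minov}{maxov}}
#' then clamped to `maxov - minov` so no pair can score better than a
#' perfect match. Because the raw value grows with `minov/maxov`, every
#' additional correctly assigned position strictly increases the allowance
#' until the clamp is reached.
#'
#' @param minov,maxov Intersection and union sizes of the pair
#'   (`1 <= minov <= maxov`).
#' @param ref_len Length of the reference segment of the pair.
#' @param ref_seq_len Length of the full reference sequence.
#' @param d_all Budget from [delta_all()].
#'
#' @return Clamped allowance in `[0, maxov - minov]`. Vectorized over pairs.
#'
#' @examples
#' d <- delta_all("CHHHHHHHHHHC")
#' delta_refine(minov = 4, maxov = 10, ref_len = 10, ref_seq_len = 12, d)
#' @export
delta_refine <- function(minov, maxov, ref_len, ref_seq_len, d_all) {
  raw <- d_all * (ref_len / ref_seq_len) * (minov / maxov)
  pmin(raw, maxov - minov)
}

#' SOV'99 per-pair allowance
#'
#' The 1999 definition grants each pair an integer allowance
#' `min(maxov - minov, minov, floor(len(s1)/2), floor(len(s2)/2))`.
#' It depends only on the pair itself, which is why it cannot guarantee an
#' increasing reward as a predicted segment grows (the motivation for the
#' refined allowance).
#'
#' @param minov,maxov Intersection and union sizes of the pair.
#' @param ref_len,pred_len Lengths of the reference and predicted segments.
#'
#' @return Non-negative integer allowance. Vectorized over pairs.
#'
#' @examples
#' delta_sov99(minov = 8, maxov = 10, ref_len = 10, pred_len = 8)  # 2
#' @export
delta_sov99 <- function(minov, maxov, ref_len, pred_len) {
  pmin(maxov - minov, minov, ref_len %/% 2L, pred_len %/% 2L)
}
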