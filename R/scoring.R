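#' Per-position accuracy (Q score)
#'
#' Fraction of positions at which the two sequences carry identical labels.
#' The operation is alphabet-agnostic: over a three-state alphabet it is the
#' classical Q3, over eight states Q8, and so on.
#'
#' @param ref,pred Equal-length state sequences (or strings).
#'
#' @return A number in `[0, 1]`.
#'
#' @examples
#' q_score("CHHHHHHHHHHC", "CHCHCHCHCHCC")  # 7/12
#' @export
q_score <- function(ref, pred) {
  sp <- check_pair(ref, pred)
  mean(sp$ref$states == sp$pred$states)
}

# Per-state SOV(i): numerator sums (minov + delta)/maxov * len(s1) over
# overlapping pairs; N(i) counts len(s1) once per pair plus once per
# unmatched reference segment, so a reference segment split across k
# predicted segments is weighted k times on both sides.
sov_state <- function(state, ref_segs, pred_segs, allowance_fn) {
  sets <- build_overlap_sets(ref_segs, pred_segs, state)
  pairs <- sets$pairs
  delta <- if (nrow(pairs) > 0L) allowance_fn(pairs) else numeric(0)
  pairs$allowance <- delta
  n_i <- sum(pairs$ref_len) + sum(sets$unmatched$length)
  num <- sum((pairs$minov + delta) / pairs$maxov * pairs$ref_len)
  list(state = state,
       sov = num / n_i,
       n = n_i,
       pairs = pairs,
       unmatched = sets$unmatched)
}

# Shared aggregation for both SOV variants: iterate over the states present
# in the reference (states only in the prediction are never scored
# directly) and combine per-state scores weighted by their normalizers.
sov_aggregate <- function(ref, pred, allowance_fn) {
  ref_segs <- extract_segments(ref)
  pred_segs <- extract_segments(pred)
  per_state <- lapply(ref$alphabet, sov_state,
                      ref_segs = ref_segs, pred_segs = pred_segs,
                      allowance_fn = allowance_fn)
  names(per_state) <- ref$alphabet
  n <- vapply(per_state, `[[`, numeric(1), "n")
  s <- vapply(per_state, `[[`, numeric(1), "sov")
  list(overall = sum(s * n) / sum(n), per_state = per_state)
}

#' Refined segment overlap score (SOV_refine)
#'
#' Scores a predicted segmentation against a reference by segment overlap,
#' with a boundary allowance drawn from a reference-wide budget
#' ([delta_all()]) and apportioned per pair by [delta_refine()]. Per-state
#' scores
#' \deqn{SOV(i) = \frac{1}{N(i)} \sum_{S(i)}
#'   \frac{minov + \delta(s_1,s_2)}{maxov} \, len(s_1)}
#' are combined over the states present in the reference, weighted by their
#' normalizers \eqn{N(i)}:
#' \deqn{SOV\_refine = \sum_i SOV(i) N(i) \big/ \sum_i N(i).}
#' Unlike SOV'99, the allowance grows with every additional correctly
#' assigned position, so improving a prediction by one residue always
#' increases the score, by an increasing amount.
#'
#' @param ref,pred Equal-length state sequences (or strings).
#' @param lambda Positive stringency parameter scaling the allowance
#'   budget; default 1. Smaller values are more stringent.
#'
#' @return A `sov_score` object: list with `method`, `lambda`, `overall`,
#'   `q_score`, `per_state` (each with `sov`, `n`, pair decomposition),
#'   `delta_all`, `n_states`, `length`.
#'
#' @examples
#' sov_refine("CHHHHHHHHHHC", "CCCHHHHHHHHC")$overall   # 0.937
#' sov_refine("AABBBBBBCCCCCCDD", "AAAAABBBCCCDDDDD", lambda = 0.1)
#' @seealso [sov99()], [q_score()], [sliding_best_score()]
#' @export
sov_refine <- function(ref, pred, lambda = 1) {
  sp <- check_pair(ref, pred)
  d_all <- delta_all(sp$ref, lambda)
  len_r <- sp$ref$length
  agg <- sov_aggregate(sp$ref, sp$pred, function(pairs) {
    delta_refine(pairs$minov, pairs$maxov, pairs$ref_len, len_r, d_all)
  })
  new_sov_score("sov_refine", sp, agg, lambda = lambda, d_all = d_all)
}

#' Normalized 1999 segment overlap score (SOV'99)
#'
#' The widely used 1999 SOV definition: same per-state form and
#' normalization as [sov_refine()], but with the integer per-pair allowance
#' of [delta_sov99()], which depends only on the pair's own overlap and
#' segment lengths.
#'
#' @inheritParams sov_refine
#'
#' @return A `sov_score` object (see [sov_refine()]); `lambda` and
#'   `delta_all` are `NA` for this method.
#'
#' @examples
#' sov99("CHHHHHHHHHHC", "CCCHHHHHHHHC")$overall   # 0.944
#' @export
sov99 <- function(ref, pred) {
  sp <- check_pair(ref, pred)
  agg <- sov_aggregate(sp$ref, sp$pred, function(pairs) {
    delta_sov99(pairs$minov, pairs$maxov, pairs$ref_len, pairs$pred_len)
  })
  new_sov_score("sov99", sp, agg, lambda = NA_real_, d_all = NA_real_)
}

new_sov_score <- function(method, sp, agg, lambda, d_all) {
  structure(
    list(method = method,
         lambda = lambda,
         overall = agg$overall,
         q_score = mean(sp$ref$states == sp$pred$states),
         per_state = agg$per_state,
         delta_all = d_all,
         n_states = length(sp$ref$alphabet),
         length = sp$ref$length,
         ref_label = sp$ref$label,
         pred_label = sp$pred$label),
    class = "sov_score"
  )
}

#' @export
print.sov_score <- function(x, digits = 3, ...) {
  cat(sprintf("<sov_score> method: %s%s\n", x$method,
              if (!is.na(x$lambda)) sprintf(" (lambda = %g)", x$lambda) else ""))
  cat(sprintf("  overall: %s   Q: %s   length: %d   states: %d\n",
              format_score(x$overall, digits), format_score(x$q_score, digits),
              x$length, x$n_states))
  if (!is.na(x$delta_all)) {
    cat(sprintf("  delta(all): %s\n", format_score(x$delta_all, digits)))
  }
  for (ps in x$per_state) {
    cat(sprintf("  state %s: SOV = %s, N = %d (%d pair(s), %d unmatched)\n",
                ps$state, format_score(ps$sov, digits), as.integer(ps$n),
                nrow(ps$pairs), nrow(ps$unmatched)))
  }
  invisible(x)
}

# Round half away from zero (round() rounds half to even, which would turn
# e.g. 0.9375 into 0.937 or 0.938 depending on binary representation).
round_half_up <- function(x, digits = 3) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

format_score <- function(x, digits = 3) {
  formatC(round_half_up(x, digits), format = "f", digits = digits)
}

#' Score a pair with one or all methods
#'
#' Convenience wrapper evaluating `q`, `sov99` and/or `sov_refine` on a
#' sequence pair and returning a tidy one-row-per-method table.
#'
#' @inheritParams sov_refine
#' @param method `"all"` (default) or any subset of
#'   `c("q", "sov99", "sov_refine")`.
#'
#' @return A `data.frame` with columns `method`, `lambda`, `score`.
#'
#' @examples
#' score_pair("CHHHHHHHHHHC", "CCCHHHHHHHHC")
#' @export
score_pair <- function(ref, pred, method = "all", lambda = 1) {
  methods <- c("q", "sov99", "sov_refine")
  if (identical(method, "all")) method <- methods
  method <- match.arg(method, methods, several.ok = TRUE)
  rows <- lapply(method, function(m) {
    score <- switch(m,
      q = q_score(ref, pred),
      sov99 = sov99(ref, pred)$overall,
      sov_refine = sov_refine(ref, pred, lambda)$overall)
    data.frame(method = m,
               lambda = if (m == "sov_refine") lambda else NA_real_,
               score = score, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
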