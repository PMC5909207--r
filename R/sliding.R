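#' Best score of a short sequence along a longer one
#'
#' The core scorers require equal lengths. For unequal-length pairs (e.g.
#' two protein chains of different size) the shorter sequence is compared
#' against every window of its own length on the longer sequence, at
#' offsets `0, step, 2*step, ...`; a final window that would extend past
#' the end is skipped. The reported score is the maximum over windows, the
#' standard reduction when no alignment anchoring is available. The shorter
#' sequence plays the reference role in each comparison.
#'
#' @param short,long State sequences (or strings) with
#'   `length(short) <= length(long)`.
#' @param step Positive integer offset increment; default 1 (gapless
#'   sliding). Coarser steps (e.g. 20) trade resolution for speed on large
#'   collections.
#' @param scorer Method name (`"q"`, `"sov99"`, `"sov_refine"`) or a
#'   function `f(ref, pred)` returning a single number.
#' @param lambda Stringency parameter passed through when `scorer` is
#'   `"sov_refine"`.
#'
#' @return List with `best` (maximum score), `offset` (0-based start of the
#'   first window achieving it), and `scores` (one score per window, in
#'   offset order).
#'
#' @examples
#' sliding_best_score("HH", "CCHHCC", scorer = "q")
#' @export
sliding_best_score <- function(short, long, step = 1L,
                               scorer = "sov_refine", lambda = 1) {
  short <- state_sequence(short)
  long <- state_sequence(long)
  if (short$length > long$length) {
    stop(sprintf("first sequence (length %d) must not be longer than second (length %d)",
                 short$length, long$length), call. = FALSE)
  }
  step <- as.integer(step)
  if (is.na(step) || step < 1L) {
    stop("step must be a positive integer", call. = FALSE)
  }
  fn <- if (is.function(scorer)) {
    scorer
  } else {
    switch(match.arg(scorer, c("q", "sov99", "sov_refine")),
           q = q_score,
           sov99 = function(r, p) sov99(r, p)$overall,
           sov_refine = function(r, p) sov_refine(r, p, lambda)$overall)
  }
  offsets <- seq.int(0L, long$length - short$length, by = step)
  scores <- vapply(offsets, function(off) {
    window <- state_sequence(long$states[(off + 1L):(off + short$length)])
    fn(short, window)
  }, numeric(1))
  best_idx <- which.max(scores)
  list(best = scores[best_idx], offset = offsets[best_idx], scores = scores)
}
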