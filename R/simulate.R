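# Run a block under a fixed seed, leaving the caller's RNG state intact.
# One integer seed fully determines a generator call.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Generate a random segmented state sequence
#'
#' Draws a state sequence of the requested length whose segment lengths are
#' geometric with the given mean (the simplest memoryless run-length
#' model); consecutive segments always change state, drawn uniformly from
#' the remaining labels. Labels are `A`, `B`, `C`, ... With
#' `mean_segment_length` around 6 and 3 states this loosely mimics
#' secondary-structure strings; 2 states with long runs mimics TAD
#' body/boundary strings.
#'
#' @param length Positive sequence length.
#' @param alphabet_size Number of distinct labels available, 2-8.
#' @param mean_segment_length Positive target mean run length.
#' @param seed Integer seed; the same seed reproduces the same sequence
#'   without touching the caller's RNG state.
#'
#' @return A `state_sequence`.
#'
#' @examples
#' as.character(random_state_sequence(30, 3, 6, seed = 1))
#' @export
random_state_sequence <- function(length, alphabet_size = 3,
                                  mean_segment_length = 6, seed) {
  if (alphabet_size < 2 || alphabet_size > 8) {
    stop("alphabet_size must be between 2 and 8", call. = FALSE)
  }
  if (length < 1) stop("length must be positive", call. = FALSE)
  if (mean_segment_length <= 0) {
    stop("mean_segment_length must be positive", call. = FALSE)
  }
  with_local_seed(seed, {
    labels <- LETTERS[seq_len(alphabet_size)]
    states <- character(0)
    prev <- NA_character_
    while (base::length(states) < length) {
      pool <- if (is.na(prev)) labels else setdiff(labels, prev)
      lab <- sample(pool, 1L)
      run <- 1L + stats::rgeom(1L, prob = min(1, 1 / mean_segment_length))
      states <- c(states, rep(lab, run))
      prev <- lab
    }
    state_sequence(states[seq_len(length)])
  })
}

#' Generate a reference/prediction pair by perturbing a random sequence
#'
#' Draws a reference with [random_state_sequence()] and derives a
#' prediction by applying one named perturbation:
#' \describe{
#'   \item{`boundary_shift`}{each internal segment boundary moves, with
#'     probability `intensity`, by 1-3 positions in a random direction
#'     (bounded so segments never vanish) — emulating callers that agree on
#'     segments but disagree on their edges.}
#'   \item{`segment_split`}{each segment of length >= 3 is, with probability
#'     `intensity`, broken by relabelling one interior position —
#'     emulating spurious short calls.}
#'   \item{`relabel`}{each segment is, with probability `intensity`,
#'     relabelled to a different state (or to `relabel_to` if given) —
#'     emulating outright misclassification.}
#' }
#' `intensity = 0` returns an identical pair under every mutation.
#'
#' @inheritParams random_state_sequence
#' @param mutation One of `"boundary_shift"`, `"segment_split"`,
#'   `"relabel"`.
#' @param intensity Perturbation probability in `[0, 1]`.
#' @param relabel_to Optional fixed target label for `"relabel"` (may be a
#'   label absent from the alphabet, producing a totally mismatched
#'   prediction at `intensity = 1`).
#'
#' @return List with `ref` and `pred` (`state_sequence`s of equal length).
#'
#' @examples
#' pr <- random_pair(50, 3, 6, seed = 42, mutation = "boundary_shift",
#'                   intensity = 0.5)
#' sov_refine(pr$ref, pr$pred)$overall
#' @export
random_pair <- function(length, alphabet_size = 3, mean_segment_length = 6,
                        seed,
                        mutation = c("boundary_shift", "segment_split",
                                     "relabel"),
                        intensity = 0.5, relabel_to = NULL) {
  mutation <- match.arg(mutation)
  if (intensity < 0 || intensity > 1) {
    stop("intensity must be in [0, 1]", call. = FALSE)
  }
  ref <- random_state_sequence(length, alphabet_size, mean_segment_length,
                               seed = seed)
  pred <- with_local_seed(seed + 1L, {
    states <- ref$states
    labels <- LETTERS[seq_len(alphabet_size)]
    if (intensity > 0) {
      segs <- extract_segments(ref)
      if (mutation == "boundary_shift") {
        for (b in seq_len(nrow(segs) - 1L)) {
          if (stats::runif(1) >= intensity) next
          pos <- segs$end[b]  # boundary between segment b and b+1
          shift <- sample(c(-3:-1, 1:3), 1L)
          # keep at least one position of each flanking segment
          lo <- segs$start[b] + 1L
          hi <- segs$end[b + 1L] - 1L
          new_pos <- min(max(pos + shift, lo), hi)
          left_lab <- segs$state[b]
          right_lab <- segs$state[b + 1L]
          if (new_pos < pos) {
            states[(new_pos + 1L):pos] <- right_lab
          } else if (new_pos > pos) {
            states[(pos + 1L):new_pos] <- left_lab
          }
        }
      } else if (mutation == "segment_split") {
        for (k in seq_len(nrow(segs))) {
          if (segs$length[k] < 3L || stats::runif(1) >= intensity) next
          pos <- sample(seq.int(segs$start[k] + 2L, segs$end[k] - 1L), 1L)
          states[pos] <- sample(setdiff(labels, segs$state[k]), 1L)
        }
      } else {  # relabel
        for (k in seq_len(nrow(segs))) {
          if (stats::runif(1) >= intensity) next
          new_lab <- if (!is.null(relabel_to)) {
            relabel_to
          } else {
            sample(setdiff(labels, segs$state[k]), 1L)
          }
          states[(segs$start[k] + 1L):segs$end[k]] <- new_lab
        }
      }
    }
    state_sequence(states)
  })
  list(ref = ref, pred = pred)
}
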