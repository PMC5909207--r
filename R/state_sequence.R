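#' Construct a validated state sequence
#'
#' A state sequence is an ordered string of single-character state labels,
#' e.g. a three-state secondary-structure string (`"CHHHHHHHHHHC"`) or a
#' two-state TAD body/boundary string (`"DDDDBBDDDD"`). Labels are
#' case-sensitive; whitespace (including line breaks from folded input) is
#' stripped. Any single-character alphabet is accepted.
#'
#' @param x A single string, or a character vector of single-character
#'   labels. An existing `state_sequence` is returned unchanged.
#' @param label Optional free-text identifier carried along for reporting.
#'
#' @return An object of class `state_sequence`: a list with elements
#'   `states` (character vector, one label per position), `length`,
#'   `alphabet` (sorted distinct labels present), and `label`.
#'
#' @examples
#' s <- state_sequence("CHHHHHHHHHHC")
#' s$length
#' s$alphabet
#' @export
state_sequence <- function(x, label = NULL) {
  if (inherits(x, "state_sequence")) {
    if (!is.null(label)) x$label <- label
    return(x)
  }
  if (!is.character(x) || length(x) == 0L) {
    stop("state sequence input must be a non-empty character string or vector",
         call. = FALSE)
  }
  if (length(x) == 1L) {
    x <- gsub("[[:space:]]", "", x)
    states <- strsplit(x, "", fixed = TRUE)[[1L]]
  } else {
    states <- x[!grepl("^[[:space:]]*$", x)]
  }
  if (length(states) == 0L) {
    stop("state sequence is empty after stripping whitespace", call. = FALSE)
  }
  if (any(nchar(states) != 1L)) {
    stop("state labels must be single characters", call. = FALSE)
  }
  structure(
    list(states = states,
         length = length(states),
         alphabet = sort(unique(states)),
         label = if (is.null(label)) NA_character_ else as.character(label)),
    class = "state_sequence"
  )
}

#' @export
print.state_sequence <- function(x, ...) {
  cat(sprintf("<state_sequence> length %d, %d state(s): %s\n",
              x$length, length(x$alphabet),
              paste(x$alphabet, collapse = " ")))
  seq_str <- paste(x$states, collapse = "")
  if (nchar(seq_str) > 70) seq_str <- paste0(substr(seq_str, 1, 67), "...")
  cat(" ", seq_str, "\n")
  invisible(x)
}

#' @export
as.character.state_sequence <- function(x, ...) paste(x$states, collapse = "")

#' @export
length.state_sequence <- function(x) x$length

# Shared validation for the pairwise scorers: coerce, check equal length,
# and warn once when the reference alphabet is large enough that
# per-position accuracy would be the more meaningful measure.
check_pair <- function(ref, pred) {
  ref <- state_sequence(ref)
  pred <- state_sequence(pred)
  if (ref$length != pred$length) {
    stop(sprintf(paste0("reference and prediction must have equal length ",
                        "(got %d and %d); use sliding_best_score() for ",
                        "unequal lengths"),
                 ref$length, pred$length), call. = FALSE)
  }
  if (length(ref$alphabet) > 10L) {
    warning(sprintf(paste0("reference has %d distinct states; segment ",
                           "overlap scores lose usefulness with many states ",
                           "- consider per-position accuracy (q_score)"),
                    length(ref$alphabet)), call. = FALSE)
  }
  list(ref = ref, pred = pred)
}
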