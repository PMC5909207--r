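#' Read a state sequence from a text file
#'
#' Two dialects are supported: `plain` — the whole file is one sequence,
#' with arbitrary line folding and whitespace stripped; `fasta` — the first
#' record's sequence lines are joined (a warning is emitted if the file
#' holds more records).
#'
#' @param path Path to the file.
#' @param format `"plain"` (default) or `"fasta"`.
#'
#' @return A `state_sequence`; its `label` is the FASTA header (first word)
#'   or the file name for plain files.
#'
#' @export
read_state_sequence <- function(path, format = c("plain", "fasta")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  if (format == "fasta") {
    headers <- grep("^>", lines)
    if (length(headers) == 0L) {
      stop(sprintf("no FASTA record in %s", path), call. = FALSE)
    }
    if (length(headers) > 1L) {
      warning(sprintf("%s holds %d FASTA records; using the first",
                      path, length(headers)), call. = FALSE)
    }
    first <- headers[1L]
    last <- if (length(headers) > 1L) headers[2L] - 1L else length(lines)
    label <- sub("^>\\s*", "", lines[first])
    label <- strsplit(label, "\\s+")[[1L]][1L]
    body <- lines[seq.int(first + 1L, length.out = max(0L, last - first))]
    state_sequence(paste(body, collapse = ""), label = label)
  } else {
    state_sequence(paste(lines, collapse = ""), label = basename(path))
  }
}

#' Read a reference/prediction sequence pair
#'
#' Reads both files with [read_state_sequence()] and checks lengths:
#' unequal lengths are an error unless `allow_unequal = TRUE` (the
#' sliding-window path).
#'
#' @param ref_path,pred_path Paths to the reference and predicted
#'   sequence files.
#' @param format `"plain"` or `"fasta"`, applied to both files.
#' @param allow_unequal Permit different lengths (for
#'   [sliding_best_score()]).
#'
#' @return List with elements `ref` and `pred` (`state_sequence`s).
#'
#' @export
read_pair <- function(ref_path, pred_path, format = c("plain", "fasta"),
                      allow_unequal = FALSE) {
  format <- match.arg(format)
  ref <- read_state_sequence(ref_path, format)
  pred <- read_state_sequence(pred_path, format)
  if (!allow_unequal && ref$length != pred$length) {
    stop(sprintf(paste0("reference (%s, length %d) and prediction (%s, ",
                        "length %d) differ in length; rerun with sliding ",
                        "mode to compare them"),
                 ref_path, ref$length, pred_path, pred$length),
         call. = FALSE)
  }
  list(ref = ref, pred = pred)
}
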