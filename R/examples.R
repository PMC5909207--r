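#' Canonical worked examples with their expected scores
#'
#' The two benchmark example sets used throughout the SOV literature: a
#' three-state secondary-structure reference (`CHHHHHHHHHHC`) with eight
#' predictions of graded quality — predictions 4 through 8 grow a single
#' centred helix run one residue at a time, the case that exposes SOV'99's
#' non-incremental allowance — and a four-state reference
#' (`AABBBBBBCCCCCCDD`) with four predictions scored at several stringency
#' levels. Expected values are the published 3-decimal scores for each
#' method; the test suite and acceptance checks recompute every cell.
#'
#' @return A `data.frame` with columns `set` (`"three_state"` /
#'   `"four_state"`), `label`, `reference`, `predicted`, `q`, `sov99`,
#'   `sov_refine_1`, `sov_refine_0.5`, `sov_refine_0.1` (the latter two
#'   `NA` for the three-state set, which is only published at
#'   `lambda = 1`).
#'
#' @examples
#' ex <- worked_examples()
#' subset(ex, set == "three_state", c(label, predicted, sov_refine_1))
#' @export
worked_examples <- function() {
  three_ref <- "CHHHHHHHHHHC"
  three <- data.frame(
    set = "three_state",
    label = paste0("predicted_", 1:8),
    reference = three_ref,
    predicted = c("CHCHCHCHCHCC", "CHHHCHHHCHHC", "CHHCCHHHHHCC",
                  "CCCHHHHCCCCC", "CCCHHHHHCCCC", "CCCHHHHHHCCC",
                  "CCCHHHHHHHCC", "CCCHHHHHHHHC"),
    q = c(0.583, 0.833, 0.750, 0.500, 0.583, 0.667, 0.750, 0.833),
    sov99 = c(0.125, 0.406, 0.523, 0.544, 0.632, 0.806, 0.903, 0.944),
    sov_refine_1 = c(0.149, 0.371, 0.464, 0.459, 0.567, 0.678, 0.797, 0.937),
    sov_refine_0.5 = NA_real_,
    sov_refine_0.1 = NA_real_,
    stringsAsFactors = FALSE)

  four_ref <- "AABBBBBBCCCCCCDD"
  four <- data.frame(
    set = "four_state",
    label = paste0("predicted_", 1:4),
    reference = four_ref,
    predicted = c("AAAAABBBCCCDDDDD", "AAAABBBBCCCCDDDD",
                  "AAABBBBBCCCCCDDD", "AABBBBBBCCCCCDDD"),
    q = c(0.625, 0.750, 0.875, 0.938),
    sov99 = c(0.650, 0.938, 1.000, 1.000),
    sov_refine_1 = c(0.807, 0.925, 1.000, 1.000),
    sov_refine_0.5 = c(0.641, 0.850, 0.961, 0.981),
    sov_refine_0.1 = c(0.508, 0.670, 0.851, 0.925),
    stringsAsFactors = FALSE)

  rbind(three, four)
}

#' Export the worked examples as a TSV test-vector file
#'
#' Writes [worked_examples()] to a tab-separated file so other
#' implementations can consume identical fixtures.
#'
#' @param path Output file path.
#'
#' @return The path, invisibly.
#'
#' @export
write_example_vectors <- function(path) {
  utils::write.table(worked_examples(), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
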