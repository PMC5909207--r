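# Independent brute-force oracle: a literal transcription of the score
# definitions using explicit position sets (intersect/union on integer
# position vectors), deliberately sharing no code with the package's
# segment-table implementation.

oracle_runs <- function(chars) {
  n <- length(chars)
  cuts <- c(0L, which(chars[-1L] != chars[-n]), n)
  lapply(seq_len(length(cuts) - 1L), function(k) {
    pos <- (cuts[k] + 1L):cuts[k + 1L]
    list(state = chars[pos[1L]], pos = pos)
  })
}

oracle_q <- function(ref, pred) {
  r <- strsplit(ref, "")[[1L]]
  p <- strsplit(pred, "")[[1L]]
  sum(r == p) / length(r)
}

# method: "refine" or "sov99"
oracle_sov <- function(ref, pred, method, lambda = 1) {
  r <- strsplit(ref, "")[[1L]]
  p <- strsplit(pred, "")[[1L]]
  len_r <- length(r)
  ref_runs <- oracle_runs(r)
  pred_runs <- oracle_runs(p)
  states <- unique(r)

  d_all <- lambda * length(states) /
    sum(vapply(ref_runs, function(s) (length(s$pos) / len_r)^2, numeric(1)))

  num_total <- 0
  den_total <- 0
  for (st in states) {
    s1s <- Filter(function(s) s$state == st, ref_runs)
    s2s <- Filter(function(s) s$state == st, pred_runs)
    for (s1 in s1s) {
      overlapped <- FALSE
      for (s2 in s2s) {
        minov <- length(intersect(s1$pos, s2$pos))
        if (minov == 0L) next
        overlapped <- TRUE
        maxov <- length(union(s1$pos, s2$pos))
        len1 <- length(s1$pos)
        len2 <- length(s2$pos)
        delta <- if (method == "refine") {
          min(d_all * (len1 / len_r) * (minov / maxov), maxov - minov)
        } else {
          min(maxov - minov, minov, floor(len1 / 2), floor(len2 / 2))
        }
        num_total <- num_total + (minov + delta) / maxov * len1
        den_total <- den_total + len1
      }
      if (!overlapped) den_total <- den_total + length(s1$pos)
    }
  }
  num_total / den_total
}
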