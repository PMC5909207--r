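# Seeded corpus of random reference/prediction pairs spanning small to
# moderate problems: alphabets of 2-8 states, lengths 5-200, mixed
# segment-length regimes and perturbation kinds.
make_corpus <- function(n, seed = 20260101) {
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      len <- sample(5:200, 1L)
      ab <- sample(2:8, 1L)
      msl <- sample(c(2, 4, 6, 10), 1L)
      mut <- sample(c("boundary_shift", "segment_split", "relabel"), 1L)
      intensity <- stats::runif(1)
      pair_seed <- sample.int(2^30, 1L)
      pr <- random_pair(len, ab, msl, seed = pair_seed,
                        mutation = mut, intensity = intensity)
      list(ref = as.character(pr$ref), pred = as.character(pr$pred),
           lambda = stats::runif(1, 0.1, 2.4))
    })
  })
}

# Display-style rounding used when comparing against published 3-dp tables.
round3 <- function(x) sign(x) * floor(abs(x) * 1000 + 0.5) / 1000
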