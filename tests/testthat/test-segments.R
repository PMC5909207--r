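test_that("maximal-run extraction tiles the sequence in order", {
  segs <- extract_segments("CHHHHHHHHHHC")
  expect_equal(segs$state, c("C", "H", "C"))
  expect_equal(segs$start, c(0, 1, 11))
  expect_equal(segs$end, c(1, 11, 12))
  expect_equal(segs$length, c(1, 10, 1))

  expect_equal(extract_segments("A"),
               data.frame(state = "A", start = 0, end = 1, length = 1))

  segs4 <- extract_segments("AABBBBBBCCCCCCDD")
  expect_equal(nrow(segs4), 4)
  expect_equal(segs4$length, c(2, 6, 6, 2))

  # tiling: ordered, gap-free, lengths conserved (property over random refs)
  for (seed in 1:25) {
    s <- random_state_sequence(sample(5:150, 1), sample(2:8, 1),
                               sample(c(2, 5, 8), 1), seed = seed)
    segs <- extract_segments(s)
    expect_equal(sum(segs$length), s$length)
    expect_equal(segs$start[-1], segs$end[-nrow(segs)])
    expect_equal(segs$start[1], 0)
    expect_equal(segs$end[nrow(segs)], s$length)
    # maximality: consecutive segments never share a state
    expect_true(all(segs$state[-1] != segs$state[-nrow(segs)]))
  }
})

test_that("empty or malformed input is rejected", {
  expect_error(state_sequence(""), "empty")
  expect_error(state_sequence("  \n\t "), "empty")
  expect_error(state_sequence(character(0)), "non-empty")
  expect_error(state_sequence(c("AB", "C")), "single characters")
})

test_that("whitespace is stripped and labels are case-sensitive", {
  s <- state_sequence("CHH H\nHC")
  expect_equal(as.character(s), "CHHHHC")
  expect_equal(state_sequence("aA")$alphabet, c("A", "a"))
})

test_that("overlap pairing separates matched pairs from unmatched refs", {
  r <- extract_segments("CHHHHHHHHHHC")
  p <- extract_segments("CHCHCHCHCHCC")

  sets <- build_overlap_sets(r, p, "H")
  expect_equal(nrow(sets$pairs), 5)
  expect_equal(sets$pairs$minov, rep(1L, 5))
  expect_equal(sets$pairs$maxov, rep(10L, 5))
  expect_equal(nrow(sets$unmatched), 0)

  # identical segmentations: one exact pair per segment
  ident <- build_overlap_sets(r, r, "C")
  expect_equal(nrow(ident$pairs), 2)
  expect_equal(ident$pairs$minov, ident$pairs$maxov)
  expect_equal(ident$pairs$minov, ident$pairs$ref_len)
  expect_equal(nrow(ident$unmatched), 0)

  # state present in ref but absent from pred: all refs unmatched
  no_h <- build_overlap_sets(r, extract_segments("CCCCCCCCCCCC"), "H")
  expect_equal(nrow(no_h$pairs), 0)
  expect_equal(no_h$unmatched$start, 1)
  expect_equal(no_h$unmatched$length, 10)

  # state absent from ref entirely: both empty
  no_e <- build_overlap_sets(r, p, "E")
  expect_equal(nrow(no_e$pairs), 0)
  expect_equal(nrow(no_e$unmatched), 0)
})

test_that("minov and maxov are intersection and union sizes", {
  for (seed in 1:20) {
    pr <- random_pair(sample(10:120, 1), 3, 5, seed = seed,
                      mutation = "boundary_shift", intensity = 0.7)
    rs <- extract_segments(pr$ref)
    ps <- extract_segments(pr$pred)
    for (st in pr$ref$alphabet) {
      sets <- build_overlap_sets(rs, ps, st)
      if (nrow(sets$pairs) == 0) next
      with(sets$pairs, {
        expect_true(all(minov >= 1))
        expect_true(all(minov <= pmin(ref_len, pred_len)))
        expect_equal(maxov, ref_len + pred_len - minov)
      })
    }
  }
})
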