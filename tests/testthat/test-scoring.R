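test_that("per-position accuracy is the fraction of identical labels", {
  expect_equal(q_score("CHHHHHHHHHHC", "CHCHCHCHCHCC"), 7 / 12)
  expect_equal(q_score("AABBBBBBCCCCCCDD", "AABBBBBBCCCCCDDD"), 15 / 16)
  expect_equal(q_score("HECHEC", "HECHEC"), 1)
  expect_error(q_score("HH", "HHH"), "equal length")
})

test_that("every published benchmark cell reproduces at three decimals", {
  ex <- worked_examples()
  for (i in seq_len(nrow(ex))) {
    r <- ex$reference[i]
    p <- ex$predicted[i]
    expect_equal(round3(q_score(r, p)), ex$q[i], info = ex$label[i])
    expect_equal(round3(sov99(r, p)$overall), ex$sov99[i], info = ex$label[i])
    expect_equal(round3(sov_refine(r, p, 1)$overall), ex$sov_refine_1[i],
                 info = ex$label[i])
    if (!is.na(ex$sov_refine_0.5[i])) {
      expect_equal(round3(sov_refine(r, p, 0.5)$overall),
                   ex$sov_refine_0.5[i], info = ex$label[i])
      expect_equal(round3(sov_refine(r, p, 0.1)$overall),
                   ex$sov_refine_0.1[i], info = ex$label[i])
    }
  }
})

test_that("per-state decomposition carries the documented normalizers", {
  # fragmented prediction: the H segment pairs with 5 one-residue
  # predictions, so N(H) counts its length once per pair
  res <- sov_refine("CHHHHHHHHHHC", "CHCHCHCHCHCC", 1)
  h <- res$per_state$H
  expect_equal(h$n, 50)
  expect_equal(nrow(h$pairs), 5)
  expect_equal(h$sov, oracle_sov_state_h <- {
    d_all <- delta_all("CHHHHHHHHHHC")
    delta <- min(d_all * (10 / 12) * (1 / 10), 9)
    5 * ((1 + delta) / 10 * 10) / 50
  })
  expect_equal(round(h$sov, 5), 0.12353)
  # overall is the N(i)-weighted combination of per-state scores
  n <- vapply(res$per_state, `[[`, numeric(1), "n")
  s <- vapply(res$per_state, `[[`, numeric(1), "sov")
  expect_equal(res$overall, sum(n * s) / sum(n))
})

test_that("states in reference but absent from prediction score zero with full weight", {
  res <- sov_refine("HHHHEECC", "HHHHCCCC")
  expect_equal(res$per_state$E$sov, 0)
  expect_equal(res$per_state$E$n, 2)
  expect_equal(nrow(res$per_state$E$unmatched), 1)
  # prediction-only states are never scored directly
  expect_equal(sort(names(res$per_state)), c("C", "E", "H"))
})

test_that("identity scores exactly 1 for any alphabet and lambda", {
  seqs <- c("H", "DDBBDD", "CHHHHHHHHHHC", "AABBBBBBCCCCCCDD",
            as.character(random_state_sequence(120, 8, 4, seed = 7)))
  for (s in seqs) {
    expect_identical(q_score(s, s), 1)
    expect_identical(sov99(s, s)$overall, 1)
    for (lam in c(0.1, 1, 2.4)) {
      expect_identical(sov_refine(s, s, lam)$overall, 1)
    }
  }
})

test_that("totally mismatched predictions score zero", {
  expect_equal(sov_refine("HHHEEE", "CCCCCC")$overall, 0)
  expect_equal(sov99("HHHEEE", "CCCCCC")$overall, 0)
})

test_that("scorers reject unequal lengths naming both, and empty input", {
  expect_error(sov_refine("HHH", "HHHH"), "3 and 4")
  expect_error(sov99("HHH", "HH"), "equal length")
  expect_error(sov_refine("", "H"), "empty")
})

test_that("many-state references trigger a diagnostics warning", {
  r <- paste(c(LETTERS[1:11], LETTERS[1:11]), collapse = "")
  expect_warning(sov_refine(r, r), "distinct states")
  expect_silent(sov99("ABCABC", "ABCABC"))
})

test_that("scores are asymmetric in general", {
  a <- "CHHHHHHHHHHC"
  b <- "CHHHCHHHCHHC"
  expect_false(isTRUE(all.equal(sov_refine(a, b)$overall,
                                sov_refine(b, a)$overall)))
})

test_that("score_pair returns one tidy row per requested method", {
  tab <- score_pair("CHHHHHHHHHHC", "CCCHHHHHHHHC", lambda = 1)
  expect_equal(tab$method, c("q", "sov99", "sov_refine"))
  expect_equal(tab$score[1], q_score("CHHHHHHHHHHC", "CCCHHHHHHHHC"))
  expect_equal(tab$score[3],
               sov_refine("CHHHHHHHHHHC", "CCCHHHHHHHHC")$overall)
  one <- score_pair("HH", "HH", method = "sov99")
  expect_equal(nrow(one), 1)
  expect_equal(one$score, 1)
})
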