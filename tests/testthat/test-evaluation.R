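# exhaustive oracle: maximum monotone matching by recursion over all
# order-preserving pairings under the residue/prefix tolerance rules
oracle_match <- function(pred, truth, vocab, rtol = 0.1, ptol = 0.5) {
  pm <- residue_mass(tokenize_peptide(pred, vocab), vocab)
  tm <- residue_mass(tokenize_peptide(truth, vocab), vocab)
  pp <- c(0, cumsum(pm)); tp <- c(0, cumsum(tm))
  rec <- function(i, j) {
    if (i > length(pm) || j > length(tm)) return(0L)
    best <- max(rec(i + 1L, j), rec(i, j + 1L))
    if (abs(pm[i] - tm[j]) < rtol && abs(pp[i] - tp[j]) < ptol)
      best <- max(best, 1L + rec(i + 1L, j + 1L))
    best
  }
  rec(1L, 1L)
}

test_that("identical peptides match fully; I/L are interchangeable", {
  v <- residue_vocab()
  r <- match_residues("GAVSLTPK", "GAVSLTPK", v)
  expect_identical(r$n_matched, 8L)
  expect_true(r$peptide_match)
  r2 <- match_residues("IAVSK", "LAVSK", v)
  expect_identical(r2$n_matched, 5L)     # identical masses at position 1
  expect_true(r2$peptide_match)
})

test_that("near-isobaric substitutions match by mass, not identity", {
  v <- residue_vocab()
  # Q (128.05858) vs K (128.09496): within 0.1 Da
  r <- match_residues("QAV", "KAV", v)
  expect_identical(r$n_matched, 3L)
  # GA vs Q: total masses nearly equal but neither residue matches
  r2 <- match_residues("GA", "Q", v)
  expect_identical(r2$n_matched, 0L)
  expect_false(r2$peptide_match)
})

test_that("prefix tolerance gates matches after a mass shift", {
  v <- residue_vocab()
  # a W->G swap early shifts all later prefixes by ~129 Da: no later match
  r <- match_residues("WGAVSK", "GGAVSK", v)
  expect_identical(r$n_matched, 0L)
  # a G<->A swap shifts prefixes by 14 Da < 0.5? no: 14 > 0.5, so only
  # the shared first residue matches
  r2 <- match_residues("GASK", "GVSK", v)
  expect_identical(r2$n_matched, 1L)
})

test_that("empty predictions count zero matches and are flagged", {
  v <- residue_vocab()
  r <- match_residues("", "GAVK", v)
  expect_identical(r$n_matched, 0L)
  expect_identical(r$pred_length, 0L)
  m <- corpus_metrics(list(r))
  expect_equal(unname(m["aa_precision"]), 0)
  expect_true(attr(m, "no_predictions"))
})

test_that("corpus metrics aggregate matched residues over lengths", {
  v <- residue_vocab()
  perfect <- match_residues("GAVSLTPK", "GAVSLTPK", v)           # 8/8
  wrong <- match_residues(strrep("W", 8), strrep("G", 10), v)    # 0 of 10
  m <- corpus_metrics(list(perfect, wrong))
  expect_equal(unname(m["aa_recall"]), 8 / 18)
  expect_equal(unname(m["aa_precision"]), 8 / 16)
  expect_equal(unname(m["peptide_recall"]), 0.5)
  all_good <- corpus_metrics(list(perfect, perfect))
  expect_equal(unname(all_good), rep(1, 4), tolerance = 1e-12)
})

test_that("precision and recall swap when pred and truth swap", {
  v <- residue_vocab()
  set.seed(51)
  toks <- v$tokens[1:20]
  for (i in 1:10) {
    a <- paste(sample(toks, sample(3:8, 1), replace = TRUE), collapse = "")
    b <- paste(sample(toks, sample(3:8, 1), replace = TRUE), collapse = "")
    m1 <- corpus_metrics(list(match_residues(a, b, v)))
    m2 <- corpus_metrics(list(match_residues(b, a, v)))
    expect_equal(unname(m1["aa_precision"]), unname(m2["aa_recall"]))
    expect_equal(unname(m1["aa_recall"]), unname(m2["aa_precision"]))
  }
})

test_that("dp matching agrees with the exhaustive oracle on random pairs", {
  v <- residue_vocab()
  set.seed(52)
  toks <- v$tokens[1:20]
  for (i in 1:60) {
    a <- paste(sample(toks, sample(1:8, 1), replace = TRUE), collapse = "")
    b <- paste(sample(toks, sample(1:8, 1), replace = TRUE), collapse = "")
    expect_identical(match_residues(a, b, v)$n_matched,
                     oracle_match(a, b, v))
  }
})

test_that("pr curve sweeps thresholds with monotone coverage", {
  # 2 correct at high confidence, 2 wrong at low confidence
  curve <- pr_curve(c(0.9, 0.8, 0.3, 0.2), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(curve$precision[curve$threshold == 0.8], 1.0)
  expect_equal(curve$recall[curve$threshold == 0.8], 0.5)
  expect_equal(curve$precision[curve$threshold == 0.2], 0.5)
  expect_true(all(diff(curve$coverage) >= 0))  # descending thresholds
  # single correct prediction
  c1 <- pr_curve(0.7, TRUE)
  expect_equal(c1$precision, 1)
  expect_equal(c1$recall, 1)
  # all-equal confidences collapse to a single point
  c2 <- pr_curve(rep(0.5, 4), c(TRUE, FALSE, TRUE, FALSE))
  expect_identical(nrow(c2), 1L)
  expect_equal(c2$precision, 0.5)
})
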