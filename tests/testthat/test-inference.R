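test_that("candidate search ranks by shared unique k-mers and aligns", {
  db <- data.frame(
    accession = c("A", "B", "C"),
    description = "",
    sequence = c("GGGAVLSTPKGGG",      # shares many contig 5-mers
                 "TTTTAVLSTTTTT",      # shares fewer
                 "WWWWWWWWWWWWW"),     # shares none
    stringsAsFactors = FALSE)
  cand <- search_candidates("GAVLSTPK", db, k = 5, identity_threshold = 0.8)
  expect_identical(cand$accession[1], "A")
  expect_true(all(cand$U == sort(cand$U, decreasing = TRUE)))
  expect_false("C" %in% cand$accession)
  # exact substring: identity 1 hit
  hitA <- cand[cand$accession == "A", ]
  expect_equal(hitA$identity, 1.0)
  expect_identical(hitA$status, "hit")
  # contig sharing no k-mer with any protein: empty
  none <- search_candidates("EDEDEDED", db, k = 5)
  expect_identical(nrow(none), 0L)
  # empty database: empty result
  expect_identical(nrow(search_candidates("GAVLSTPK", db[0, ], k = 5)), 0L)
})

test_that("scan stops after the configured run of consecutive rejects", {
  seqs <- c(paste0("GAVLS", strrep("W", 20)),   # shares one 5-mer, poor identity
            paste0("AVLST", strrep("F", 20)),
            paste0("VLSTP", strrep("Y", 20)),
            paste0("GGGGG", "GAVLSTPKEDRN"))    # true source, fewer shared k-mers
  db <- data.frame(accession = sprintf("P%d", seq_along(seqs)),
                   description = "", sequence = seqs,
                   stringsAsFactors = FALSE)
  full <- search_candidates("GAVLSTPKEDRN", db, k = 5,
                            identity_threshold = 0.9, max_rejects = 8)
  expect_true("P4" %in% full$accession[full$status == "hit"])
  limited <- search_candidates("GAVLSTPKEDRN", db, k = 5,
                               identity_threshold = 0.9, max_rejects = 1)
  expect_lte(nrow(limited), nrow(full))
})

test_that("iterative scoring reproduces the worked examples", {
  # c2 is degenerate between P1 and P2
  hits <- data.frame(contig = c("c1", "c2", "c2", "c3"),
                     accession = c("P1", "P1", "P2", "P2"))
  scores <- c(c1 = 0.9, c2 = 0.8, c3 = 0.5)
  out <- infer_proteins(hits, scores)
  p1 <- out[out$accession == "P1", ]
  p2 <- out[out$accession == "P2", ]
  expect_equal(p1$score, 1.7)           # round 1: P1 = 1.7 beats P2 = 1.3
  expect_setequal(p1$contigs[[1]], c("c1", "c2"))
  expect_equal(p2$score, 0.5)           # round 2 recomputed over {c3}
  expect_setequal(p2$contigs[[1]], "c3")
  expect_true(all(is.na(out$subset_of)))

  # P2 only associated with the degenerate contig: becomes a subset of P1
  hits2 <- data.frame(contig = c("c1", "c2", "c2"),
                      accession = c("P1", "P1", "P2"))
  out2 <- infer_proteins(hits2, scores[c("c1", "c2")])
  p2b <- out2[out2$accession == "P2", ]
  expect_identical(p2b$subset_of, "P1")
  expect_length(p2b$contigs[[1]], 0L)

  # single protein, single contig
  out3 <- infer_proteins(data.frame(contig = "c1", accession = "P9"),
                         c(c1 = 0.4))
  expect_equal(out3$score, 0.4)
  expect_setequal(out3$contigs[[1]], "c1")
})

test_that("every contig ends in exactly one protein's assignment", {
  set.seed(41)
  for (rep in 1:25) {
    np <- sample(2:6, 1); nc <- sample(2:12, 1)
    cn <- sprintf("c%02d", seq_len(nc))
    hits <- do.call(rbind, lapply(seq_len(np), function(p) {
      take <- sample(cn, sample(seq_len(nc), 1))
      data.frame(contig = take, accession = sprintf("P%02d", p))
    }))
    scores <- setNames(round(runif(nc), 3), cn)
    out <- infer_proteins(hits, scores)
    assigned <- unlist(out$contigs)
    expect_setequal(assigned, unique(hits$contig))
    expect_identical(anyDuplicated(assigned), 0L)
    expect_same_inference(hits, scores)
  }
})

test_that("protein report computes coverage and accuracy from alignments", {
  set.seed(71)   # aperiodic sequence so local alignments are unambiguous
  prot <- paste(sample(c("G", "A", "S", "V", "L", "T", "P", "K", "E", "D",
                         "R", "N", "Q", "H", "F", "W", "Y", "C", "M"),
                       60, replace = TRUE), collapse = "")
  db <- data.frame(accession = "T1", description = "",
                   sequence = prot, stringsAsFactors = FALSE)
  # one contig equal to the full protein
  asg <- data.frame(accession = "T1", score = 1,
                    subset_of = NA_character_, stringsAsFactors = FALSE)
  asg$contigs <- list("ctg1")
  rep1 <- protein_report(asg, c(ctg1 = prot), db)
  expect_equal(rep1$coverage_pct, 100)
  expect_equal(rep1$accuracy_pct, 100)
  expect_equal(rep1$longest_pct, 100)
  # two adjacent halves: coverage 100, longest 50
  asg2 <- asg; asg2$contigs <- list(c("h1", "h2"))
  halves <- c(h1 = substr(prot, 1, 30), h2 = substr(prot, 31, 60))
  rep2 <- protein_report(asg2, halves, db)
  expect_equal(rep2$coverage_pct, 100)
  expect_equal(rep2$longest_pct, 50)
  # a contig below 80% identity is excluded: substitutions every third
  # position keep the local alignment spanning but drop identity to ~2/3
  ch <- strsplit(substr(prot, 1, 30), "")[[1]]
  ch[seq(2, 30, 3)] <- ifelse(ch[seq(2, 30, 3)] == "W", "Y", "W")
  bad <- paste(ch, collapse = "")
  asg3 <- asg; asg3$contigs <- list("bad")
  rep3 <- protein_report(asg3, c(bad = bad), db)
  expect_identical(rep3$n_contigs, 0L)
})
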