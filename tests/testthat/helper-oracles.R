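# Independent brute-force simulator of the 4-step iterative protein
# scoring, used to cross-check infer_proteins().
brute_force_infer <- function(hits, scores, recompute = TRUE) {
  assoc <- lapply(split(hits$contig, hits$accession), unique)
  pending <- sort(names(assoc))
  unassigned <- unique(hits$contig)
  frozen <- vapply(pending, function(p) sum(scores[assoc[[p]]]), numeric(1))
  out <- list()
  last <- NA_character_
  while (length(unassigned) && length(pending)) {
    prov <- vapply(pending, function(p)
      if (recompute) sum(scores[intersect(assoc[[p]], unassigned)])
      else frozen[[p]], numeric(1))
    best <- pending[order(-prov, pending)][1]
    take <- intersect(assoc[[best]], unassigned)
    out[[best]] <- list(score = unname(prov[best]), contigs = take,
                        subset_of = NA_character_)
    unassigned <- setdiff(unassigned, take)
    pending <- setdiff(pending, best)
    last <- best
    gone <- pending[vapply(pending, function(p)
      !length(intersect(assoc[[p]], unassigned)), logical(1))]
    for (p in gone) out[[p]] <- list(score = 0, contigs = character(0),
                                     subset_of = last)
    pending <- setdiff(pending, gone)
  }
  out
}

expect_same_inference <- function(hits, scores) {
  got <- infer_proteins(hits, scores)
  want <- brute_force_infer(hits, scores)
  expect_setequal(got$accession, names(want))
  for (i in seq_len(nrow(got))) {
    w <- want[[got$accession[i]]]
    expect_equal(got$score[i], w$score)
    expect_setequal(got$contigs[[i]], w$contigs)
    expect_identical(got$subset_of[i], w$subset_of)
  }
}
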