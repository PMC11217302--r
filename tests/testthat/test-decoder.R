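# independent oracle: enumerate all residue multisets up to a mass bound
enumerate_sums <- function(masses, max_mass, resolution) {
  sums <- 0
  frontier <- 0
  repeat {
    new <- unique(round(as.numeric(outer(frontier, masses, `+`)), 9))
    new <- new[new <= max_mass + resolution / 2]
    new <- setdiff(new, sums)
    if (!length(new)) break
    sums <- c(sums, new)
    frontier <- new
  }
  sort(unique(round(sums / resolution)))
}

test_that("knapsack table equals exhaustive multiset enumeration (toy)", {
  kt <- build_knapsack(c(X = 1.0, Y = 2.5), resolution = 0.1, max_mass = 5)
  feas <- (which(kt$feasible) - 1) * 0.1
  expect_equal(sort(feas), c(0, 1, 2, 2.5, 3, 3.5, 4, 4.5, 5),
               tolerance = 1e-9)
  expect_false(knapsack_feasible(kt, 0.7, tolerance = 0.01))
  expect_true(knapsack_feasible(kt, 3.5, tolerance = 0.01))
  expect_error(build_knapsack(c(X = 1), resolution = 0, max_mass = 5),
               "positive")
  expect_error(build_knapsack(c(X = 1), resolution = 0.1, max_mass = -1),
               "positive")
})

test_that("knapsack matches enumeration over random small vocabularies", {
  set.seed(21)
  for (rep in 1:10) {
    n <- sample(1:3, 1)
    masses <- round(runif(n, 0.5, 9.5), 1)
    names(masses) <- LETTERS[seq_len(n)]
    for (res in c(0.1, 0.01)) {
      kt <- build_knapsack(masses, resolution = res, max_mass = 30)
      want <- enumerate_sums(masses, 30, res)
      expect_identical(which(kt$feasible) - 1L, as.integer(want))
    }
  }
})

test_that("poly-glycine multiples are feasible in the full vocabulary", {
  v <- residue_vocab()
  kt <- build_knapsack(v, resolution = 1e-4, max_mass = 600)
  g <- 57.021464
  for (k in 1:10)
    expect_true(knapsack_feasible(kt, k * g, tolerance = 1e-3))
})

test_that("beam search emits only multiset arrangements of the target mass", {
  v <- residue_vocab(residues = c(X = 1.0, Y = 2.5), phospho = FALSE)
  mc <- model_config(v, d_model = 8L, n_heads = 2L, d_ff = 8L,
                     max_len = 8L, seed = 3L)
  m <- structure(list(params = tandemnovo:::denovo_init_params(mc),
                      config = mc, loss_history = numeric(0),
                      vocab_hash = tandemnovo:::vocab_hash(v)),
                 class = "denovo_model")
  kt <- build_knapsack(v, resolution = 0.01, max_mass = 10)
  # precursor residue mass 4.5 => the only admissible multiset is {X,X,Y}
  sp <- spectrum("toy", c(1.5, 2.5), c(1, 1),
                 neutral_to_mz(4.5 + 18.010565, 1), 1)
  out <- beam_search(sp, m, kt, beam_width = 5L, tolerance = 0.05)
  expect_gt(nrow(out), 0)
  expect_true(all(out$peptide %in% c("XXY", "XYX", "YXX")))
  # infeasible residue mass 0.7: empty result with a diagnostic
  sp2 <- spectrum("toy2", 1.0, 1, neutral_to_mz(0.7 + 18.010565, 1), 1)
  out2 <- beam_search(sp2, m, kt, beam_width = 5L, tolerance = 1e-6)
  expect_identical(nrow(out2), 0L)
  expect_match(attr(out2, "diagnostic"), "no hypothesis")
})

test_that("beam width 1 equals greedy decoding under the same filter", {
  cfg <- noise_free_cfg(13L)
  v <- synth_vocab(cfg)
  m <- tiny_trained_model()
  kt <- build_knapsack(v, max_mass = 1500)
  sp <- tiny_heldout()[[2]]
  out <- beam_search(sp, m, kt, beam_width = 1L)
  # independent greedy reimplementation
  target <- sp$precursor_neutral_mass - 18.010565
  H <- encode_spectrum(m, sp)
  ids <- integer(0); cum <- 0
  rmass <- unname(v$masses)
  repeat {
    lp <- decode_step(m, H, ids)
    ok <- knapsack_feasible(kt, target - cum - rmass, 0.1)
    toks <- v$residue_ids[ok]
    if (abs(target - cum) <= 0.1 && length(ids) > 0) toks <- c(toks, v$end_id)
    if (!length(toks)) {ids <- NULL; break}
    best <- toks[order(-lp[toks], toks)][1]
    if (best == v$end_id) break
    ids <- c(ids, best)
    cum <- cum + rmass[best - v$n_special]
    if (length(ids) > m$config$max_len) {ids <- NULL; break}
  }
  if (is.null(ids)) {
    expect_identical(nrow(out), 0L)
  } else {
    expect_identical(out$peptide[1], tandemnovo:::ids_to_peptide(ids, v))
  }
})

test_that("every returned peptide matches the precursor mass (property)", {
  cfg <- noise_free_cfg(17L)
  v <- synth_vocab(cfg)
  m <- rand_denovo_model(v, seed = 23L)   # untrained: worst case
  corp <- make_spectrum_corpus(synth_config(seed = 17L, alphabet = "reduced"),
                               60)
  kt <- build_knapsack(v, max_mass = 1500)
  for (sp in corp) {
    out <- beam_search(sp, m, kt, beam_width = 3L, tolerance = 0.1)
    for (pep in out$peptide)
      expect_lte(abs(peptide_mass(pep, v) - sp$precursor_neutral_mass), 0.1)
  }
})

test_that("hypothesis scoring follows the stated priority rules", {
  expect_equal(score_hypothesis(c(0, 0, 0)), 1)
  expect_equal(score_hypothesis(c(-0.5, -0.1), label = "decoy"), 0)
  expect_gt(score_hypothesis(c(-0.1, -0.1)), score_hypothesis(c(-0.5, -0.5)))
  # high-detectable 0.6 ranks above potential 0.9; decoy 0.99 is removed
  hyps <- data.frame(conf = c(0.6, 0.9, 0.99),
                     label = c("high", "potential", "decoy"))
  hyps$conf[hyps$label == "decoy"] <-
    score_hypothesis(log(0.99), label = "decoy")
  kept <- hyps[hyps$conf > 0, ]
  prio <- vapply(kept$label, tandemnovo:::.detect_priority, integer(1))
  ord <- kept[order(prio, -kept$conf), ]
  expect_identical(ord$label, c("high", "potential"))
})

test_that("rescorer filtering removes decoy-labelled hypotheses entirely", {
  cfg <- noise_free_cfg(19L)
  v <- synth_vocab(cfg)
  m <- rand_denovo_model(v, seed = 29L)
  bc <- bert_config(v, d_model = 16L, n_heads = 2L, d_ff = 24L,
                    max_len = 14L, seed = 31L)
  rescorer <- structure(list(params = tandemnovo:::bert_init_params(bc),
                             config = bc, loss_history = numeric(0),
                             vocab_hash = tandemnovo:::vocab_hash(v)),
                        class = "peptide_bert")
  corp <- make_spectrum_corpus(cfg, 12)
  kt <- build_knapsack(v, max_mass = 1500)
  for (sp in corp) {
    plain <- beam_search(sp, m, kt, beam_width = 3L)
    rescored <- beam_search(sp, m, kt, beam_width = 3L, rescorer = rescorer)
    expect_lte(nrow(rescored), nrow(plain))
    if (nrow(rescored))
      expect_false(any(rescored$detectability == "decoy"))
  }
})
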