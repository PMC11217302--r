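test_that("decoy generators follow their stated permutation rules", {
  set.seed(1)
  expect_identical(as.character(make_decoys("PEPTIDEK", "reverse")),
                   "EDITPEPK")
  # trivial permutation group: returned unchanged but reported
  d <- make_decoys("AK", "shuffle_keep_cleavage")
  expect_identical(as.character(d), "AK")
  expect_identical(attr(d, "n_trivial"), 1L)
  # K/R positions fixed under cleavage-conserving shuffle
  set.seed(2)
  d2 <- make_decoys(rep("GAKVLRSE", 20), "shuffle_keep_cleavage")
  for (x in d2) {
    expect_identical(substr(x, 3, 3), "K")
    expect_identical(substr(x, 6, 6), "R")
  }
})

test_that("every decoy method preserves the residue multiset", {
  set.seed(3)
  peps <- synth_peptides(synth_config(seed = 3, peptide_length = c(6, 12)), 30)
  for (m in c("shuffle", "reverse", "shuffle_keep_cleavage", "shuffle_free")) {
    d <- make_decoys(peps, m)
    expect_gt(length(d), 0)
    # compare sorted residue strings of decoys against the target pool
    key <- function(x) vapply(strsplit(x, ""), function(c)
      paste(sort(c), collapse = ""), character(1))
    expect_true(all(key(d) %in% key(peps)))
  }
})

test_that("non-trivial decoys never equal a target sequence", {
  set.seed(4)
  peps <- unique(c("GAVLSE", "LLLLK", synth_peptides(synth_config(seed = 4), 50)))
  for (m in c("shuffle", "shuffle_free", "shuffle_keep_cleavage")) {
    d <- make_decoys(peps, m)
    nt <- attr(d, "n_trivial")
    expect_identical(sum(as.character(d) %in% peps), nt)
  }
})

test_that("detectability labels follow the 3rd-quartile rule", {
  freq <- c(a = 1, b = 1, c = 1, d = 100)
  lab <- label_detectability(freq)
  expect_identical(unname(lab["d"]), "high")
  expect_identical(unname(lab[c("a", "b", "c")]), rep("potential", 3))
  # all-equal frequencies: everyone crosses the threshold
  lab2 <- label_detectability(c(x = 5, y = 5, z = 5))
  expect_true(all(lab2 == "high"))
  # decoys are class decoy regardless of frequency
  lab3 <- label_detectability(freq, decoys = c("zzz"))
  expect_identical(unname(lab3["zzz"]), "decoy")
})

test_that("masking selects ceil(7%) of positions, half substituted", {
  v <- residue_vocab()
  pep14 <- "ACDEFGHIKLMNPQ"
  set.seed(5)
  mk <- apply_masking(pep14, masking_recipe(), v)
  expect_identical(length(mk$positions), 1L)   # ceiling(0.07 * 14)
  expect_identical(mk$targets,
                   strsplit(pep14, "")[[1]][mk$positions])
  # with k = 1 the substitution half rounds down: the position is masked
  expect_identical(mk$tokens[mk$positions], v$special[["mask"]])
  # fraction 0: unchanged, no targets
  mk0 <- apply_masking(pep14, masking_recipe(select_fraction = 0), v)
  expect_identical(paste(mk0$tokens, collapse = ""), pep14)
  expect_length(mk0$positions, 0L)
  # reproducible under a fixed seed
  set.seed(6); a <- apply_masking(pep14, masking_recipe(0.3), v)
  set.seed(6); b <- apply_masking(pep14, masking_recipe(0.3), v)
  expect_identical(a, b)
  # larger selection: floor(0.5k) substituted, remainder masked
  set.seed(7)
  mk2 <- apply_masking(paste(rep("GAVSLTPK", 3), collapse = ""),
                       masking_recipe(0.3), v)  # n=24, k=8
  n_masked <- sum(mk2$tokens == v$special[["mask"]])
  expect_identical(length(mk2$positions), 8L)
  expect_identical(n_masked, 4L)
})

test_that("class weights are inverse-frequency ordered", {
  w <- class_weights(c(decoy = 16e6, high = 163e3, potential = 4.27e6))
  expect_gt(w[["high"]], w[["potential"]])
  expect_gt(w[["potential"]], w[["decoy"]])
  expect_equal(mean(w), 1)
})

test_that("classification probabilities normalise; empty proposals empty", {
  cfg <- synth_config(seed = 8, alphabet = "reduced")
  v <- synth_vocab(cfg)
  bc <- bert_config(v, d_model = 16L, n_heads = 2L, d_ff = 24L,
                    max_len = 20L, seed = 8L)
  m <- structure(list(params = tandemnovo:::bert_init_params(bc),
                      config = bc, loss_history = numeric(0),
                      vocab_hash = tandemnovo:::vocab_hash(v)),
                 class = "peptide_bert")
  cl <- bert_classify(m, "GAVSL")
  expect_equal(sum(cl$probabilities), 1, tolerance = 1e-9)
  expect_true(cl$label %in% c("decoy", "high", "potential"))
  expect_identical(propose_residues(m, "GAVSL", integer(0)), list())
  pr <- propose_residues(m, "GAVSL", c(2L, 4L))
  expect_length(pr, 2L)
  expect_equal(sum(pr[[1]]), 1, tolerance = 1e-9)
})

test_that("an overfitted masked LM restores the true residue", {
  cfg <- synth_config(seed = 9, alphabet = "reduced")
  v <- synth_vocab(cfg)
  bc <- bert_config(v, d_model = 16L, n_heads = 2L, d_ff = 32L,
                    max_len = 12L, seed = 10L)
  m <- train_rescorer(rep(c("GAVSL", "LSVAG"), 10),
                      rep(c("high", "potential"), 10), bc,
                      recipe = masking_recipe(0.4), epochs = 30L,
                      verbose = FALSE)
  pr <- propose_residues(m, "GAVSL", 3L)[[1]]
  expect_identical(names(pr)[which.max(pr)], "V")
})

test_that("untrained rescorer separates nothing; trained one separates well", {
  cfg <- synth_config(seed = 12, n_proteins = 40L)
  corp <- make_detectability_corpus(cfg)
  v <- residue_vocab(phospho = FALSE)
  n_tr_t <- floor(length(corp$peptides) * 0.7)
  n_tr_d <- floor(length(corp$decoys) * 0.7)
  tr_pep <- c(corp$peptides[seq_len(n_tr_t)], corp$decoys[seq_len(n_tr_d)])
  tr_lab <- c(corp$labels[seq_len(n_tr_t)],
              rep("decoy", n_tr_d))
  te_t <- corp$peptides[(n_tr_t + 1):length(corp$peptides)]
  te_d <- corp$decoys[(n_tr_d + 1):length(corp$decoys)]
  bc <- bert_config(v, d_model = 32L, n_heads = 2L, d_ff = 64L,
                    max_len = 32L, seed = 13L)
  m0 <- train_rescorer(tr_pep, tr_lab, bc, epochs = 0L, verbose = FALSE)
  p_target <- function(model, peps) vapply(peps, function(p)
    1 - bert_classify(model, p)$probabilities[["decoy"]], numeric(1))
  auc0 <- rank_auc(p_target(m0, te_t), p_target(m0, te_d))
  expect_lt(abs(auc0 - 0.5), 0.25)   # chance level before training
  m1 <- train_rescorer(tr_pep, tr_lab, bc, epochs = 6L, verbose = FALSE,
                       samples_per_epoch = 1500L, lr = 2e-3)
  auc1 <- rank_auc(p_target(m1, te_t), p_target(m1, te_d))
  expect_gt(auc1, 0.8)
  expect_gt(auc1, auc0)
})
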