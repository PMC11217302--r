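test_that("encoder output has one hidden vector per input row", {
  cfg <- noise_free_cfg()
  v <- synth_vocab(cfg)
  m <- rand_denovo_model(v)
  sp <- spectrum("one", 300.15, 10, 400.2, 2)
  H <- encode_spectrum(m, sp)
  expect_identical(nrow(H), 3L)   # 2 precursor tokens + 1 peak
  expect_identical(ncol(H), m$config$d_model)
})

test_that("padding rows are masked out and leave valid rows unchanged", {
  cfg <- noise_free_cfg()
  v <- synth_vocab(cfg)
  m <- rand_denovo_model(v)
  sp <- simulate_spectrum("GAVSL", 2, cfg, v, seed = 1)
  H0 <- encode_spectrum(m, sp)
  H4 <- encode_spectrum(m, sp, pad_rows = 4L)
  expect_identical(nrow(H4), nrow(H0) + 4L)
  expect_equal(H4[seq_len(nrow(H0)), ], unclass(H0)[, ], tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("decode_step yields a normalised, causal distribution", {
  cfg <- noise_free_cfg()
  v <- synth_vocab(cfg)
  m <- rand_denovo_model(v)
  sp <- simulate_spectrum("GAVSL", 2, cfg, v, seed = 2)
  H <- encode_spectrum(m, sp)
  lp <- decode_step(m, H, integer(0))
  expect_equal(sum(exp(lp)), 1, tolerance = 1e-5)
  # causality: the distribution after a prefix does not depend on what
  # would come later -- the step-k output under prefix p equals the k-th
  # row computed under any extension of p
  p1 <- tandemnovo:::peptide_to_ids("GA", v)
  p2 <- tandemnovo:::peptide_to_ids("GAVSL", v)
  lp1 <- decode_step(m, H, p1)
  full <- tandemnovo:::denovo_decode_fwd(
    m$params, m$config, H, c(v$start_id, p2),
    total_mass = attr(H, "precursor_residue_mass"),
    key_mz = attr(H, "key_mz"))
  row3 <- full$logits[3, ]
  row3 <- row3 - log(sum(exp(row3 - max(row3)))) - max(row3)
  expect_equal(lp1, row3, tolerance = 1e-10)
  # eval-mode determinism
  expect_identical(decode_step(m, H, p1), lp1)
})

test_that("a single (spectrum, peptide) pair can be overfitted", {
  cfg <- noise_free_cfg(7L)
  v <- synth_vocab(cfg)
  sp <- simulate_spectrum("GAVSL", 2, cfg, v, seed = 3)
  mc <- model_config(v, d_model = 16L, n_heads = 2L, d_ff = 32L,
                     max_len = 8L, seed = 9L)
  m <- train_denovo(list(sp), mc, epochs = 80L, batch_size = 1L,
                    lr = 3e-3, verbose = FALSE)
  H <- encode_spectrum(m, sp)
  ids <- integer(0)
  for (k in 1:6) {
    lp <- decode_step(m, H, ids)
    nxt <- which.max(lp)
    if (nxt == v$end_id) break
    ids <- c(ids, nxt)
  }
  expect_identical(tandemnovo:::ids_to_peptide(ids, v), "GAVSL")
})

test_that("training reduces loss on a noise-free corpus", {
  m <- tiny_trained_model()
  lh <- m$loss_history
  expect_gt(lh[1], lh[length(lh)])
  expect_lt(lh[5], lh[1])
})

test_that("trained perplexity beats the uniform baseline on held-out data", {
  m <- tiny_trained_model()
  held <- tiny_heldout()
  V <- m$config$vocab
  uniform <- length(V$all_tokens)
  expect_lt(perplexity(m, held), uniform)
})

test_that("training refuses empty data and mismatched vocabularies", {
  cfg <- noise_free_cfg()
  v <- synth_vocab(cfg)
  mc <- model_config(v, d_model = 16L, n_heads = 2L, d_ff = 16L, seed = 1L)
  expect_error(train_denovo(list(), mc), "empty")
  sp <- simulate_spectrum("GAVSL", 2, cfg, v, seed = 1)
  sp$peptide <- "GAWSL"  # W not in the reduced vocabulary
  expect_error(train_denovo(list(sp), mc), "vocabulary mismatch")
})

test_that("checkpoints restore bit-identical eval behaviour", {
  m <- tiny_trained_model()
  f <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, f)
  m2 <- load_checkpoint(f)
  expect_identical(m2$vocab_hash, m$vocab_hash)
  sp <- tiny_heldout()[[1]]
  H1 <- encode_spectrum(m, sp)
  H2 <- encode_spectrum(m2, sp)
  expect_identical(unclass(H1), unclass(H2))
  ids <- tandemnovo:::peptide_to_ids("GA", m$config$vocab)
  expect_identical(decode_step(m, H1, ids), decode_step(m2, H2, ids))
})

test_that("fixed seed gives bitwise-reproducible initialisation", {
  cfg <- noise_free_cfg()
  v <- synth_vocab(cfg)
  mc <- model_config(v, d_model = 16L, n_heads = 2L, d_ff = 16L, seed = 42L)
  p1 <- tandemnovo:::denovo_init_params(mc)
  p2 <- tandemnovo:::denovo_init_params(mc)
  expect_identical(p1, p2)
})
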