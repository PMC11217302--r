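# Shared fixtures: tiny corpora and models built once per test run.

# noise-free reduced-alphabet generator settings used by model-level tests
noise_free_cfg <- function(seed = 11L)
  synth_config(seed = seed, alphabet = "reduced", peak_miss_prob = 0,
               noise_peaks_per_signal = 0)

# an untrained (randomly initialised) model -- "any checkpoint"
rand_denovo_model <- function(vocab, d_model = 32L, n_heads = 2L,
                              d_ff = 64L, max_len = 14L, seed = 2L) {
  mc <- model_config(vocab, d_model = d_model, n_heads = n_heads,
                     d_ff = d_ff, max_len = max_len, seed = seed)
  structure(list(params = tandemnovo:::denovo_init_params(mc), config = mc,
                 opt = NULL, loss_history = numeric(0),
                 vocab_hash = tandemnovo:::vocab_hash(vocab)),
            class = "denovo_model")
}

# small trained model shared across tests (trained once per run)
.fixture_env <- new.env()

tiny_trained_model <- function() {
  if (is.null(.fixture_env$model)) {
    cfg <- noise_free_cfg(31L)
    corp <- make_spectrum_corpus(cfg, 320)   # deduplication shrinks this
    stopifnot(length(corp) > 210L)
    mc <- model_config(synth_vocab(cfg), d_model = 32L, n_heads = 2L,
                       d_ff = 64L, max_len = 12L, seed = 5L)
    .fixture_env$model <- train_denovo(corp[seq_len(200)], mc, epochs = 8L,
                                       verbose = FALSE)
    .fixture_env$heldout <- corp[201:length(corp)]
  }
  .fixture_env$model
}

tiny_heldout <- function() {
  tiny_trained_model()
  .fixture_env$heldout
}

# Mann-Whitney AUC: P(score_target > score_decoy) + 0.5 ties
rank_auc <- function(scores_pos, scores_neg) {
  r <- rank(c(scores_pos, scores_neg))
  n1 <- length(scores_pos); n2 <- length(scores_neg)
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}
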