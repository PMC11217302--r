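# Desk-scale benchmark study: generate a noise-free reduced-alphabet
# corpus, train the seq2seq model and the rescorer on it, decode held-out
# spectra with and without rescoring, and score everything. Used by the
# test suite and the acceptance script so the protocol lives in one place.

#' Run the desk-scale sequencing benchmark
#'
#' Study conditions: 2000 noise-free reduced-alphabet training spectra,
#' 200 held-out spectra, beam width 5, 0.1 Da mass tolerance. A peptide
#' universe receives simulated observation frequencies (motif-boosted:
#' the detectability structure), and the observed spectrum corpus is
#' drawn from the highly detectable pool with probability proportional
#' to frequency -- observed spectra come from detectable peptides, as
#' the notion of detectability implies. The rescorer is trained on the universe
#' (labels from the frequency quantile rule) against shuffle and
#' reverse decoys, and its effect on peptide recall is measured by
#' decoding the held-out set with and without it.
#'
#' @param seed master seed; all corpus, model and training seeds derive
#'   from it
#' @param n_train,n_test corpus split sizes
#' @param d_model,n_heads,d_ff,dropout seq2seq dimensions (desk defaults)
#' @param epochs integer vector: epochs at 1e-3 then at 3e-4
#' @param bert_epochs rescorer training epochs
#' @param beam_width,tolerance decoding parameters
#' @param verbose print progress
#' @return list: \code{model}, \code{rescorer}, \code{metrics} (without
#'   rescorer), \code{metrics_rescored}, \code{auc} (held-out
#'   decoy-vs-target), \code{n_decoy_as_high}, \code{mass_consistency}
#'   (fraction of emitted held-out peptides within tolerance of the
#'   precursor), \code{test} (held-out spectra), timings
#' @export
desk_benchmark <- function(seed = 11L, n_train = 2000L, n_test = 200L,
                           d_model = 64L, n_heads = 8L, d_ff = 256L,
                           dropout = 0.1, epochs = c(12L, 5L),
                           bert_epochs = 4L, beam_width = 5L,
                           tolerance = 0.1, verbose = TRUE) {
  t0 <- Sys.time()
  cfg <- synth_config(seed = seed, alphabet = "reduced",
                      peak_miss_prob = 0, noise_peaks_per_signal = 0)
  vocab <- synth_vocab(cfg)
  # peptide universe with simulated observation frequencies: peptides
  # carrying the first planted motif are strongly boosted (the
  # detectability structure); the observed spectrum corpus is drawn
  # without replacement with probability proportional to frequency, so
  # observed peptides are predominantly the highly detectable ones --
  # which is what peptide detectability means
  universe <- synth_peptides(cfg, ceiling((n_train + n_test) * 10L))
  set.seed(seed + 101L)
  freq <- stats::rpois(length(universe),
                       ifelse(grepl(cfg$motifs[1], universe, fixed = TRUE),
                              cfg$motif_boost * 4, 2)) + 1
  names(freq) <- universe
  labels <- label_detectability(freq)
  pool <- universe[labels[universe] == "high"]
  if (length(pool) < n_train + n_test)
    stop("generator produced too few highly detectable peptides")
  observed <- sample(pool, n_train + n_test, prob = freq[pool])
  spectra <- make_spectrum_corpus(cfg, peptides = observed)
  train <- spectra[seq_len(n_train)]
  test <- spectra[(n_train + 1L):(n_train + n_test)]

  mc <- model_config(vocab, d_model = d_model, n_heads = n_heads,
                     d_ff = d_ff, dropout = dropout, max_len = 12L,
                     seed = seed %% 100000L + 7L)
  model <- train_denovo(train, mc, epochs = epochs[1], batch_size = 16L,
                        lr = 1e-3, verbose = verbose)
  if (length(epochs) > 1L && epochs[2] > 0L)
    model <- train_denovo(train, mc, epochs = epochs[2], batch_size = 16L,
                          lr = 3e-4, model = model, verbose = verbose)
  t_train <- Sys.time()

  # rescorer corpus: the peptide universe minus held-out test peptides,
  # with shuffle + reverse decoys; held-out targets/decoys feed the AUC
  tr_pep <- vapply(train, function(s) s$peptide, character(1))
  te_pep <- vapply(test, function(s) s$peptide, character(1))
  set.seed(seed + 103L)
  bert_targets <- setdiff(universe, te_pep)
  decoys <- unique(c(make_decoys(bert_targets, "shuffle"),
                     make_decoys(bert_targets, "reverse")))
  decoys <- setdiff(decoys, c(universe))
  te_decoys <- unique(c(make_decoys(te_pep, "shuffle"),
                        make_decoys(te_pep, "reverse")))
  te_decoys <- setdiff(te_decoys, c(universe, decoys))
  bc <- bert_config(vocab, d_model = 32L, n_heads = 4L, n_layers = 2L,
                    d_ff = 64L, max_len = 12L,
                    seed = seed %% 100000L + 13L)
  rescorer <- train_rescorer(c(bert_targets, decoys),
                             c(unname(labels[bert_targets]),
                               rep("decoy", length(decoys))),
                             bc, epochs = bert_epochs,
                             samples_per_epoch = min(5000L,
                                                     length(bert_targets) +
                                                       length(decoys)),
                             verbose = verbose)
  t_bert <- Sys.time()

  p_target <- function(peps) vapply(peps, function(p)
    1 - bert_classify(rescorer, p)$probabilities[["decoy"]], numeric(1))
  auc <- local({
    r <- rank(c(p_target(te_pep), p_target(te_decoys)))
    n1 <- length(te_pep); n2 <- length(te_decoys)
    (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
  })
  n_decoy_as_high <- sum(vapply(te_decoys, function(p)
    bert_classify(rescorer, p)$label == "high", logical(1)))

  knap <- build_knapsack(vocab, max_mass = max(vapply(
    test, function(s) s$precursor_neutral_mass, numeric(1))) + 1)
  truth <- stats::setNames(te_pep,
                           vapply(test, function(s) s$spectrum_id,
                                  character(1)))
  preds <- predict(model, test, knapsack = knap, beam_width = beam_width,
                   tolerance = tolerance)
  preds_re <- predict(model, test, knapsack = knap,
                      beam_width = beam_width, tolerance = tolerance,
                      rescorer = rescorer)
  metrics <- evaluate_predictions(preds, truth, vocab)$metrics
  metrics_re <- evaluate_predictions(preds_re, truth, vocab)$metrics

  emitted <- nzchar(preds$peptide)
  mass_ok <- vapply(which(emitted), function(i)
    abs(peptide_mass(preds$peptide[i], vocab) -
          test[[i]]$precursor_neutral_mass) <= tolerance, logical(1))

  list(model = model, rescorer = rescorer, test = test, truth = truth,
       predictions = preds, predictions_rescored = preds_re,
       metrics = metrics, metrics_rescored = metrics_re,
       auc = auc, n_decoy_as_high = n_decoy_as_high,
       n_test_decoys = length(te_decoys),
       mass_consistency = mean(mass_ok),
       timings = c(train = as.numeric(difftime(t_train, t0, units = "mins")),
                   rescorer = as.numeric(difftime(t_bert, t_train,
                                                  units = "mins")),
                   decode = as.numeric(difftime(Sys.time(), t_bert,
                                                units = "mins"))))
}
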