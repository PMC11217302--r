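test_that("tryptic digestion cleaves after K/R except before P", {
  cfg <- synth_config(missed_cleavage_prob = 0)
  expect_setequal(digest("AKPGKR", cfg), c("AKPGK", "R"))
  expect_identical(digest("GAVSGALS", cfg), "GAVSGALS")   # no K/R
  expect_setequal(digest("GAKSLRTP", cfg), c("GAK", "SLR", "TP"))
  # trailing K: no empty peptide
  expect_setequal(digest("GAKVLK", cfg), c("GAK", "VLK"))
})

test_that("missed-cleavage products appear only when enabled", {
  prot <- "GAKSLRTPKEDN"
  none <- digest(prot, synth_config(missed_cleavage_prob = 0))
  expect_true(all(!grepl("K.", none) | none == "TPKEDN"))
  set.seed(1)
  cfg1 <- synth_config(missed_cleavage_prob = 1, max_missed = 1L)
  withmc <- digest(prot, cfg1)
  expect_true("GAKSLR" %in% withmc)     # spans one missed site
  expect_true(all(none %in% withmc))
})

test_that("noise-free simulated spectra equal the theoretical ion set", {
  cfg <- synth_config(seed = 3, peak_miss_prob = 0,
                      noise_peaks_per_signal = 0)
  v <- residue_vocab(phospho = FALSE)
  sp <- simulate_spectrum("GAVSLTPK", 2, cfg, v, seed = 4)
  want <- sort(fragment_ions("GAVSLTPK", 1, c("b", "y"), v)$mz)
  expect_equal(sp$mz, want, tolerance = 1e-9)
  # precursor fields consistent with the peptide to well under 1e-4 Da
  expect_lt(abs(sp$precursor_neutral_mass - peptide_mass("GAVSLTPK", v)),
            1e-6)
  expect_identical(sp$peptide, "GAVSLTPK")
})

test_that("noise and missing-peak rates realise their configured levels", {
  cfg <- synth_config(seed = 5)   # defaults: miss 0.125, noise 5.25/signal
  v <- residue_vocab(phospho = FALSE)
  set.seed(5)
  n_signal <- 0L; n_total <- 0L; n_missing_any <- 0L; n_spec <- 300L
  for (i in seq_len(n_spec)) {
    sp <- simulate_spectrum("GAVSLTPKED", 2, cfg, v)
    theo <- nrow(fragment_ions("GAVSLTPKED", 1, c("b", "y"), v))
    sig <- sum(sp$mz %in% fragment_ions("GAVSLTPKED", 1, c("b", "y"), v)$mz)
    n_signal <- n_signal + sig
    n_total <- n_total + length(sp$mz)
    if (sig < theo) n_missing_any <- n_missing_any + 1L
  }
  noise_frac <- 1 - n_signal / n_total
  expect_gt(noise_frac, 0.80)     # targets ~0.84
  expect_lt(noise_frac, 0.88)
  expect_gt(n_missing_any / n_spec, 0.80)  # most spectra miss >= 1 ion
})

test_that("the corpus is byte-identical under a fixed seed", {
  cfg <- synth_config(seed = 77, alphabet = "reduced")
  a <- make_spectrum_corpus(cfg, 25)
  b <- make_spectrum_corpus(cfg, 25)
  expect_identical(a, b)
  expect_identical(make_proteome(cfg), make_proteome(cfg))
})

test_that("detectability corpus has motif structure, labels and decoys", {
  cfg <- synth_config(seed = 6, n_proteins = 30L)
  corp <- make_detectability_corpus(cfg)
  expect_gt(mean(corp$frequencies[corp$has_motif]),
            mean(corp$frequencies[!corp$has_motif]))
  # labels follow the 75th-percentile rule
  thr <- quantile(corp$frequencies, 0.75, names = FALSE)
  expect_identical(unname(corp$labels),
                   unname(ifelse(corp$frequencies >= thr, "high",
                                 "potential")))
  # decoy set disjoint from targets
  expect_length(intersect(corp$decoys, corp$peptides), 0L)
  expect_gt(length(corp$decoys), length(corp$peptides))
})

test_that("a written corpus round-trips through MGF with annotations", {
  cfg <- synth_config(seed = 8, alphabet = "reduced")
  spectra <- make_spectrum_corpus(cfg, 10)
  dir <- withr::local_tempdir()
  paths <- write_corpus(spectra, dir, cfg, proteome = make_proteome(cfg))
  expect_true(all(file.exists(paths)))
  back <- read_mgf(paths[["mgf"]])
  expect_length(back, 10L)
  expect_identical(vapply(back, function(s) s$peptide, character(1)),
                   vapply(spectra, function(s) s$peptide, character(1)))
  man <- jsonlite::read_json(paths[["manifest"]])
  expect_identical(man$n_spectra, 10L)
  expect_identical(man$seed, 8L)
})
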