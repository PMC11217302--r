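# Synthetic-data generator: proteomes, tryptic digestion, annotated
# fragment spectra with configurable missing-peak and noise rates, and a
# motif-structured detectability corpus with decoys. Defaults emulate the
# error structure of real tandem MS data, where roughly 91% of spectra
# miss at least one fragment ion and ~84% of peaks are noise; every draw
# is deterministic under the configuration seed.

#' Synthetic-data configuration
#'
#' @param seed RNG seed; a fixed seed gives a byte-identical corpus
#' @param n_proteins proteins in the synthetic proteome
#' @param protein_length length range (uniform integer draw)
#' @param alphabet \code{"full"} (20 canonical residues) or
#'   \code{"reduced"} (5 residues, G/A/S/V/L, with well-separated
#'   masses; desk-scale model training converges in minutes on it)
#' @param missed_cleavage_prob probability that a cleavage site is
#'   missed; a peptide spanning j missed sites is emitted with
#'   probability prob^j
#' @param max_missed maximum missed cleavages per peptide
#' @param motifs planted subsequences that raise a peptide's simulated
#'   observation frequency (learnable detectability structure); defaults
#'   depend on the alphabet
#' @param motif_boost frequency multiplier for motif-bearing peptides
#' @param peptide_motif_prob probability that a directly sampled peptide
#'   (\code{\link{synth_peptides}}) carries one planted motif (default
#'   1: every observable peptide has the compositional bias that makes
#'   detectability learnable, emulating the strong sequence biases of
#'   real observable peptides)
#' @param motif_spacing average residue spacing between motif implants
#'   in synthetic proteins (default 10, so typical tryptic peptides
#'   span at least one motif); set to \code{Inf} for motif-free
#'   proteomes
#' @param motif_weights sampling weights over \code{motifs} for
#'   proteome implants; the default gives the first (frequency-boosted)
#'   motif weight 0.25 so the prevalence of boosted peptides matches
#'   the 3rd-quartile labelling cut and the highly detectable class
#'   stays the minority, as in real detectability corpora
#' @param fragment_kinds,fragment_charge_max theoretical ion series
#' @param peak_miss_prob probability each fragment peak is absent
#'   (0.125 leaves ~91% of typical tryptic spectra missing at least one
#'   ion)
#' @param noise_peaks_per_signal expected noise peaks per observed
#'   signal peak (5.25 makes ~84% of all peaks noise)
#' @param mz_range m/z window for noise peaks
#' @param charges precursor charge states sampled uniformly
#' @param peptide_length peptide length range for directly sampled
#'   peptide corpora
#' @param decoy_ratio decoys per target in the detectability corpus
#'   (the full-scale corpus shape is roughly 4:1)
#' @return object of class \code{synth_config}
#' @export
synth_config <- function(seed = 1L, n_proteins = 20L,
                         protein_length = c(80L, 200L),
                         alphabet = c("full", "reduced"),
                         missed_cleavage_prob = 0.1, max_missed = 2L,
                         motifs = NULL, motif_boost = 10,
                         peptide_motif_prob = 1, motif_spacing = 10,
                         motif_weights = NULL,
                         fragment_kinds = c("b", "y"),
                         fragment_charge_max = 1L,
                         peak_miss_prob = 0.125,
                         noise_peaks_per_signal = 5.25,
                         mz_range = c(100, 1600),
                         charges = 2L,
                         peptide_length = c(5L, 10L),
                         decoy_ratio = 4L) {
  alphabet <- match.arg(alphabet)
  # default planted motifs are K/R-free so digestion keeps them intact;
  # the full-alphabet motifs are 6-mers because shorter motifs reappear
  # too easily inside shuffled decoys, blurring the detectability classes
  if (is.null(motifs))
    motifs <- if (alphabet == "reduced") c("GASV", "LSVG")
              else c("GASVTE", "LDENSH")
  if (is.null(motif_weights))
    motif_weights <- if (length(motifs) > 1L)
      c(0.25, rep(0.75 / (length(motifs) - 1L), length(motifs) - 1L))
    else 1
  structure(list(seed = as.integer(seed), n_proteins = as.integer(n_proteins),
                 protein_length = protein_length, alphabet = alphabet,
                 missed_cleavage_prob = missed_cleavage_prob,
                 max_missed = as.integer(max_missed), motifs = motifs,
                 motif_boost = motif_boost,
                 peptide_motif_prob = peptide_motif_prob,
                 motif_spacing = motif_spacing,
                 motif_weights = motif_weights,
                 fragment_kinds = fragment_kinds,
                 fragment_charge_max = as.integer(fragment_charge_max),
                 peak_miss_prob = peak_miss_prob,
                 noise_peaks_per_signal = noise_peaks_per_signal,
                 mz_range = mz_range, charges = as.integer(charges),
                 peptide_length = peptide_length,
                 decoy_ratio = as.integer(decoy_ratio)),
            class = "synth_config")
}

#' Vocabulary matching a synthetic configuration
#' @param cfg a \code{\link{synth_config}}
#' @return a \code{\link{residue_vocab}}: the 5-residue reduced alphabet
#'   or the 20 canonical residues (no modified tokens)
#' @export
synth_vocab <- function(cfg) {
  if (cfg$alphabet == "reduced")
    residue_vocab(residues = .CANONICAL_MASSES[c("G", "A", "S", "V", "L")],
                  phospho = FALSE)
  else residue_vocab(phospho = FALSE)
}

.synth_alphabet <- function(cfg) {
  if (cfg$alphabet == "reduced") c("G", "A", "S", "V", "L")
  else names(.CANONICAL_MASSES)[names(.CANONICAL_MASSES) != "I"]
}

#' Generate a synthetic proteome
#'
#' Uniform residue draws over the configured alphabet (I excluded to
#' keep sequences unambiguous under I/L mass identity), lengths uniform
#' in \code{protein_length}. The planted motifs are implanted along
#' each protein at an average spacing of \code{cfg$motif_spacing}
#' residues (jittered), so typical digestion products carry the
#' detectability structure. Deterministic under \code{cfg$seed}.
#'
#' @param cfg a \code{\link{synth_config}}
#' @return data.frame with accession, description, sequence
#' @export
make_proteome <- function(cfg) {
  set.seed(cfg$seed)
  alpha <- .synth_alphabet(cfg)
  lens <- sample(cfg$protein_length[1]:cfg$protein_length[2],
                 cfg$n_proteins, replace = TRUE)
  seqs <- vapply(lens, function(n) {
    ch <- sample(alpha, n, replace = TRUE)
    if (length(cfg$motifs) && is.finite(cfg$motif_spacing)) {
      at <- 1L
      while (at + max(nchar(cfg$motifs)) <= n) {
        m <- strsplit(sample(cfg$motifs, 1L, prob = cfg$motif_weights),
                      "")[[1L]]
        ch[at:(at + length(m) - 1L)] <- m
        at <- at + length(m) +
          sample.int(max(1L, 2L * (cfg$motif_spacing - length(m))), 1L)
      }
    }
    paste(ch, collapse = "")
  }, character(1))
  data.frame(accession = sprintf("SYN%03d", seq_len(cfg$n_proteins)),
             description = "synthetic protein",
             sequence = seqs, stringsAsFactors = FALSE)
}

#' Tryptic digestion with missed cleavages
#'
#' Cleaves after K or R except when the next residue is P. Fully
#' cleaved peptides are always emitted; a peptide spanning j missed
#' cleavage sites (up to \code{max_missed}) is emitted with probability
#' \code{missed_cleavage_prob^j}.
#'
#' @param protein protein sequence string
#' @param cfg a \code{\link{synth_config}}
#' @return character vector of peptides
#' @export
digest <- function(protein, cfg = synth_config()) {
  ch <- strsplit(protein, "")[[1L]]
  n <- length(ch)
  cut_after <- which(ch %in% c("K", "R"))
  cut_after <- cut_after[cut_after < n & ch[pmin(cut_after + 1L, n)] != "P"]
  bounds <- c(0L, cut_after, n)
  bounds <- unique(bounds)
  starts <- bounds[-length(bounds)] + 1L
  ends <- bounds[-1L]
  base <- substring(protein, starts, ends)
  out <- base
  if (cfg$max_missed > 0L && cfg$missed_cleavage_prob > 0) {
    for (j in seq_len(min(cfg$max_missed, length(base) - 1L))) {
      for (i in seq_len(length(base) - j)) {
        if (stats::runif(1) < cfg$missed_cleavage_prob^j)
          out <- c(out, paste(base[i:(i + j)], collapse = ""))
      }
    }
  }
  out
}

#' Simulate an annotated fragment spectrum
#'
#' Theoretical fragment ions of the configured kinds/charges; each
#' fragment peak is dropped independently with \code{peak_miss_prob};
#' Poisson(\code{noise_peaks_per_signal} x observed signal count) noise
#' peaks are added uniformly over \code{mz_range} with intensities drawn
#' uniformly below the median signal intensity (so a peak is "noise"
#' exactly when its intensity is below the set median, mirroring how
#' noise is labelled in error analyses). Signal intensities are
#' log-normal. The precursor fields are exact for the peptide and
#' charge; the true peptide is recorded in the \code{peptide} field.
#'
#' @param peptide peptide string
#' @param charge precursor charge
#' @param cfg a \code{\link{synth_config}}
#' @param vocab vocabulary (defaults to \code{\link{synth_vocab}})
#' @param seed optional seed for this one spectrum (otherwise the
#'   current RNG state is used)
#' @return an annotated \code{\link{spectrum}}
#' @export
simulate_spectrum <- function(peptide, charge = 2L, cfg = synth_config(),
                              vocab = synth_vocab(cfg), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fr <- fragment_ions(peptide, cfg$fragment_charge_max, cfg$fragment_kinds,
                      vocab)
  keep <- stats::runif(nrow(fr)) >= cfg$peak_miss_prob
  mz <- fr$mz[keep]
  int <- stats::rlnorm(sum(keep), meanlog = log(100), sdlog = 0.5)
  n_noise <- if (cfg$noise_peaks_per_signal > 0 && sum(keep) > 0)
    stats::rpois(1L, cfg$noise_peaks_per_signal * sum(keep)) else 0L
  if (n_noise > 0L) {
    med <- stats::median(int)
    mz <- c(mz, stats::runif(n_noise, cfg$mz_range[1], cfg$mz_range[2]))
    int <- c(int, stats::runif(n_noise, 0, med))
  }
  neutral <- peptide_mass(peptide, vocab)
  spectrum(paste0("synth:", peptide, "/", charge), mz, int,
           neutral_to_mz(neutral, charge), charge, peptide = peptide)
}

#' Sample a peptide corpus directly
#'
#' Residue draws over the configured alphabet with lengths in
#' \code{cfg$peptide_length}; with probability
#' \code{cfg$peptide_motif_prob} one planted motif is implanted at a
#' random position, giving the peptide population the compositional
#' structure that makes detectability discrimination learnable.
#' Duplicates are removed. Used for model training corpora where
#' digestion structure is irrelevant.
#'
#' @param cfg a \code{\link{synth_config}}
#' @param n number of peptides requested (returned count can be lower
#'   after deduplication)
#' @return character vector of peptides
#' @export
synth_peptides <- function(cfg, n) {
  set.seed(cfg$seed + 17L)
  alpha <- .synth_alphabet(cfg)
  motifs <- cfg$motifs[nchar(cfg$motifs) <= cfg$peptide_length[1]]
  lens <- sample(cfg$peptide_length[1]:cfg$peptide_length[2], n,
                 replace = TRUE)
  peps <- vapply(lens, function(l) {
    ch <- sample(alpha, l, replace = TRUE)
    if (length(motifs) && stats::runif(1) < cfg$peptide_motif_prob) {
      m <- strsplit(sample(motifs, 1L), "")[[1L]]
      at <- sample.int(l - length(m) + 1L, 1L)
      ch[at:(at + length(m) - 1L)] <- m
    }
    paste(ch, collapse = "")
  }, character(1))
  unique(peps)
}

#' Annotated spectrum corpus
#'
#' Simulates one spectrum per peptide (or per sampled peptide when
#' \code{peptides} is NULL), with charges drawn from \code{cfg$charges}.
#' Deterministic under \code{cfg$seed}.
#'
#' @param cfg a \code{\link{synth_config}}
#' @param n corpus size when sampling peptides
#' @param peptides optional peptide set to simulate from
#' @return list of annotated \code{\link{spectrum}} objects
#' @export
make_spectrum_corpus <- function(cfg, n = 100L, peptides = NULL) {
  if (is.null(peptides)) peptides <- synth_peptides(cfg, n)
  vocab <- synth_vocab(cfg)
  set.seed(cfg$seed + 29L)
  charges <- if (length(cfg$charges) == 1L)
    rep(cfg$charges, length(peptides))
  else sample(cfg$charges, length(peptides), replace = TRUE)
  lapply(seq_along(peptides), function(i)
    simulate_spectrum(peptides[i], charges[i], cfg, vocab))
}

#' Motif-structured detectability corpus
#'
#' Digests a synthetic proteome, simulates observation frequencies
#' (Poisson counts; peptides containing the \emph{first} planted motif
#' get \code{motif_boost}-fold higher expected frequency, so the three
#' classes have crisp identities: highly detectable peptides carry the
#' boosted motif, potentially detectable ones the other motifs or
#' none), labels targets by the 3rd-quartile rule and generates decoys
#' by cycling the four decoy methods up to \code{decoy_ratio} per
#' target. Trivial decoys, collisions with targets and decoys that
#' retain an intact planted motif are dropped -- at this corpus scale a
#' shuffle that recreates the detectability structure is not a valid
#' negative control (at proteome scale such collisions are vanishingly
#' rare).
#'
#' @param cfg a \code{\link{synth_config}}
#' @return list: peptides, frequencies (named), labels (named;
#'   high/potential), decoys, has_motif (logical per target)
#' @export
make_detectability_corpus <- function(cfg) {
  prot <- make_proteome(cfg)
  set.seed(cfg$seed + 43L)
  peps <- unique(unlist(lapply(prot$sequence, digest, cfg = cfg)))
  peps <- peps[nchar(peps) >= 6L & nchar(peps) <= 30L]
  if (!length(peps)) stop("digestion produced no peptides in 6..30 residues")
  has_motif <- Reduce(`|`, lapply(cfg$motifs, function(m)
    grepl(m, peps, fixed = TRUE)), rep(FALSE, length(peps)))
  lambda <- ifelse(grepl(cfg$motifs[1], peps, fixed = TRUE),
                   cfg$motif_boost, 1) * 2
  freq <- stats::rpois(length(peps), lambda) + 1
  names(freq) <- peps
  labels <- label_detectability(freq)
  methods <- c("shuffle", "reverse", "shuffle_keep_cleavage", "shuffle_free")
  decoys <- character(0)
  for (r in seq_len(cfg$decoy_ratio)) {
    m <- methods[(r - 1L) %% length(methods) + 1L]
    d <- make_decoys(peps, m)
    d <- d[!d %in% peps]
    decoys <- c(decoys, d)
  }
  decoys <- unique(decoys)
  keep <- !Reduce(`|`, lapply(cfg$motifs, function(m)
    grepl(m, decoys, fixed = TRUE)), rep(FALSE, length(decoys)))
  decoys <- decoys[keep]
  list(peptides = peps, frequencies = freq, labels = labels,
       decoys = decoys, has_motif = has_motif)
}

#' Write a synthetic corpus to files
#'
#' MGF with SEQ annotations, a FASTA of the proteome (when given) and a
#' JSON manifest recording the seed, the configuration hash and counts,
#' so downstream stages can run end-to-end from files.
#'
#' @param spectra list of annotated spectra
#' @param dir output directory (created)
#' @param cfg the \code{\link{synth_config}} used
#' @param proteome optional proteome data.frame
#' @return invisible named vector of written paths
#' @export
write_corpus <- function(spectra, dir, cfg, proteome = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(mgf = file.path(dir, "spectra.mgf"))
  write_mgf(spectra, paths[["mgf"]])
  if (!is.null(proteome)) {
    paths[["fasta"]] <- file.path(dir, "proteome.fasta")
    write_fasta(stats::setNames(proteome$sequence, proteome$accession),
                paths[["fasta"]])
  }
  manifest <- list(seed = cfg$seed,
                   config_hash = config_hash(unclass(cfg)),
                   n_spectra = length(spectra),
                   n_proteins = if (is.null(proteome)) 0L else nrow(proteome))
  paths[["manifest"]] <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(paths)
}

# stable hash of a plain list (configs, manifests)
config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA), f)
  unname(tools::md5sum(f))
}
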