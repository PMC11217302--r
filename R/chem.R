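# Monoisotopic mass bookkeeping for residues, peptides and fragment ions.
# All masses in Da; all bookkeeping monoisotopic (the 0.1/0.5 Da matching
# tolerances used downstream presume monoisotopic masses).

#' Physical constants (monoisotopic, Da)
#'
#' Proton, water, ammonia, carbon monoxide and hydrogen masses used in every
#' charge/mass conversion and fragment-ion offset in the package.
#' @keywords internal
#' @name chem-constants
NULL

MASS_PROTON <- 1.007276
MASS_WATER  <- 18.010565
MASS_NH3    <- 17.026549
MASS_CO     <- 27.994915
MASS_H      <- 1.007825
MASS_PHOSPHO <- 79.966331

.CANONICAL_MASSES <- c(
  G = 57.021464, A = 71.037114, S = 87.032028, P = 97.052764,
  V = 99.068414, T = 101.047678, C = 103.009185, L = 113.084064,
  I = 113.084064, N = 114.042927, D = 115.026943, Q = 128.058578,
  K = 128.094963, E = 129.042593, M = 131.040485, H = 137.058912,
  F = 147.068414, R = 156.101111, Y = 163.063329, W = 186.079313
)

#' Residue vocabulary
#'
#' Builds the token set shared by the seq2seq model, the decoder, the
#' rescorer and the synthetic-data generator: massful residue tokens plus
#' the massless special tokens (pad, start, end, mask). Modified residues
#' are distinct tokens; phosphorylated S/T/Y are shipped by default as the
#' lowercase tokens \code{s}, \code{t}, \code{y} (residue mass + 79.966331).
#'
#' @param residues named numeric vector of residue monoisotopic masses;
#'   defaults to the 20 canonical amino acids. Token names must be single
#'   characters.
#' @param phospho add the three phospho tokens \code{s}, \code{t}, \code{y}.
#' @param extra optional named numeric vector of additional modified tokens.
#' @return an object of class \code{residue_vocab} with fields
#'   \code{tokens} (residue tokens), \code{masses} (named masses),
#'   \code{special} (pad/start/end/mask token strings), \code{all_tokens}
#'   (specials first, then residues; defines integer token ids), and the
#'   id bookkeeping used by the models.
#' @examples
#' v <- residue_vocab()
#' residue_mass("G", v)
#' @export
residue_vocab <- function(residues = .CANONICAL_MASSES, phospho = TRUE,
                          extra = NULL) {
  stopifnot(is.numeric(residues), !is.null(names(residues)))
  masses <- residues
  if (phospho) {
    ph <- c(s = unname(residues["S"]) + MASS_PHOSPHO,
            t = unname(residues["T"]) + MASS_PHOSPHO,
            y = unname(residues["Y"]) + MASS_PHOSPHO)
    ph <- ph[!is.na(ph)]
    masses <- c(masses, ph)
  }
  if (!is.null(extra)) {
    stopifnot(is.numeric(extra), !is.null(names(extra)))
    masses <- c(masses, extra)
  }
  if (any(nchar(names(masses)) != 1L))
    stop("residue tokens must be single characters")
  if (anyDuplicated(names(masses)))
    stop("duplicate residue tokens in vocabulary")
  if (any(masses <= 0)) stop("every residue token must have positive mass")
  special <- c(pad = "<pad>", start = "<s>", end = "</s>", mask = "<mask>")
  all_tokens <- c(unname(special), names(masses))
  structure(
    list(tokens = names(masses),
         masses = masses,
         special = special,
         all_tokens = all_tokens,
         pad_id = 1L, start_id = 2L, end_id = 3L, mask_id = 4L,
         n_special = 4L,
         residue_ids = seq_along(masses) + 4L),
    class = "residue_vocab")
}

#' @export
print.residue_vocab <- function(x, ...) {
  cat(sprintf("residue_vocab: %d residue tokens + %d special tokens\n",
              length(x$tokens), x$n_special))
  cat("  residues:", paste(x$tokens, collapse = " "), "\n")
  invisible(x)
}

#' Hash of a vocabulary (used to stamp model checkpoints)
#' @param vocab a \code{residue_vocab}
#' @return md5 string over tokens and masses
#' @keywords internal
vocab_hash <- function(vocab) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(sprintf("%s\t%.6f", vocab$tokens, vocab$masses), f)
  unname(tools::md5sum(f))
}

#' Read / write a vocabulary table
#'
#' Plain-text serialization: tab-separated columns \code{token},
#' \code{mass}, \code{flags} (comma-joined; \code{mod} marks modified
#' tokens). A default table covering the canonical residues and the three
#' phospho tokens ships in \code{inst/extdata/vocabulary.tsv}.
#'
#' @param path file path
#' @return \code{read_vocab}: a \code{residue_vocab}
#' @export
read_vocab <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#",
                           colClasses = c("character", "numeric", "character"))
  masses <- stats::setNames(tab$mass, tab$token)
  residue_vocab(residues = masses, phospho = FALSE)
}

#' @rdname read_vocab
#' @param vocab a \code{residue_vocab}
#' @export
write_vocab <- function(vocab, path) {
  mod <- ifelse(vocab$tokens %in% names(.CANONICAL_MASSES), "", "mod")
  tab <- data.frame(token = vocab$tokens,
                    mass = sprintf("%.6f", vocab$masses),
                    flags = mod)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Monoisotopic residue mass
#'
#' @param token residue token(s); special tokens are an error (they carry
#'   no mass).
#' @param vocab a \code{residue_vocab}
#' @return numeric vector of residue masses (Da)
#' @export
residue_mass <- function(token, vocab) {
  if (any(token %in% vocab$special))
    stop("special tokens have no mass: ",
         paste(intersect(token, vocab$special), collapse = ", "))
  m <- vocab$masses[token]
  if (anyNA(m))
    stop("unknown residue token(s): ",
         paste(unique(token[is.na(m)]), collapse = ", "))
  unname(m)
}

#' Split a peptide string into residue tokens
#' @param sequence peptide as a string or an already-split character vector
#' @param vocab a \code{residue_vocab}
#' @return character vector of single-character residue tokens
#' @export
tokenize_peptide <- function(sequence, vocab) {
  if (length(sequence) == 1L && nchar(sequence) > 1L)
    sequence <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  bad <- setdiff(sequence, vocab$tokens)
  if (length(bad))
    stop("unknown residue token(s): ", paste(unique(bad), collapse = ", "))
  sequence
}

#' Neutral monoisotopic peptide mass
#'
#' Sum of residue masses plus one water (the intact, uncharged peptide).
#'
#' @inheritParams tokenize_peptide
#' @return neutral monoisotopic mass in Da
#' @examples
#' v <- residue_vocab()
#' peptide_mass("GG", v)   # 132.05349
#' @export
peptide_mass <- function(sequence, vocab) {
  if (length(sequence) == 0L ||
      (length(sequence) == 1L && !nzchar(sequence)))
    stop("empty peptide sequence")
  toks <- tokenize_peptide(sequence, vocab)
  sum(residue_mass(toks, vocab)) + MASS_WATER
}

# neutral mass <-> m/z conversions (z protons added on ionisation)
#' Convert between m/z and neutral mass
#' @param mz,neutral_mass value to convert (Da/charge resp. Da)
#' @param charge positive integer charge state
#' @return the converted value
#' @export
mz_to_neutral <- function(mz, charge) mz * charge - charge * MASS_PROTON

#' @rdname mz_to_neutral
#' @export
neutral_to_mz <- function(neutral_mass, charge)
  (neutral_mass + charge * MASS_PROTON) / charge

#' Theoretical fragment ions
#'
#' Enumerates a/b/c (N-terminal) and y/z (C-terminal) fragment ions for all
#' cleavage positions and charges 1..\code{charge_max}. Offsets follow the
#' standard conventions: b = prefix residues + proton; a = b - CO;
#' c = b + NH3; y = suffix residues + water + proton; z = y - NH3, and by
#' default the radical z-dot ion (z + H) commonly observed in ETD spectra.
#'
#' @param sequence peptide (string or token vector), length >= 2
#' @param charge_max maximum fragment charge
#' @param kinds subset of c("a","b","c","y","z")
#' @param vocab a \code{residue_vocab}
#' @param z_dot use the z+H (z-dot) convention for z ions (default TRUE)
#' @return data.frame with columns kind, index (1-based from the ion's own
#'   terminus), charge, mz
#' @export
fragment_ions <- function(sequence, charge_max = 1L, kinds = c("b", "y"),
                          vocab, z_dot = TRUE) {
  toks <- tokenize_peptide(sequence, vocab)
  n <- length(toks)
  if (n < 2L) stop("peptide must have at least 2 residues")
  kinds <- match.arg(kinds, c("a", "b", "c", "y", "z"), several.ok = TRUE)
  rm <- residue_mass(toks, vocab)
  prefix <- cumsum(rm)[-n]              # neutral residue sums, k = 1..n-1
  suffix <- cumsum(rev(rm))[-n]         # suffix sums, k = 1..n-1 from C-term
  out <- vector("list", length(kinds) * charge_max)
  i <- 0L
  for (kind in kinds) {
    neutral <- switch(kind,
      b = prefix,
      a = prefix - MASS_CO,
      c = prefix + MASS_NH3,
      y = suffix + MASS_WATER,
      z = suffix + MASS_WATER - MASS_NH3 + if (z_dot) MASS_H else 0)
    for (z in seq_len(charge_max)) {
      i <- i + 1L
      out[[i]] <- data.frame(kind = kind, index = seq_len(n - 1L),
                             charge = z,
                             mz = (neutral + z * MASS_PROTON) / z)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
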