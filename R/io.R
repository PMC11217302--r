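# Readers and writers: MGF, mzML (via mzR), FASTA (via Biostrings), and the
# pipeline's TSV outputs. Readers enforce the Spectrum invariants (peaks
# sorted by m/z, non-negative intensities, derived precursor neutral mass).

#' Tandem mass spectrum
#'
#' Container for one MS2 peak list. Peaks are sorted ascending by m/z on
#' construction; the precursor neutral mass is derived as
#' \code{mz * z - z * proton}.
#'
#' @param spectrum_id identifier string
#' @param mz,intensity numeric peak vectors (equal length)
#' @param precursor_mz precursor m/z (Da/charge)
#' @param precursor_charge positive integer; if missing/NA it is imputed as
#'   2 (most tryptic precursors) and the record is flagged
#'   (\code{charge_imputed}).
#' @param peptide optional ground-truth peptide annotation (training data)
#' @return object of class \code{spectrum}
#' @export
spectrum <- function(spectrum_id, mz, intensity, precursor_mz,
                     precursor_charge = NA_integer_, peptide = NA_character_) {
  stopifnot(length(mz) == length(intensity))
  if (any(intensity < 0)) stop("negative peak intensity in ", spectrum_id)
  ord <- order(mz)
  charge_imputed <- FALSE
  if (is.na(precursor_charge)) {
    precursor_charge <- 2L
    charge_imputed <- TRUE
  }
  if (precursor_charge < 1L) stop("precursor charge must be >= 1")
  structure(
    list(spectrum_id = as.character(spectrum_id),
         mz = as.numeric(mz[ord]), intensity = as.numeric(intensity[ord]),
         precursor_mz = precursor_mz,
         precursor_charge = as.integer(precursor_charge),
         precursor_neutral_mass = mz_to_neutral(precursor_mz, precursor_charge),
         charge_imputed = charge_imputed,
         peptide = peptide),
    class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("spectrum %s: %d peaks, precursor %.4f m/z (%d+), neutral %.4f Da%s\n",
              x$spectrum_id, length(x$mz), x$precursor_mz,
              x$precursor_charge, x$precursor_neutral_mass,
              if (!is.na(x$peptide)) paste0(", SEQ=", x$peptide) else ""))
  invisible(x)
}

#' Read an MGF peak-list file
#'
#' One \code{spectrum} per BEGIN/END IONS block. \code{PEPMASS} gives the
#' precursor m/z, \code{CHARGE} is parsed with its sign, and annotated
#' \code{SEQ=} lines (training data) are captured when present. Records
#' without a PEPMASS are dropped with a warning naming the spectrum;
#' malformed peak lines are skipped with a warning.
#'
#' @param path MGF file
#' @param callback optional function applied to each spectrum in file order
#'   (streaming use); when supplied, spectra are not accumulated and
#'   \code{invisible(NULL)} is returned.
#' @return list of \code{spectrum} objects (file order), or NULL with
#'   callback
#' @export
read_mgf <- function(path, callback = NULL) {
  lines <- readLines(path)
  begins <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(begins) != length(ends))
    stop("malformed MGF: unbalanced BEGIN/END IONS")
  out <- if (is.null(callback)) vector("list", length(begins)) else NULL
  kept <- 0L
  for (b in seq_along(begins)) {
    block <- lines[(begins[b] + 1L):(ends[b] - 1L)]
    kv <- grepl("=", block, fixed = TRUE)
    keys <- sub("=.*$", "", block[kv])
    vals <- sub("^[^=]*=", "", block[kv])
    id <- if ("TITLE" %in% keys) vals[match("TITLE", keys)]
          else sprintf("index=%d", b)
    if (!"PEPMASS" %in% keys) {
      warning("MGF record without PEPMASS skipped: ", id)
      next
    }
    pepmass <- as.numeric(strsplit(trimws(vals[match("PEPMASS", keys)]),
                                   "[ \t]+")[[1L]][1L])
    charge <- NA_integer_
    if ("CHARGE" %in% keys) {
      ch <- vals[match("CHARGE", keys)]
      sign <- if (grepl("-", ch, fixed = TRUE)) -1L else 1L
      charge <- sign * as.integer(gsub("[^0-9]", "", ch))
      if (!is.na(charge) && charge < 0)
        stop("negative precursor charge unsupported: ", id)
    }
    seq_ann <- if ("SEQ" %in% keys) vals[match("SEQ", keys)] else NA_character_
    peak_lines <- trimws(block[!kv])
    peak_lines <- peak_lines[nzchar(peak_lines)]
    mzs <- numeric(0); ints <- numeric(0)
    if (length(peak_lines)) {
      fields <- strsplit(peak_lines, "[ \t]+")
      ok <- vapply(fields, function(f)
        length(f) >= 2L && !anyNA(suppressWarnings(as.numeric(f[1:2]))),
        logical(1))
      if (any(!ok))
        warning(sum(!ok), " malformed peak line(s) skipped in ", id)
      mzs <- vapply(fields[ok], function(f) as.numeric(f[1L]), numeric(1))
      ints <- vapply(fields[ok], function(f) as.numeric(f[2L]), numeric(1))
    }
    sp <- spectrum(id, mzs, ints, pepmass, charge, peptide = seq_ann)
    kept <- kept + 1L
    if (is.null(callback)) out[[kept]] <- sp else callback(sp)
  }
  if (is.null(callback)) out[seq_len(kept)] else invisible(NULL)
}

#' Write spectra to MGF
#'
#' Writes \code{SEQ=} lines for annotated spectra so the synthetic corpus
#' round-trips through files.
#' @param spectra list of \code{spectrum}
#' @param path output file
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (sp in spectra) {
    writeLines(c("BEGIN IONS",
                 paste0("TITLE=", sp$spectrum_id),
                 sprintf("PEPMASS=%.6f", sp$precursor_mz),
                 sprintf("CHARGE=%d+", sp$precursor_charge)), con)
    if (!is.na(sp$peptide)) writeLines(paste0("SEQ=", sp$peptide), con)
    if (length(sp$mz))
      writeLines(sprintf("%.6f %.6f", sp$mz, sp$intensity), con)
    writeLines("END IONS", con)
  }
  invisible(path)
}

#' Read MS2 spectra from mzML
#'
#' Uses \pkg{mzR}. Only MS-level-2 scans are returned; the precursor m/z
#' and charge come from the selected-ion metadata. Scans without a
#' precursor charge are imputed as 2+ and flagged.
#'
#' @param path mzML file
#' @inheritParams read_mgf
#' @return list of \code{spectrum} (acquisition order), or NULL with
#'   callback
#' @export
read_mzml <- function(path, callback = NULL) {
  fh <- mzR::openMSfile(path)
  on.exit(mzR::close(fh))
  hd <- mzR::header(fh)
  ms2 <- which(hd$msLevel == 2L)
  out <- if (is.null(callback)) vector("list", length(ms2)) else NULL
  for (j in seq_along(ms2)) {
    i <- ms2[j]
    pk <- mzR::peaks(fh, i)
    charge <- hd$precursorCharge[i]
    if (is.na(charge) || charge == 0L) charge <- NA_integer_
    id <- if (!is.null(hd$spectrumId) && nzchar(hd$spectrumId[i]))
      hd$spectrumId[i] else sprintf("scan=%d", hd$acquisitionNum[i])
    sp <- spectrum(id, pk[, 1L], pk[, 2L], hd$precursorMZ[i], charge)
    if (is.null(callback)) out[[j]] <- sp else callback(sp)
  }
  if (is.null(callback)) out else invisible(NULL)
}

#' Write a minimal uncompressed mzML file
#'
#' Emits a small, schema-conformant mzML document (64-bit little-endian
#' peak arrays, no compression) sufficient for round-tripping synthetic
#' spectra through standard mzML readers.
#' @param spectra list of \code{spectrum}
#' @param path output file
#' @export
write_mzml <- function(spectra, path) {
  b64 <- function(x) {
    raw <- writeBin(as.numeric(x), raw(), size = 8L, endian = "little")
    gsub("\n", "", jsonlite::base64_enc(raw), fixed = TRUE)
  }
  con <- file(path, "w")
  on.exit(close(con))
  n <- length(spectra)
  writeLines(c(
    '<?xml version="1.0" encoding="utf-8"?>',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">',
    '<cvList count="1"><cv id="MS" fullName="PSI-MS" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/></cvList>',
    '<fileDescription><fileContent><cvParam cvRef="MS" accession="MS:1000580" name="MSn spectrum" value=""/></fileContent></fileDescription>',
    '<softwareList count="1"><software id="tandemnovo" version="0.1"/></softwareList>',
    '<instrumentConfigurationList count="1"><instrumentConfiguration id="IC1"/></instrumentConfigurationList>',
    '<dataProcessingList count="1"><dataProcessing id="dp1"><processingMethod order="1" softwareRef="tandemnovo"/></dataProcessing></dataProcessingList>',
    '<run id="run1" defaultInstrumentConfigurationRef="IC1">',
    sprintf('<spectrumList count="%d" defaultDataProcessingRef="dp1">', n)), con)
  for (i in seq_len(n)) {
    sp <- spectra[[i]]
    mzb <- b64(sp$mz); inb <- b64(sp$intensity)
    writeLines(c(
      sprintf('<spectrum index="%d" id="%s" defaultArrayLength="%d">',
              i - 1L, sp$spectrum_id, length(sp$mz)),
      '<cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="2"/>',
      '<cvParam cvRef="MS" accession="MS:1000580" name="MSn spectrum" value=""/>',
      '<precursorList count="1"><precursor><selectedIonList count="1"><selectedIon>',
      sprintf('<cvParam cvRef="MS" accession="MS:1000744" name="selected ion m/z" value="%.6f" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>',
              sp$precursor_mz),
      sprintf('<cvParam cvRef="MS" accession="MS:1000041" name="charge state" value="%d"/>',
              sp$precursor_charge),
      '</selectedIon></selectedIonList><activation/></precursor></precursorList>',
      '<binaryDataArrayList count="2">',
      sprintf('<binaryDataArray encodedLength="%d">', nchar(mzb)),
      '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>',
      '<cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>',
      '<cvParam cvRef="MS" accession="MS:1000514" name="m/z array" value="" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>',
      sprintf('<binary>%s</binary>', mzb),
      '</binaryDataArray>',
      sprintf('<binaryDataArray encodedLength="%d">', nchar(inb)),
      '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>',
      '<cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>',
      '<cvParam cvRef="MS" accession="MS:1000515" name="intensity array" value="" unitCvRef="MS" unitAccession="MS:1000131" unitName="number of detector counts"/>',
      sprintf('<binary>%s</binary>', inb),
      '</binaryDataArray></binaryDataArrayList></spectrum>'), con)
  }
  writeLines(c('</spectrumList></run></mzML>'), con)
  invisible(path)
}

#' Read a protein FASTA database
#'
#' @param path FASTA file
#' @return data.frame with columns accession (first word of the header),
#'   description, sequence (uppercase). Non-standard residue codes
#'   (B, Z, X, U) are retained in the sequence; the protein-inference
#'   module excludes them from k-mer indexing.
#' @export
read_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  nm <- names(aa)
  data.frame(
    accession = sub("[ \t].*$", "", nm),
    description = ifelse(grepl("[ \t]", nm), sub("^[^ \t]+[ \t]+", "", nm), ""),
    sequence = toupper(as.character(aa)),
    stringsAsFactors = FALSE)
}

#' Write sequences to FASTA
#' @param sequences named character vector (names become headers)
#' @param path output file
#' @export
write_fasta <- function(sequences, path) {
  aa <- Biostrings::AAStringSet(sequences)
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

#' Pipeline output tables
#'
#' Stable TSV schemata. Predictions: \code{spectrum_id}, \code{peptide},
#' \code{residue_scores} (comma-joined per-residue confidences),
#' \code{confidence}, \code{detectability}. Rows with an empty peptide
#' (no completable hypothesis) are written, not dropped, for auditability.
#' Contigs: \code{contig}, \code{score}, \code{n_support},
#' \code{support} (comma-joined peptide ids). Protein report: see
#' \code{\link{protein_report}}.
#'
#' @param predictions data.frame as produced by \code{\link{denovo}}
#' @param path output TSV
#' @name output-tables
#' @export
write_predictions <- function(predictions, path) {
  df <- predictions
  df$residue_scores <- vapply(df$residue_scores, function(s)
    paste(sprintf("%.6f", s), collapse = ","), character(1))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' @rdname output-tables
#' @export
read_predictions <- function(path) {
  df <- utils::read.delim(path, colClasses = "character", na.strings = NULL)
  df$confidence <- as.numeric(df$confidence)
  df$residue_scores <- lapply(strsplit(df$residue_scores, ",", fixed = TRUE),
                              as.numeric)
  df
}

#' @rdname output-tables
#' @param contigs data.frame from \code{\link{extract_contigs}}
#' @export
write_contigs <- function(contigs, path) {
  df <- contigs
  df$support <- vapply(df$support, paste, character(1), collapse = ",")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname output-tables
#' @export
read_contigs <- function(path) {
  df <- utils::read.delim(path, colClasses = "character")
  df$score <- as.numeric(df$score)
  df$n_support <- as.integer(df$n_support)
  df$support <- strsplit(df$support, ",", fixed = TRUE)
  df
}

#' @rdname output-tables
#' @param report data.frame from \code{\link{protein_report}} or
#'   \code{\link{infer_proteins}}
#' @export
write_protein_report <- function(report, path) {
  df <- report
  if (is.list(df$contigs))
    df$contigs <- vapply(df$contigs, paste, character(1), collapse = ",")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}
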