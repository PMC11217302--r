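# Amino-acid- and peptide-level matching metrics for de novo sequencing.
# A predicted residue matches a true residue when their masses differ by
# less than 0.1 Da and the masses of the prefixes before them differ by
# less than 0.5 Da; the match count is the maximum order-preserving
# (monotone) matching under both constraints.

#' Match predicted vs true residues under mass tolerances
#'
#' Computes the maximum monotone matching: predicted residue i can pair
#' with true residue j iff |m_i - m_j| < \code{residue_tol} and
#' |prefix_i - prefix_j| < \code{prefix_tol} (prefix = summed residue
#' masses before the position); pairs are order-preserving and each
#' residue is used at most once. A peptide-level match requires every
#' true residue matched and equal lengths.
#'
#' @param pred predicted peptide (string; may be empty)
#' @param truth true peptide (string)
#' @param vocab a \code{\link{residue_vocab}}
#' @param residue_tol residue mass tolerance in Da (default 0.1)
#' @param prefix_tol prefix mass tolerance in Da (default 0.5)
#' @return object of class \code{match_result}: n_matched, pred_length,
#'   truth_length, peptide_match
#' @export
match_residues <- function(pred, truth, vocab, residue_tol = 0.1,
                           prefix_tol = 0.5) {
  tt <- tokenize_peptide(truth, vocab)
  tm <- residue_mass(tt, vocab)
  tp <- c(0, cumsum(tm))[seq_along(tm)]
  if (is.na(pred) || !nzchar(pred)) {
    return(structure(list(n_matched = 0L, pred_length = 0L,
                          truth_length = length(tm), peptide_match = FALSE),
                     class = "match_result"))
  }
  pt <- tokenize_peptide(pred, vocab)
  pm <- residue_mass(pt, vocab)
  pp <- c(0, cumsum(pm))[seq_along(pm)]
  n <- length(pm); m <- length(tm)
  # dp over maximum monotone matching
  f <- matrix(0L, n + 1L, m + 1L)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      ok <- abs(pm[i] - tm[j]) < residue_tol &&
        abs(pp[i] - tp[j]) < prefix_tol
      f[i + 1L, j + 1L] <- max(f[i, j + 1L], f[i + 1L, j],
                               f[i, j] + as.integer(ok))
    }
  }
  n_matched <- f[n + 1L, m + 1L]
  structure(list(n_matched = n_matched, pred_length = n, truth_length = m,
                 peptide_match = n_matched == m && n == m),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("match_result: %d/%d true residues matched (pred length %d)%s\n",
              x$n_matched, x$truth_length, x$pred_length,
              if (x$peptide_match) " [peptide match]" else ""))
  invisible(x)
}

#' Corpus-level precision and recall
#'
#' Amino-acid recall is the total number of matched residues over the
#' total length of the true peptides; amino-acid precision divides by
#' the total predicted length instead. Peptide-level analogues count
#' spectra: recall over all spectra, precision over spectra with a
#' non-empty prediction. With no predictions emitted, precision is
#' reported as 0 and flagged (\code{attr(, "no_predictions")}).
#'
#' @param results list of \code{\link{match_residues}} results
#' @return named numeric vector: aa_precision, aa_recall,
#'   peptide_precision, peptide_recall
#' @export
corpus_metrics <- function(results) {
  matched <- sum(vapply(results, `[[`, integer(1), "n_matched"))
  pred_len <- sum(vapply(results, `[[`, integer(1), "pred_length"))
  truth_len <- sum(vapply(results, `[[`, integer(1), "truth_length"))
  pep_ok <- vapply(results, `[[`, logical(1), "peptide_match")
  emitted <- vapply(results, function(r) r$pred_length > 0L, logical(1))
  no_pred <- pred_len == 0L
  out <- c(aa_precision = if (no_pred) 0 else matched / pred_len,
           aa_recall = if (truth_len) matched / truth_len else 0,
           peptide_precision = if (any(emitted))
             sum(pep_ok) / sum(emitted) else 0,
           peptide_recall = mean(pep_ok))
  if (no_pred) attr(out, "no_predictions") <- TRUE
  out
}

#' Precision-recall curve over confidence thresholds
#'
#' Predictions are sorted by decreasing confidence; at each distinct
#' confidence value taken as a threshold, precision is the fraction of
#' retained predictions that are correct and recall is the fraction of
#' all spectra correctly predicted. Coverage is monotone non-increasing
#' as the threshold rises.
#'
#' @param confidences numeric vector of prediction confidences
#' @param correct logical vector (peptide-level match per prediction)
#' @param n_total total number of spectra (default
#'   \code{length(correct)}): the recall denominator
#' @return data.frame: threshold, precision, recall, coverage (points at
#'   every distinct confidence value, descending)
#' @export
pr_curve <- function(confidences, correct, n_total = length(correct)) {
  stopifnot(length(confidences) == length(correct))
  ord <- order(confidences, decreasing = TRUE)
  conf <- confidences[ord]
  corr <- correct[ord]
  cum_ok <- cumsum(corr)
  k <- seq_along(conf)
  last <- !duplicated(conf, fromLast = TRUE)  # last index of each value
  data.frame(threshold = conf[last],
             precision = (cum_ok / k)[last],
             recall = (cum_ok / n_total)[last],
             coverage = (k / n_total)[last])
}
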