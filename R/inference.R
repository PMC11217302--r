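# Contig-to-protein mapping and protein inference: k-mer candidate search
# with local-alignment identity (a few good candidates suffice; candidates
# are examined in decreasing order of shared unique k-mers until a run of
# rejects), followed by iterative parsimony scoring that clusters contigs
# into proteins.

.identity_submat <- function() {
  alpha <- c(LETTERS, "*")
  m <- matrix(-1, length(alpha), length(alpha),
              dimnames = list(alpha, alpha))
  diag(m) <- 1
  m
}

# best local alignment of contig vs protein with match=1, mismatch=-1,
# gap=-2 (linear); identity = matches / alignment length
.align_contig <- function(contig, protein) {
  aln <- Biostrings::pairwiseAlignment(
    pattern = contig, subject = protein, type = "local",
    substitutionMatrix = .identity_submat(),
    gapOpening = 0, gapExtension = 2)
  pat <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1L]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1L]]
  list(identity = sum(pat == sub) / length(pat),
       n_match = sum(pat == sub),
       length = length(pat),
       pattern = pat, subject = sub,
       subject_start = Biostrings::start(Biostrings::subject(aln)),
       subject_end = Biostrings::end(Biostrings::subject(aln)))
}

.kmerize <- function(x, k) {
  n <- nchar(x)
  if (n < k) return(character(0))
  unique(substring(x, 1:(n - k + 1L), k:n))
}

#' k-mer candidate search of a contig against a protein database
#'
#' Candidate proteins are ranked by U, the number of unique k-mers they
#' share with the contig, and examined in decreasing order of U. Each
#' candidate's similarity to the contig is the identity of the best
#' local alignment (match 1, mismatch -1, gap -2; identity = matches /
#' alignment length). Candidates at or above the identity threshold are
#' hits; scanning stops after \code{max_rejects} consecutive rejects.
#' Protein k-mers containing non-standard residue codes (B, Z, X, U) are
#' excluded from indexing.
#'
#' @param contig contig sequence (length >= k)
#' @param protein_db data.frame from \code{\link{read_fasta}}
#' @param k search k-mer size (default 5)
#' @param identity_threshold hit threshold on alignment identity
#'   (default 0.8)
#' @param max_rejects consecutive rejects before the scan stops
#'   (default 8)
#' @return data.frame of examined candidates: accession, U, identity,
#'   status (\code{"hit"}/\code{"reject"}), ordered by decreasing U;
#'   zero rows when no protein shares a k-mer (or the database is empty)
#' @export
search_candidates <- function(contig, protein_db, k = 5L,
                              identity_threshold = 0.8, max_rejects = 8L) {
  if (nchar(contig) < k) stop("contig shorter than k")
  empty <- data.frame(accession = character(0), U = integer(0),
                      identity = numeric(0), status = character(0))
  if (!nrow(protein_db)) return(empty)
  ckm <- .kmerize(contig, k)
  U <- vapply(protein_db$sequence, function(s) {
    pk <- .kmerize(s, k)
    pk <- pk[!grepl("[BZXU]", pk)]
    length(intersect(ckm, pk))
  }, integer(1), USE.NAMES = FALSE)
  cand <- which(U > 0L)
  if (!length(cand)) return(empty)
  cand <- cand[order(-U[cand], protein_db$accession[cand])]
  rows <- list()
  rejects <- 0L
  for (i in cand) {
    al <- .align_contig(contig, protein_db$sequence[i])
    hit <- al$identity >= identity_threshold
    rows[[length(rows) + 1L]] <- data.frame(
      accession = protein_db$accession[i], U = U[i],
      identity = al$identity, status = if (hit) "hit" else "reject")
    if (hit) rejects <- 0L
    else {
      rejects <- rejects + 1L
      if (rejects >= max_rejects) break
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Iterative protein inference
#'
#' Clusters contigs into proteins by iterative parsimony scoring:
#' \enumerate{
#'   \item unscored proteins get a provisional score equal to the sum of
#'     the scores of their associated, still-unassigned contigs;
#'   \item the protein with the highest provisional score is assigned its
#'     currently associated contigs, which are then excluded;
#'   \item any protein left without a possible unassigned contig is
#'     marked a subset of the protein last assigned peptides;
#'   \item repeat until every contig is assigned.
#' }
#' Ties in step 2 break lexicographically by accession, making runs
#' deterministic. Provisional scores are recomputed over the remaining
#' unassigned contigs each round by default; set \code{recompute =
#' FALSE} to freeze them at their first-round values.
#'
#' @param hits data.frame with columns \code{contig} (contig identifier)
#'   and \code{accession} (protein it may belong to); one row per
#'   association (e.g. the hits from \code{\link{search_candidates}})
#' @param contig_scores named numeric vector: score per contig id
#' @param recompute recompute provisional scores each round
#' @return data.frame: accession, score (provisional score at
#'   assignment), contigs (list-column of assigned contig ids; empty for
#'   subset proteins), subset_of (accession or NA). Every input contig
#'   appears in exactly one protein's assignment.
#' @export
infer_proteins <- function(hits, contig_scores, recompute = TRUE) {
  stopifnot(all(c("contig", "accession") %in% names(hits)))
  contigs_all <- unique(hits$contig)
  if (!all(contigs_all %in% names(contig_scores)))
    stop("missing scores for contig(s): ",
         paste(setdiff(contigs_all, names(contig_scores)), collapse = ", "))
  assoc <- split(hits$contig, hits$accession)
  assoc <- lapply(assoc, unique)
  prots <- sort(names(assoc))
  unassigned <- contigs_all
  frozen <- vapply(prots, function(p)
    sum(contig_scores[assoc[[p]]]), numeric(1))
  pending <- prots
  last_assigned <- NA_character_
  rows <- list()
  while (length(unassigned) && length(pending)) {
    prov <- if (recompute)
      vapply(pending, function(p)
        sum(contig_scores[intersect(assoc[[p]], unassigned)]), numeric(1))
    else frozen[pending]
    best <- pending[order(-prov, pending)][1L]
    take <- intersect(assoc[[best]], unassigned)
    rows[[length(rows) + 1L]] <- list(accession = best,
                                      score = unname(prov[best]),
                                      contigs = take,
                                      subset_of = NA_character_)
    unassigned <- setdiff(unassigned, take)
    pending <- setdiff(pending, best)
    last_assigned <- best
    # step c: proteins with no possible unassigned contigs become subsets
    empty_now <- pending[vapply(pending, function(p)
      length(intersect(assoc[[p]], unassigned)) == 0L, logical(1))]
    for (p in empty_now) {
      rows[[length(rows) + 1L]] <- list(accession = p, score = 0,
                                        contigs = character(0),
                                        subset_of = last_assigned)
    }
    pending <- setdiff(pending, empty_now)
  }
  out <- data.frame(
    accession = vapply(rows, `[[`, character(1), "accession"),
    score = vapply(rows, `[[`, numeric(1), "score"),
    subset_of = vapply(rows, `[[`, character(1), "subset_of"),
    stringsAsFactors = FALSE)
  out$contigs <- lapply(rows, `[[`, "contigs")
  out[, c("accession", "score", "contigs", "subset_of")]
}

#' Protein-level coverage and accuracy report
#'
#' For each protein with assigned contigs: number of mapped contigs,
#' longest contig (residues and percent of protein length), sequence
#' coverage (percent of protein positions covered by at least one
#' aligned contig) and accuracy (percent of aligned contig calls that
#' match the protein residue). Only contigs whose best local alignment
#' reaches \code{identity_threshold} (default 0.8) are counted.
#'
#' @param assignments data.frame from \code{\link{infer_proteins}}
#' @param contig_seqs named character vector: contig id -> sequence
#' @param protein_db data.frame from \code{\link{read_fasta}}
#' @param identity_threshold minimum alignment identity for a contig to
#'   count (default 0.8)
#' @return data.frame: accession, n_contigs, longest, longest_pct,
#'   coverage_pct, accuracy_pct, score, subset_of
#' @export
protein_report <- function(assignments, contig_seqs, protein_db,
                           identity_threshold = 0.8) {
  rows <- vector("list", nrow(assignments))
  for (i in seq_len(nrow(assignments))) {
    acc <- assignments$accession[i]
    pseq <- protein_db$sequence[match(acc, protein_db$accession)]
    plen <- nchar(pseq)
    covered <- logical(plen)
    n_call <- 0L; n_correct <- 0L; n_used <- 0L; longest <- 0L
    for (cid in assignments$contigs[[i]]) {
      cseq <- contig_seqs[[cid]]
      al <- .align_contig(cseq, pseq)
      if (al$identity < identity_threshold) next
      n_used <- n_used + 1L
      longest <- max(longest, nchar(cseq))
      pos <- al$subject_start
      for (j in seq_along(al$subject)) {
        if (al$subject[j] != "-") {
          if (al$pattern[j] != "-") {
            covered[pos] <- TRUE
            n_call <- n_call + 1L
            if (al$pattern[j] == al$subject[j])
              n_correct <- n_correct + 1L
          }
          pos <- pos + 1L
        }
      }
    }
    rows[[i]] <- data.frame(
      accession = acc, n_contigs = n_used, longest = longest,
      longest_pct = 100 * longest / plen,
      coverage_pct = 100 * sum(covered) / plen,
      accuracy_pct = if (n_call) 100 * n_correct / n_call else NA_real_,
      score = assignments$score[i],
      subset_of = assignments$subset_of[i],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
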