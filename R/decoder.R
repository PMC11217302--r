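# Knapsack-constrained beam search. A residue extension is admitted only
# if the mass remaining after it is reachable by some residue multiset
# (knapsack feasibility), so every completed hypothesis matches the
# precursor neutral mass within tolerance -- by construction, not post hoc.

#' Build a knapsack feasibility table
#'
#' Exact dynamic-programming reachability over the discretised residue
#' masses of a vocabulary: bin \code{b} is feasible iff some multiset of
#' residue masses sums into it. Bin 0 (empty multiset) is always
#' feasible.
#'
#' @param vocab a \code{\link{residue_vocab}} (or a bare named numeric
#'   vector of residue masses)
#' @param resolution bin width in Da (default 1e-4)
#' @param max_mass table upper bound in Da (must cover the precursor
#'   residue mass of every spectrum to be decoded)
#' @return object of class \code{knapsack_table}
#' @export
build_knapsack <- function(vocab, resolution = 1e-4, max_mass) {
  if (resolution <= 0) stop("resolution must be positive")
  if (max_mass <= 0) stop("max_mass must be positive")
  masses <- if (inherits(vocab, "residue_vocab")) vocab$masses else vocab
  feas <- knapsack_reachable_cpp(as.numeric(masses), resolution, max_mass)
  structure(list(feasible = feas, resolution = resolution,
                 max_mass = max_mass, masses = masses),
            class = "knapsack_table")
}

#' @export
print.knapsack_table <- function(x, ...) {
  cat(sprintf("knapsack_table: %d residues, %.4g Da bins up to %.2f Da (%d/%d bins feasible)\n",
              length(x$masses), x$resolution, x$max_mass,
              sum(x$feasible), length(x$feasible)))
  invisible(x)
}

#' Query knapsack feasibility of a remaining mass
#'
#' TRUE iff some feasible bin lies within \code{tolerance} of
#' \code{target} (with one extra bin of slack on each side against
#' rounding at bin edges).
#'
#' @param knapsack a \code{\link{build_knapsack}} table
#' @param target remaining mass(es), Da; vectorised
#' @param tolerance mass tolerance in Da
#' @return logical vector
#' @export
knapsack_feasible <- function(knapsack, target, tolerance = 0.1) {
  res <- knapsack$resolution
  n <- length(knapsack$feasible)
  vapply(target, function(tg) {
    if (tg < -tolerance) return(FALSE)
    lo <- max(0, floor((tg - tolerance) / res) - 1)
    hi <- min(n - 1, ceiling((tg + tolerance) / res) + 1)
    if (hi < lo) return(FALSE)
    any(knapsack$feasible[(lo + 1):(hi + 1)])
  }, logical(1))
}

#' Hypothesis confidence score
#'
#' Base confidence is \code{exp(mean per-token log-probability)}. A
#' hypothesis classified as decoy by the rescorer is forced to 0.
#'
#' @param per_token_logprobs numeric vector of per-token log-probabilities
#'   (residues plus the end token)
#' @param label optional detectability label from the rescorer
#'   (\code{"decoy"}, \code{"high"}, \code{"potential"})
#' @return confidence in [0, 1]
#' @export
score_hypothesis <- function(per_token_logprobs, label = NULL) {
  if (!is.null(label) && !is.na(label) && label == "decoy") return(0)
  exp(mean(per_token_logprobs))
}

# rank key: highly detectable first, then base confidence
.detect_priority <- function(label) {
  if (is.null(label) || is.na(label)) 1L
  else if (label == "high") 0L else 1L
}

#' Knapsack-constrained beam search
#'
#' Decodes one spectrum into ranked peptide hypotheses. At every
#' expansion a residue token is admissible only if the remaining
#' precursor residue mass after appending it falls in a feasible knapsack
#' bin within tolerance; the end token is admissible only when the
#' remaining mass itself is within tolerance. Completed hypotheses
#' therefore always satisfy \code{|peptide_mass - precursor_neutral_mass|
#' <= tolerance}. Ties between equal-log-probability expansions break
#' lexicographically by token index, so runs are deterministic.
#'
#' With a rescorer: hypotheses classified decoy are removed; highly
#' detectable hypotheses rank first; residues whose decoder
#' log-probability falls in the bottom \code{refine_quantile} of the
#' peptide are masked and the rescorer's proposals accepted when they
#' preserve mass feasibility and raise the combined score
#' (base confidence times 1 - P(decoy)).
#'
#' @param spec a \code{\link{spectrum}}
#' @param model a trained \code{denovo_model}
#' @param knapsack a \code{\link{build_knapsack}} table over the model
#'   vocabulary
#' @param beam_width number of live hypotheses (default 5)
#' @param tolerance neutral-mass tolerance in Da (default 0.1)
#' @param rescorer optional \code{peptide_bert} model
#' @param refine_quantile quantile of per-residue log-probability below
#'   which positions are mask-refined (default 0.1)
#' @param max_len maximum peptide length (default from model config)
#' @return data.frame with columns \code{peptide}, \code{confidence},
#'   \code{detectability}, \code{logprob}, \code{mass_delta} and the
#'   list-column \code{residue_scores}, ranked best first. Zero rows
#'   (with attribute \code{diagnostic}) when no hypothesis can complete.
#' @export
beam_search <- function(spec, model, knapsack, beam_width = 5L,
                        tolerance = 0.1, rescorer = NULL,
                        refine_quantile = 0.1, max_len = NULL) {
  cfg <- model$config
  vocab <- cfg$vocab
  if (is.null(max_len)) max_len <- cfg$max_len
  target <- spec$precursor_neutral_mass - MASS_WATER
  if (target > knapsack$max_mass)
    stop("precursor residue mass ", round(target, 2),
         " exceeds knapsack max_mass ", knapsack$max_mass)
  H <- encode_spectrum(model, spec)
  rids <- vocab$residue_ids
  rmass <- unname(vocab$masses)

  live <- list(list(ids = integer(0), cum = 0, lp = 0, steps = numeric(0)))
  completed <- list()
  for (step in seq_len(max_len + 1L)) {
    cand_hyp <- integer(0); cand_tok <- integer(0); cand_lp <- numeric(0)
    cand_step <- numeric(0)
    for (i in seq_along(live)) {
      hyp <- live[[i]]
      logp <- decode_step(model, H, hyp$ids)
      rem <- target - hyp$cum - rmass
      ok <- knapsack_feasible(knapsack, rem, tolerance)
      if (length(hyp$ids) >= max_len) ok[] <- FALSE
      toks <- rids[ok]
      if (abs(target - hyp$cum) <= tolerance && length(hyp$ids) > 0L)
        toks <- c(toks, vocab$end_id)
      if (!length(toks)) next
      cand_hyp <- c(cand_hyp, rep.int(i, length(toks)))
      cand_tok <- c(cand_tok, toks)
      cand_step <- c(cand_step, logp[toks])
      cand_lp <- c(cand_lp, hyp$lp + logp[toks])
    }
    if (!length(cand_tok)) break
    # completed hypotheses move to the pool without consuming beam slots:
    # the top candidates ending now are collected, and the beam keeps the
    # best beam_width continuing hypotheses exploring
    ord <- order(-cand_lp, cand_tok)
    ord <- ord[seq_len(min(2L * beam_width, length(ord)))]
    nxt <- list()
    for (j in ord) {
      hyp <- live[[cand_hyp[j]]]
      tok <- cand_tok[j]
      if (tok == vocab$end_id) {
        completed[[length(completed) + 1L]] <-
          list(ids = hyp$ids, cum = hyp$cum,
               steps = c(hyp$steps, cand_step[j]), lp = cand_lp[j])
      } else if (length(nxt) < beam_width) {
        nxt[[length(nxt) + 1L]] <-
          list(ids = c(hyp$ids, tok),
               cum = hyp$cum + rmass[tok - vocab$n_special],
               lp = cand_lp[j], steps = c(hyp$steps, cand_step[j]))
      }
    }
    live <- nxt
    if (!length(live)) break
  }

  empty <- data.frame(peptide = character(0), confidence = numeric(0),
                      detectability = character(0), logprob = numeric(0),
                      mass_delta = numeric(0))
  empty$residue_scores <- list()
  if (!length(completed)) {
    attr(empty, "diagnostic") <- sprintf(
      "no hypothesis completed within tolerance %.3g Da for %s (precursor residue mass %.4f)",
      tolerance, spec$spectrum_id, target)
    return(empty)
  }

  rows <- lapply(completed, function(h) {
    ids <- if (cfg$direction == "CN") rev(h$ids) else h$ids
    res_lp <- if (cfg$direction == "CN")
      rev(h$steps[-length(h$steps)]) else h$steps[-length(h$steps)]
    list(peptide = ids_to_peptide(ids, vocab),
         res_lp = res_lp, steps = h$steps, lp = h$lp,
         mass_delta = (h$cum + MASS_WATER) - spec$precursor_neutral_mass)
  })

  label <- rep(NA_character_, length(rows))
  if (!is.null(rescorer)) {
    for (i in seq_along(rows)) {
      cl <- bert_classify(rescorer, rows[[i]]$peptide)
      label[i] <- cl$label
      rows[[i]]$p_decoy <- cl$probabilities[["decoy"]]
    }
    drop <- label == "decoy"
    n_decoy <- sum(drop)
    rows <- rows[!drop]; label <- label[!drop]
    if (!length(rows)) {
      attr(empty, "diagnostic") <- sprintf(
        "all %d completed hypotheses classified decoy for %s",
        n_decoy, spec$spectrum_id)
      return(empty)
    }
    rows <- lapply(rows, refine_hypothesis, rescorer = rescorer,
                   model = model, target = target, tolerance = tolerance,
                   refine_quantile = refine_quantile)
    for (i in seq_along(rows)) {    # refinement may change the class
      cl <- bert_classify(rescorer, rows[[i]]$peptide)
      label[i] <- cl$label
    }
  }

  conf <- vapply(seq_along(rows), function(i)
    score_hypothesis(rows[[i]]$steps, label[i]), numeric(1))
  prio <- vapply(label, .detect_priority, integer(1))
  ord <- order(prio, -conf)
  out <- data.frame(
    peptide = vapply(rows, `[[`, character(1), "peptide")[ord],
    confidence = conf[ord],
    detectability = label[ord],
    logprob = vapply(rows, `[[`, numeric(1), "lp")[ord],
    mass_delta = vapply(rows, `[[`, numeric(1), "mass_delta")[ord],
    stringsAsFactors = FALSE)
  out$residue_scores <- lapply(rows[ord], function(r) exp(r$res_lp))
  out[!duplicated(out$peptide), , drop = FALSE]
}

# Masked refinement of low-confidence residues: the rescorer's masked-LM
# proposal at a position is accepted only if the substitution keeps the
# peptide mass within tolerance of the precursor and raises the combined
# score (base confidence x (1 - P(decoy))).
refine_hypothesis <- function(row, rescorer, model, target, tolerance,
                              refine_quantile) {
  vocab <- model$config$vocab
  lps <- row$res_lp
  if (length(lps) < 2L || refine_quantile <= 0) return(row)
  thr <- stats::quantile(lps, refine_quantile, names = FALSE)
  positions <- which(lps < thr)
  if (!length(positions)) return(row)
  toks <- tokenize_peptide(row$peptide, vocab)
  cum <- sum(residue_mass(toks, vocab))
  combined <- function(steps, pep) {
    cl <- bert_classify(rescorer, pep)
    exp(mean(steps)) * (1 - cl$probabilities[["decoy"]])
  }
  best_score <- combined(row$steps, row$peptide)
  for (pos in positions) {
    prop <- propose_residues(rescorer, paste(toks, collapse = ""), pos)[[1L]]
    cand_tok <- names(prop)[which.max(prop)]
    if (identical(cand_tok, toks[pos])) next
    new_cum <- cum - residue_mass(toks[pos], vocab) +
      residue_mass(cand_tok, vocab)
    if (abs(target - new_cum) > tolerance) next
    new_toks <- toks; new_toks[pos] <- cand_tok
    new_pep <- paste(new_toks, collapse = "")
    new_steps <- row$steps
    new_steps[pos] <- log(pmax(prop[[cand_tok]], 1e-12))
    sc <- combined(new_steps, new_pep)
    if (sc > best_score) {
      toks <- new_toks; cum <- new_cum
      row$peptide <- new_pep
      row$steps <- new_steps
      row$res_lp[pos] <- new_steps[pos]
      best_score <- sc
    }
  }
  row$lp <- sum(row$steps)
  row
}

#' De novo sequencing of a batch of spectra
#'
#' Runs \code{\link{beam_search}} over a list of spectra and returns the
#' top prediction per spectrum (plus, optionally, lower-ranked
#' hypotheses). Spectra with no completable hypothesis yield a row with
#' an empty peptide so every input is accounted for.
#'
#' @param object a trained \code{denovo_model}
#' @param spectra list of \code{\link{spectrum}} objects
#' @param knapsack optional precomputed \code{knapsack_table}; built to
#'   cover the batch when NULL
#' @param beam_width,tolerance,rescorer,refine_quantile passed to
#'   \code{\link{beam_search}}
#' @param top_n hypotheses kept per spectrum (default 1)
#' @param ... unused
#' @return data.frame: spectrum_id, peptide, residue_scores (list),
#'   confidence, detectability
#' @export
predict.denovo_model <- function(object, spectra, knapsack = NULL,
                                 beam_width = 5L, tolerance = 0.1,
                                 rescorer = NULL, refine_quantile = 0.1,
                                 top_n = 1L, ...) {
  if (inherits(spectra, "spectrum")) spectra <- list(spectra)
  if (is.null(knapsack)) {
    mm <- max(vapply(spectra, function(s)
      s$precursor_neutral_mass, numeric(1))) - MASS_WATER + 1
    knapsack <- build_knapsack(object$config$vocab, max_mass = mm)
  }
  out <- vector("list", length(spectra))
  for (i in seq_along(spectra)) {
    sp <- spectra[[i]]
    bs <- beam_search(sp, object, knapsack, beam_width = beam_width,
                      tolerance = tolerance, rescorer = rescorer,
                      refine_quantile = refine_quantile)
    if (nrow(bs) == 0L) {
      df <- data.frame(spectrum_id = sp$spectrum_id, peptide = "",
                       confidence = NA_real_,
                       detectability = NA_character_,
                       stringsAsFactors = FALSE)
      df$residue_scores <- list(numeric(0))
    } else {
      bs <- utils::head(bs, top_n)
      df <- data.frame(spectrum_id = sp$spectrum_id, peptide = bs$peptide,
                       confidence = bs$confidence,
                       detectability = bs$detectability,
                       stringsAsFactors = FALSE)
      df$residue_scores <- bs$residue_scores
    }
    out[[i]] <- df
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("spectrum_id", "peptide", "residue_scores", "confidence",
          "detectability")]
}
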