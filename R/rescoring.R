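# Peptide-language rescorer: a small BERT-style transformer encoder
# trained from scratch with a masked-residue language-model head plus a
# 3-class detectability head (decoy / highly detectable / potentially
# detectable), together with its training-data construction: decoy
# generation, quantile-based detectability labelling and masking.

#' Generate decoy peptides
#'
#' Decoy construction mirrors standard target-decoy practice:
#' \describe{
#'   \item{shuffle}{permute all residues except the C-terminal one (the
#'     enzymatic terminus is kept)}
#'   \item{shuffle_free}{permute all residues}
#'   \item{shuffle_keep_cleavage}{permute only non-cleavage-site residues;
#'     K/R positions stay fixed}
#'   \item{reverse}{keep the C-terminal residue fixed, reverse the rest}
#' }
#' A decoy identical to its source is re-drawn; sources whose permutation
#' group is trivial (every rearrangement reproduces the source, e.g. "AK"
#' with the cleavage site fixed) are returned unchanged and counted in the
#' \code{n_trivial} attribute so callers can drop them. Non-trivial decoys
#' that collide with any target are removed.
#'
#' @param peptides character vector of target peptides
#' @param method one of \code{"shuffle"}, \code{"reverse"},
#'   \code{"shuffle_keep_cleavage"}, \code{"shuffle_free"}
#' @param max_tries redraws allowed before declaring a source trivial
#' @return character vector of decoys (attribute \code{n_trivial} counts
#'   dropped sources). The residue multiset of every decoy equals its
#'   source's.
#' @export
make_decoys <- function(peptides,
                        method = c("shuffle", "reverse",
                                   "shuffle_keep_cleavage", "shuffle_free"),
                        max_tries = 20L) {
  method <- match.arg(method)
  if (!length(peptides)) stop("no peptides supplied")
  perm_one <- function(pep) {
    ch <- strsplit(pep, "")[[1L]]
    n <- length(ch)
    free <- switch(method,
      shuffle = if (n > 1L) seq_len(n - 1L) else integer(0),
      shuffle_free = seq_len(n),
      shuffle_keep_cleavage = which(!ch %in% c("K", "R")),
      reverse = if (n > 1L) seq_len(n - 1L) else integer(0))
    if (method == "reverse") {
      out <- ch; out[free] <- rev(ch[free])
      return(paste(out, collapse = ""))
    }
    if (length(unique(ch[free])) < 2L) return(pep)  # trivial group
    for (k in seq_len(max_tries)) {
      out <- ch
      out[free] <- sample(ch[free])
      cand <- paste(out, collapse = "")
      if (cand != pep) return(cand)
    }
    pep
  }
  dec <- vapply(peptides, perm_one, character(1), USE.NAMES = FALSE)
  trivial <- dec == peptides
  # non-trivial decoys that collide with a target are dropped; trivial
  # sources (permutation group of size 1) are kept but reported
  keep <- trivial | !(dec %in% peptides)
  structure(dec[keep], n_trivial = sum(trivial))
}

#' Detectability labels from observation frequencies
#'
#' Target peptides whose observation frequency reaches the 75th
#' percentile (3rd quartile) of the group distribution are labelled
#' highly detectable; the remaining targets are potentially detectable.
#' Decoys are always class decoy, regardless of frequency. With
#' all-equal frequencies every peptide crosses the threshold and is
#' labelled highly detectable (degenerate case).
#'
#' @param frequencies named numeric vector (names = peptides) of
#'   observation counts
#' @param decoys optional character vector of decoy peptides to append
#' @return character vector of labels (\code{"high"},
#'   \code{"potential"}, \code{"decoy"}) named by peptide
#' @export
label_detectability <- function(frequencies, decoys = NULL) {
  stopifnot(is.numeric(frequencies), !is.null(names(frequencies)))
  thr <- stats::quantile(frequencies, 0.75, names = FALSE)
  lab <- ifelse(frequencies >= thr, "high", "potential")
  names(lab) <- names(frequencies)
  if (!is.null(decoys))
    lab <- c(lab, stats::setNames(rep("decoy", length(decoys)), decoys))
  lab
}

#' Masking recipe
#' @param select_fraction fraction of residues selected for corruption
#'   (default 0.07)
#' @param substitute_fraction of the selected residues, the fraction
#'   replaced by a random different residue (default 0.5); the remainder
#'   becomes the [MASK] token
#' @return list with the two fractions
#' @export
masking_recipe <- function(select_fraction = 0.07,
                           substitute_fraction = 0.5) {
  stopifnot(select_fraction >= 0, select_fraction <= 1,
            substitute_fraction >= 0, substitute_fraction <= 1)
  list(select_fraction = select_fraction,
       substitute_fraction = substitute_fraction)
}

#' Corrupt a peptide for masked-language-model training
#'
#' Selects \code{ceiling(select_fraction * n)} positions; of these,
#' \code{floor(substitute_fraction * k)} get a random different residue
#' and the rest become the [MASK] token. Restoration targets are
#' recorded at the selected positions only. Uses the current RNG state
#' (seed outside for reproducibility).
#'
#' @param peptide peptide string
#' @param recipe a \code{\link{masking_recipe}}
#' @param vocab a \code{\link{residue_vocab}}
#' @return list: \code{tokens} (corrupted token vector, [MASK] as the
#'   vocabulary mask token), \code{positions} (selected positions),
#'   \code{targets} (original tokens at those positions)
#' @export
apply_masking <- function(peptide, recipe = masking_recipe(), vocab) {
  toks <- tokenize_peptide(peptide, vocab)
  n <- length(toks)
  k <- ceiling(recipe$select_fraction * n)
  if (k == 0L)
    return(list(tokens = toks, positions = integer(0),
                targets = character(0)))
  positions <- sort(sample.int(n, k))
  n_sub <- floor(recipe$substitute_fraction * k)
  sub_pos <- positions[seq_len(n_sub)]
  mask_pos <- setdiff(positions, sub_pos)
  targets <- toks[positions]
  out <- toks
  for (p in sub_pos) {
    alt <- setdiff(vocab$tokens, toks[p])
    out[p] <- sample(alt, 1L)
  }
  out[mask_pos] <- vocab$special[["mask"]]
  list(tokens = out, positions = positions, targets = targets)
}

#' Inverse-frequency class weights
#'
#' Weights proportional to inverse class frequency, normalised to mean 1;
#' rarer classes weigh more.
#' @param counts named numeric vector of class counts
#' @return named numeric weights
#' @export
class_weights <- function(counts) {
  w <- 1 / counts
  w / mean(w)
}

## ---- BERT-style model ----------------------------------------------------

.BERT_CLASSES <- c("decoy", "high", "potential")

bert_init_params <- function(cfg) {
  d <- cfg$d_model
  V <- cfg$vocab$n_special + length(cfg$vocab$tokens)
  set.seed(cfg$seed)
  list(
    emb = matrix(stats::rnorm(V * d, sd = 0.02), V, d),
    pos = matrix(stats::rnorm((cfg$max_len + 1L) * d, sd = 0.02),
                 cfg$max_len + 1L, d),
    enc = lapply(seq_len(cfg$n_layers), function(i)
      nn_enc_layer_init(d, cfg$d_ff, rel_window = 8L)),
    lnf = nn_ln_init(d),
    lm = nn_linear_init(d, V),
    cls = nn_linear_init(d, 3L))
}

#' Rescorer configuration
#'
#' @param vocab a \code{\link{residue_vocab}}
#' @param d_model,n_heads,n_layers,d_ff encoder dimensions (desk-scale
#'   defaults; the architecture contract -- stacked transformer encoders
#'   with a masked-LM head and a 3-class head -- matches the full-scale
#'   model at reduced width/depth)
#' @param max_len maximum peptide length
#' @param seed RNG seed
#' @return object of class \code{bert_config}
#' @export
bert_config <- function(vocab, d_model = 32L, n_heads = 4L, n_layers = 2L,
                        d_ff = 64L, max_len = 40L, seed = 1L) {
  stopifnot(inherits(vocab, "residue_vocab"), d_model %% n_heads == 0L)
  structure(list(vocab = vocab, d_model = as.integer(d_model),
                 n_heads = as.integer(n_heads),
                 n_layers = as.integer(n_layers), d_ff = as.integer(d_ff),
                 max_len = as.integer(max_len), seed = as.integer(seed)),
            class = "bert_config")
}

# forward over one token sequence; row 1 is the [CLS] position (start token)
bert_fwd <- function(params, cfg, ids) {
  ids_in <- c(cfg$vocab$start_id, ids)
  x <- params$emb[ids_in, , drop = FALSE] +
    params$pos[seq_along(ids_in), , drop = FALSE]
  caches <- vector("list", cfg$n_layers)
  for (l in seq_len(cfg$n_layers)) {
    caches[[l]] <- enc_layer_fwd(x, params$enc[[l]], cfg$n_heads)
    x <- caches[[l]]$y
  }
  lnf <- ln_fwd(x, params$lnf)
  list(h = lnf$y, caches = caches, lnf = lnf, ids_in = ids_in)
}

# joint masked-LM + classification loss and gradient for one sample
bert_sample_grad <- function(params, cfg, ids_corrupt, lm_positions,
                             lm_targets, class_id, class_weight) {
  fw <- bert_fwd(params, cfg, ids_corrupt)
  h <- fw$h
  k <- nrow(h)
  dh <- matrix(0, k, cfg$d_model)
  g <- list()
  loss <- 0

  # classification reads the mean-pooled hidden states: every position
  # feeds the head directly, so local features (motifs) reach it without
  # having to be routed through one attention hop
  pool <- matrix(colMeans(h), 1L)
  cls <- lin_fwd(pool, params$cls)
  pc <- softmax_rows(cls$y)
  loss <- loss - class_weight * log(pmax(pc[1L, class_id], 1e-300))
  dcls <- pc; dcls[1L, class_id] <- dcls[1L, class_id] - 1
  dcls <- dcls * class_weight
  cb <- lin_bwd(dcls, cls, params$cls)
  g$cls <- cb$g
  dh <- dh + matrix(cb$dx[1L, ], k, cfg$d_model, byrow = TRUE) / k

  if (length(lm_positions)) {
    rows <- lm_positions + 1L   # offset for the CLS row
    lm <- lin_fwd(h[rows, , drop = FALSE], params$lm)
    pl <- softmax_rows(lm$y)
    pick <- cbind(seq_along(rows), lm_targets)
    loss <- loss - sum(log(pmax(pl[pick], 1e-300))) / length(rows)
    dlm <- pl; dlm[pick] <- dlm[pick] - 1
    dlm <- dlm / length(rows)
    lb <- lin_bwd(dlm, lm, params$lm)
    g$lm <- lb$g
    dh[rows, ] <- dh[rows, ] + lb$dx
  } else {
    g$lm <- tree_zero(params$lm)
  }

  lb2 <- ln_bwd(dh, fw$lnf, params$lnf)
  g$lnf <- lb2$g
  dx <- lb2$dx
  g$enc <- vector("list", cfg$n_layers)
  for (l in rev(seq_len(cfg$n_layers))) {
    eb <- enc_layer_bwd(dx, fw$caches[[l]], params$enc[[l]], cfg$n_heads)
    g$enc[[l]] <- eb$g
    dx <- eb$dx
  }
  V <- nrow(params$emb)
  g$emb <- matrix(0, V, cfg$d_model)
  rs <- rowsum(dx, group = fw$ids_in)
  g$emb[as.integer(rownames(rs)), ] <- rs
  g$pos <- matrix(0, nrow(params$pos), cfg$d_model)
  g$pos[seq_along(fw$ids_in), ] <- dx
  g <- g[names(params)]
  list(loss = loss, grads = g)
}

#' Train the peptide rescorer
#'
#' Joint objective: masked-token cross-entropy (restore the original
#' residues at corrupted positions) plus 3-class detectability
#' cross-entropy with class weights proportional to inverse class
#' frequency. Each epoch draws a balanced sample: classes are sampled at
#' equal rates regardless of their corpus frequency (weighted sampling).
#'
#' @param peptides character vector (targets and decoys)
#' @param labels character vector of classes per peptide
#'   (\code{"decoy"}, \code{"high"}, \code{"potential"})
#' @param config a \code{\link{bert_config}}
#' @param recipe a \code{\link{masking_recipe}}
#' @param epochs,batch_size,lr training hyperparameters;
#'   \code{samples_per_epoch} defaults to the corpus size
#' @param samples_per_epoch draws per epoch (balanced over classes)
#' @param balance imbalance correction: \code{"sampling"} (default)
#'   draws classes at balanced rates, after which the effective class
#'   frequencies are equal and the inverse-frequency loss weights
#'   reduce to 1; \code{"weights"} keeps the corpus sampling and
#'   applies inverse-frequency class weights in the loss; \code{"both"}
#'   applies the two corrections simultaneously (which over-corrects:
#'   the majority class is then both down-weighted and down-sampled,
#'   and its decision boundary can fail to form)
#' @param decoy_weight extra multiplicative loss weight on decoy
#'   examples (default 1). Raising it makes the classifier
#'   cost-sensitive: letting a decoy score as a target is penalised
#'   more than the reverse, which is the asymmetry a decoy filter
#'   exists to enforce.
#' @param model optionally a \code{peptide_bert} to continue training
#'   (its config is reused)
#' @param verbose print per-epoch losses
#' @return object of class \code{peptide_bert}
#' @export
train_rescorer <- function(peptides, labels, config,
                           recipe = masking_recipe(), epochs = 5L,
                           batch_size = 16L, lr = 1e-3,
                           samples_per_epoch = length(peptides),
                           balance = c("sampling", "weights", "both"),
                           decoy_weight = 1,
                           model = NULL, verbose = TRUE) {
  balance <- match.arg(balance)
  stopifnot(length(peptides) == length(labels))
  if (!length(peptides)) stop("empty training corpus")
  if (!all(labels %in% .BERT_CLASSES))
    stop("labels must be one of: ", paste(.BERT_CLASSES, collapse = ", "))
  vocab <- config$vocab
  if (max(nchar(peptides)) > config$max_len)
    stop("peptide longer than config max_len")
  counts <- table(factor(labels, levels = .BERT_CLASSES))
  present <- names(counts)[counts > 0]
  cw <- rep(1, 3); names(cw) <- .BERT_CLASSES
  if (balance %in% c("weights", "both"))
    cw[present] <- class_weights(counts[present])
  cw["decoy"] <- cw["decoy"] * decoy_weight
  samp_w <- if (balance %in% c("sampling", "both"))
    1 / as.numeric(counts[labels])   # balanced class draw rates
  else rep(1, length(labels))

  if (is.null(model)) {
    params <- bert_init_params(config)
    opt <- adam_init(params)
    loss_history <- numeric(0)
    set.seed(config$seed + 1L)
  } else {
    params <- model$params
    opt <- model$opt
    config <- model$config
    loss_history <- model$loss_history
  }
  class_ids <- match(labels, .BERT_CLASSES)
  for (ep in seq_len(epochs)) {
    draw <- sample.int(length(peptides), samples_per_epoch, replace = TRUE,
                       prob = samp_w)
    ep_loss <- 0; done <- 0L
    while (done < length(draw)) {
      idx <- draw[(done + 1L):min(done + batch_size, length(draw))]
      done <- done + length(idx)
      acc <- NULL; bl <- 0
      for (i in idx) {
        mk <- apply_masking(peptides[i], recipe, vocab)
        ids_c <- ifelse(mk$tokens == vocab$special[["mask"]],
                        vocab$mask_id,
                        match(mk$tokens, vocab$tokens) + vocab$n_special)
        tids <- match(mk$targets, vocab$tokens) + vocab$n_special
        sg <- bert_sample_grad(params, config, as.integer(ids_c),
                               mk$positions, tids, class_ids[i],
                               cw[labels[i]])
        bl <- bl + sg$loss
        acc <- if (is.null(acc)) sg$grads else tree_add(acc, sg$grads)
      }
      acc <- tree_map(function(x) x / length(idx), acc)
      st <- adam_step(params, acc, opt, lr = lr)
      params <- st$params; opt <- st$state
      ep_loss <- ep_loss + bl
    }
    loss_history <- c(loss_history, ep_loss / length(draw))
    if (verbose)
      message(sprintf("rescorer epoch %d/%d  loss %.4f", ep, epochs,
                      ep_loss / length(draw)))
  }
  structure(list(params = params, config = config, opt = opt,
                 class_weights = cw, loss_history = loss_history,
                 vocab_hash = vocab_hash(vocab)),
            class = "peptide_bert")
}

#' @export
print.peptide_bert <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("peptide_bert: %d encoder layers, d=%d, %d heads (vocab hash %s)\n",
              cfg$n_layers, cfg$d_model, cfg$n_heads,
              substr(x$vocab_hash, 1, 8)))
  if (length(x$loss_history))
    cat(sprintf("  trained: %d epochs, final loss %.4f\n",
                length(x$loss_history), utils::tail(x$loss_history, 1)))
  invisible(x)
}

#' Classify a peptide's detectability
#'
#' @param model a trained \code{peptide_bert}
#' @param peptide peptide string
#' @return list with \code{label} (\code{"decoy"}, \code{"high"} or
#'   \code{"potential"}, the argmax) and \code{probabilities} (named,
#'   sums to 1)
#' @export
bert_classify <- function(model, peptide) {
  cfg <- model$config
  ids <- peptide_to_ids(peptide, cfg$vocab)
  fw <- bert_fwd(model$params, cfg, ids)
  pool <- matrix(colMeans(fw$h), 1L)
  p <- softmax_rows(lin_fwd(pool, model$params$cls)$y)[1L, ]
  names(p) <- .BERT_CLASSES
  list(label = .BERT_CLASSES[which.max(p)], probabilities = p)
}

#' Masked-LM residue proposals
#'
#' Masks the given positions and returns the masked-language-model
#' distribution over residue tokens at each (renormalised over massful
#' residues).
#'
#' @param model a trained \code{peptide_bert}
#' @param peptide peptide string
#' @param positions integer positions to mask (1-based); empty gives an
#'   empty list
#' @return named list (by position) of named probability vectors over
#'   residue tokens
#' @export
propose_residues <- function(model, peptide, positions) {
  if (!length(positions)) return(list())
  cfg <- model$config
  vocab <- cfg$vocab
  ids <- peptide_to_ids(peptide, vocab)
  stopifnot(all(positions >= 1L), all(positions <= length(ids)))
  ids[positions] <- vocab$mask_id
  fw <- bert_fwd(model$params, cfg, ids)
  out <- vector("list", length(positions))
  for (j in seq_along(positions)) {
    logits <- lin_fwd(fw$h[positions[j] + 1L, , drop = FALSE],
                      model$params$lm)$y[1L, ]
    pr <- exp(logits[vocab$residue_ids] - max(logits[vocab$residue_ids]))
    pr <- pr / sum(pr)
    names(pr) <- vocab$tokens
    out[[j]] <- pr
  }
  names(out) <- positions
  out
}
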