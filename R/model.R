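# Sequence-to-sequence transformer translating embedded spectra into
# peptide token sequences. Implemented directly on the blocks in nn.R:
# pre-norm encoder/decoder stacks, teacher-forced cross-entropy training
# with Adam, deterministic under a fixed seed.

#' Model configuration
#'
#' @param vocab a \code{\link{residue_vocab}}
#' @param d_model hidden width (must match the embedding dimension)
#' @param n_heads attention heads (divides d_model)
#' @param n_layers_encoder,n_layers_decoder encoder/decoder depth. The
#'   full-scale architecture uses 10 of each; the desk default is 2,
#'   which trains in minutes on synthetic corpora.
#' @param d_ff feed-forward width
#' @param dropout input-embedding dropout probability (training only)
#' @param peak_dropout probability of dropping each peak row during
#'   training (training-time augmentation: the model must learn to read
#'   whichever fragment ions remain instead of memorising whole-spectrum
#'   patterns; at least two peaks are always kept)
#' @param label_smoothing cross-entropy label smoothing (training only)
#' @param max_len maximum peptide length in residues (default 40)
#' @param max_charge size of the learned precursor-charge table
#' @param direction decoding direction: \code{"NC"} (N- to C-terminus,
#'   default) or \code{"CN"}
#' @param prefix_mass fuse the cumulative decoded residue mass into the
#'   decoder input through the sinusoidal m/z encoder (default TRUE).
#'   Cross-attention can then locate the next fragment ion by comparing
#'   encoded masses directly instead of inferring mass arithmetic from
#'   token identities -- the decisive inductive bias at desk scale.
#' @param mass_bias add learned mass-offset biases to the decoder
#'   cross-attention (default TRUE): attention logits gain a learnable
#'   weight per 0.25 Da bin of (peak m/z - ladder anchor), for both the
#'   prefix-side and complement-side anchors, so heads can spotlight the
#'   fragment ions that discriminate the next residue.
#' @param seed RNG seed; fixed seed gives bitwise-reproducible
#'   initialisation and training
#' @param embedding an \code{\link{embedding_config}} with \code{d ==
#'   d_model}; defaults to the paired sinusoidal layout spanning the
#'   0.001--10000 m/z wavelength range, with scale pairs strided across
#'   the attention heads
#' @return object of class \code{model_config}
#' @export
model_config <- function(vocab, d_model = 64L, n_heads = 4L,
                         n_layers_encoder = 2L, n_layers_decoder = 2L,
                         d_ff = 128L, dropout = 0, peak_dropout = 0,
                         label_smoothing = 0, max_len = 40L,
                         max_charge = 6L, direction = c("NC", "CN"),
                         prefix_mass = TRUE, mass_bias = TRUE, seed = 1L,
                         embedding = embedding_config(d = d_model,
                                                      scheme = "paired",
                                                      scale_stride = n_heads)) {
  direction <- match.arg(direction)
  stopifnot(inherits(vocab, "residue_vocab"),
            d_model %% n_heads == 0L,
            embedding$d == d_model)
  structure(list(vocab = vocab, d_model = as.integer(d_model),
                 n_heads = as.integer(n_heads),
                 n_layers_encoder = as.integer(n_layers_encoder),
                 n_layers_decoder = as.integer(n_layers_decoder),
                 d_ff = as.integer(d_ff), dropout = dropout,
                 peak_dropout = peak_dropout,
                 label_smoothing = label_smoothing,
                 max_len = as.integer(max_len),
                 max_charge = as.integer(max_charge),
                 direction = direction, prefix_mass = isTRUE(prefix_mass),
                 mass_bias = isTRUE(mass_bias),
                 seed = as.integer(seed),
                 embedding = embedding),
            class = "model_config")
}

# mass-offset attention bias: binned offsets between each decoder query's
# ladder anchors (prefix side and complement side) and each peak m/z;
# one learnable weight per bin plus a shared "elsewhere/no-mass" bin.
.MB_LO <- -2
.MB_HI <- 130
.MB_W <- 0.25
.MB_NBINS <- as.integer((.MB_HI - .MB_LO) / .MB_W) + 1L  # + null bin

mass_bias_index <- function(offsets) {
  idx <- floor((offsets - .MB_LO) / .MB_W) + 1L
  idx[!is.finite(offsets) | offsets < .MB_LO | offsets >= .MB_HI] <- .MB_NBINS
  storage.mode(idx) <- "integer"
  idx
}

# token-id helpers: residue ids follow the 4 special tokens
peptide_to_ids <- function(peptide, vocab) {
  toks <- tokenize_peptide(peptide, vocab)
  match(toks, vocab$tokens) + vocab$n_special
}

ids_to_peptide <- function(ids, vocab) {
  paste(vocab$tokens[ids - vocab$n_special], collapse = "")
}

denovo_init_params <- function(cfg) {
  d <- cfg$d_model; V <- cfg$vocab$n_special + length(cfg$vocab$tokens)
  set.seed(cfg$seed)
  list(
    int_W = stats::rnorm(d, sd = 1 / sqrt(d)),
    int_b = numeric(d),
    charge_emb = matrix(stats::rnorm(cfg$max_charge * d, sd = 0.02),
                        cfg$max_charge, d),
    enc = lapply(seq_len(cfg$n_layers_encoder),
                 function(i) nn_enc_layer_init(d, cfg$d_ff,
                                               identity_qk = cfg$prefix_mass)),
    enc_lnf = nn_ln_init(d),
    dec_emb = matrix(stats::rnorm(V * d, sd = 0.02), V, d),
    dec_pos = matrix(stats::rnorm((cfg$max_len + 2L) * d, sd = 0.02),
                     cfg$max_len + 2L, d),
    dec = lapply(seq_len(cfg$n_layers_decoder),
                 function(i) nn_dec_layer_init(
                   d, cfg$d_ff, identity_qk = cfg$prefix_mass,
                   mass_bias_bins = if (isTRUE(cfg$mass_bias)) .MB_NBINS
                                    else 0L)),
    dec_lnf = nn_ln_init(d),
    out = nn_linear_init(d, V))
}

# Encoder input rows for one spectrum: 2 precursor tokens then peak rows.
denovo_encoder_input <- function(params, cfg, spec) {
  mz <- spec$mz; int <- spec$intensity
  if (length(mz) > cfg$embedding$top_k) {
    keep <- sort(order(int, decreasing = TRUE)[seq_len(cfg$embedding$top_k)])
    mz <- mz[keep]; int <- int[keep]
  }
  int_n <- normalize_intensity(int)
  peaks <- encode_mz(mz, cfg$embedding) +
    encode_intensity(int_n, params$int_W, params$int_b)
  charge <- min(spec$precursor_charge, cfg$max_charge)
  prec <- rbind(
    encode_mz(spec$precursor_neutral_mass, cfg$embedding) +
      encode_mz(spec$precursor_mz, cfg$embedding),
    params$charge_emb[charge, , drop = FALSE])
  list(x = rbind(prec, peaks), int_n = int_n, charge = charge, mz = mz)
}

# Full encoder forward; key_mask marks valid (non-padding) rows.
denovo_encode_fwd <- function(params, cfg, x, key_mask = NULL) {
  caches <- vector("list", cfg$n_layers_encoder)
  for (l in seq_len(cfg$n_layers_encoder)) {
    caches[[l]] <- enc_layer_fwd(x, params$enc[[l]], cfg$n_heads,
                                 key_mask = key_mask)
    x <- caches[[l]]$y
  }
  lnf <- ln_fwd(x, params$enc_lnf)
  list(H = lnf$y, caches = caches, lnf = lnf)
}

denovo_decode_fwd <- function(params, cfg, H, ids_in, enc_mask = NULL,
                              drop_mask = NULL, total_mass = NULL,
                              key_mz = NULL) {
  k <- length(ids_in)
  x <- params$dec_emb[ids_in, , drop = FALSE] +
    params$dec_pos[seq_len(k), , drop = FALSE]
  rm <- c(0, cfg$vocab$masses)[pmax(ids_in - cfg$vocab$n_special, 0L) + 1L]
  pm <- cumsum(rm)
  if (isTRUE(cfg$prefix_mass)) {
    # fuse the running decoded mass through the sinusoidal encoder so
    # cross-attention can align the decoder state against fragment peaks
    # (a remaining-mass term was deliberately left out: encoding the
    # complement hands the decoder a per-peptide fingerprint that invites
    # memorisation instead of peak reading)
    x <- x + encode_mz(pm, cfg$embedding)
  }
  mass_idx <- NULL
  if (isTRUE(cfg$mass_bias) && !is.null(key_mz) && !is.null(total_mass)) {
    # ladder anchors for each decoder position: the prefix-side ion and
    # its complement; binned offsets of every peak from both anchors
    if (cfg$direction == "NC") {
      a1 <- pm + MASS_PROTON
      a2 <- total_mass - pm + MASS_WATER + MASS_PROTON
    } else {
      a1 <- pm + MASS_WATER + MASS_PROTON
      a2 <- total_mass - pm + MASS_PROTON
    }
    mass_idx <- list(b = mass_bias_index(outer(-a1, key_mz, `+`)),
                     y = mass_bias_index(outer(-a2, key_mz, `+`)))
  }
  if (!is.null(drop_mask)) x <- x * drop_mask
  caches <- vector("list", cfg$n_layers_decoder)
  for (l in seq_len(cfg$n_layers_decoder)) {
    caches[[l]] <- dec_layer_fwd(x, H, params$dec[[l]], cfg$n_heads,
                                 enc_mask = enc_mask, mass_idx = mass_idx)
    x <- caches[[l]]$y
  }
  lnf <- ln_fwd(x, params$dec_lnf)
  out <- lin_fwd(lnf$y, params$out)
  list(logits = out$y, caches = caches, lnf = lnf, out = out, ids_in = ids_in)
}

# teacher-forced loss + full gradient for one (spectrum, peptide) sample
denovo_sample_grad <- function(params, cfg, spec, target_ids) {
  vocab <- cfg$vocab
  ein <- denovo_encoder_input(params, cfg, spec)
  ids_in <- c(vocab$start_id, target_ids)
  targets <- c(target_ids, vocab$end_id)
  # peak-dropout augmentation: drop whole peak rows (training only)
  if (cfg$peak_dropout > 0 && nrow(ein$x) > 4L) {
    n_peaks <- nrow(ein$x) - 2L
    keep <- stats::runif(n_peaks) >= cfg$peak_dropout
    if (sum(keep) < 2L) keep[sample.int(n_peaks, 2L)] <- TRUE
    ein$x <- ein$x[c(TRUE, TRUE, keep), , drop = FALSE]
    ein$int_n <- ein$int_n[keep]
    ein$mz <- ein$mz[keep]
  }
  # inverted dropout on the input embeddings (training only)
  me <- md <- NULL
  xe <- ein$x
  if (cfg$dropout > 0) {
    p <- cfg$dropout
    me <- matrix(stats::rbinom(length(xe), 1L, 1 - p), nrow(xe)) / (1 - p)
    md <- matrix(stats::rbinom(length(ids_in) * cfg$d_model, 1L, 1 - p),
                 length(ids_in)) / (1 - p)
    xe <- xe * me
  }
  enc <- denovo_encode_fwd(params, cfg, xe)
  dec <- denovo_decode_fwd(params, cfg, enc$H, ids_in, drop_mask = md,
                           total_mass = spec$precursor_neutral_mass -
                             MASS_WATER,
                           key_mz = c(NA, NA, ein$mz))
  k <- length(targets)
  P <- softmax_rows(dec$logits)
  # token-summed loss; the training loop normalises by tokens per batch,
  # so long peptides carry their full per-token weight
  loss <- -sum(log(pmax(P[cbind(seq_len(k), targets)], 1e-300)))
  dlogits <- P
  eps_ls <- cfg$label_smoothing
  if (eps_ls > 0) {
    V <- ncol(P)
    dlogits <- dlogits - eps_ls / V
    dlogits[cbind(seq_len(k), targets)] <-
      dlogits[cbind(seq_len(k), targets)] - (1 - eps_ls)
  } else {
    dlogits[cbind(seq_len(k), targets)] <-
      dlogits[cbind(seq_len(k), targets)] - 1
  }

  g <- list()
  ob <- lin_bwd(dlogits, dec$out, params$out)
  g$out <- ob$g
  lb <- ln_bwd(ob$dx, dec$lnf, params$dec_lnf)
  g$dec_lnf <- lb$g
  dx <- lb$dx
  dH <- matrix(0, nrow(enc$H), cfg$d_model)
  g$dec <- vector("list", cfg$n_layers_decoder)
  for (l in rev(seq_len(cfg$n_layers_decoder))) {
    db <- dec_layer_bwd(dx, dec$caches[[l]], params$dec[[l]], cfg$n_heads)
    g$dec[[l]] <- db$g
    dx <- db$dx
    dH <- dH + db$dH
  }
  # decoder embeddings
  if (!is.null(md)) dx <- dx * md
  V <- nrow(params$dec_emb)
  g$dec_emb <- matrix(0, V, cfg$d_model)
  rs <- rowsum(dx, group = ids_in)
  g$dec_emb[as.integer(rownames(rs)), ] <- rs
  g$dec_pos <- matrix(0, nrow(params$dec_pos), cfg$d_model)
  g$dec_pos[seq_along(ids_in), ] <- dx

  # encoder stack backward
  lb2 <- ln_bwd(dH, enc$lnf, params$enc_lnf)
  g$enc_lnf <- lb2$g
  dxe <- lb2$dx
  g$enc <- vector("list", cfg$n_layers_encoder)
  for (l in rev(seq_len(cfg$n_layers_encoder))) {
    eb <- enc_layer_bwd(dxe, enc$caches[[l]], params$enc[[l]], cfg$n_heads)
    g$enc[[l]] <- eb$g
    dxe <- eb$dx
  }
  # encoder input rows: [1] mass+mz (fixed), [2] charge emb, [3..] peaks
  if (!is.null(me)) dxe <- dxe * me
  g$charge_emb <- matrix(0, nrow(params$charge_emb), cfg$d_model)
  g$charge_emb[ein$charge, ] <- dxe[2L, ]
  peak_rows <- dxe[-(1:2), , drop = FALSE]
  g$int_W <- as.numeric(crossprod(peak_rows, ein$int_n))
  g$int_b <- colSums(peak_rows)

  # order fields to mirror params
  g <- g[names(params)]
  list(loss = loss, grads = g, ntok = k)
}

#' Train the spectrum-to-peptide model
#'
#' Teacher-forced next-token cross-entropy with Adam, deterministic under
#' the configuration seed. Every annotated peptide must tokenize under the
#' model vocabulary; a mismatch refuses to train.
#'
#' @param data list of annotated \code{\link{spectrum}} objects (the
#'   \code{peptide} field holds the ground truth)
#' @param config a \code{\link{model_config}}
#' @param epochs training epochs
#' @param batch_size minibatch size (gradients averaged per batch)
#' @param lr Adam learning rate
#' @param model optionally, a \code{denovo_model} to continue training
#'   (e.g. loaded from a checkpoint); its config is reused
#' @param verbose print per-epoch losses
#' @return object of class \code{denovo_model} with fields \code{params},
#'   \code{config}, \code{loss_history}, \code{vocab_hash}
#' @export
train_denovo <- function(data, config, epochs = 10L, batch_size = 16L,
                         lr = 1e-3, model = NULL, verbose = TRUE) {
  if (length(data) == 0L) stop("empty training dataset")
  peptides <- vapply(data, function(s) s$peptide, character(1))
  if (anyNA(peptides)) stop("all training spectra must carry a peptide annotation")
  vocab <- config$vocab
  ok <- vapply(peptides, function(p)
    tryCatch({tokenize_peptide(p, vocab); TRUE}, error = function(e) FALSE),
    logical(1))
  if (!all(ok))
    stop("vocabulary mismatch: peptide(s) with tokens outside the model ",
         "vocabulary, e.g. ", peptides[which(!ok)[1L]])
  if (max(nchar(peptides)) > config$max_len)
    stop("peptide longer than config max_len")

  targets <- lapply(peptides, function(p) {
    ids <- peptide_to_ids(p, vocab)
    if (config$direction == "CN") rev(ids) else ids
  })
  if (is.null(model)) {
    params <- denovo_init_params(config)
    opt <- adam_init(params)
    loss_history <- numeric(0)
  } else {
    params <- model$params
    opt <- model$opt
    config <- model$config
    loss_history <- model$loss_history
  }
  n <- length(data)
  set.seed(config$seed + 1L)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0
    ep_tok <- 0L
    done <- 0L
    while (done < n) {
      idx <- ord[(done + 1L):min(done + batch_size, n)]
      done <- done + length(idx)
      acc <- NULL
      bl <- 0
      btok <- 0L
      for (i in idx) {
        sg <- denovo_sample_grad(params, config, data[[i]], targets[[i]])
        bl <- bl + sg$loss
        btok <- btok + sg$ntok
        acc <- if (is.null(acc)) sg$grads else tree_add(acc, sg$grads)
      }
      acc <- tree_map(function(x) x / btok, acc)
      st <- adam_step(params, acc, opt, lr = lr)
      params <- st$params
      opt <- st$state
      ep_loss <- ep_loss + bl
      ep_tok <- ep_tok + btok
    }
    loss_history <- c(loss_history, ep_loss / ep_tok)
    if (verbose)
      message(sprintf("epoch %d/%d  loss %.4f", ep, epochs,
                      ep_loss / ep_tok))
  }
  structure(list(params = params, config = config, opt = opt,
                 loss_history = loss_history,
                 vocab_hash = vocab_hash(vocab)),
            class = "denovo_model")
}

#' @export
print.denovo_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0("denovo_model: %d+%d transformer layers, d=%d, %d heads\n",
                     "  vocabulary: %d residues (hash %s)\n"),
              cfg$n_layers_encoder, cfg$n_layers_decoder, cfg$d_model,
              cfg$n_heads, length(cfg$vocab$tokens),
              substr(x$vocab_hash, 1, 8)))
  if (length(x$loss_history))
    cat(sprintf("  trained: %d epochs, final loss %.4f\n",
                length(x$loss_history), utils::tail(x$loss_history, 1)))
  invisible(x)
}

#' Encode a spectrum into hidden representations
#'
#' Runs the encoder stack: one hidden vector per input row (2 precursor
#' tokens + one row per retained peak). Optional trailing padding rows are
#' masked out of attention and do not affect the valid rows.
#'
#' @param model a \code{denovo_model}
#' @param spec a \code{\link{spectrum}}
#' @param pad_rows number of zero padding rows to append (masked)
#' @return matrix of hidden states (rows: precursor tokens, peaks,
#'   padding), with attribute \code{key_mask}
#' @export
encode_spectrum <- function(model, spec, pad_rows = 0L) {
  cfg <- model$config
  ein <- denovo_encoder_input(model$params, cfg, spec)
  x <- ein$x
  key_mask <- rep(TRUE, nrow(x))
  key_mz <- c(NA, NA, ein$mz)
  if (pad_rows > 0L) {
    x <- rbind(x, matrix(0, pad_rows, ncol(x)))
    key_mask <- c(key_mask, rep(FALSE, pad_rows))
    key_mz <- c(key_mz, rep(NA_real_, pad_rows))
  }
  enc <- denovo_encode_fwd(model$params, cfg, x, key_mask = key_mask)
  structure(enc$H, key_mask = key_mask, key_mz = key_mz,
            precursor_residue_mass = spec$precursor_neutral_mass - MASS_WATER)
}

#' One autoregressive decoding step
#'
#' Given the encoder hidden states and a (possibly empty) prefix of
#' residue token ids, returns the log-probability distribution over the
#' full vocabulary for the next token (causally masked).
#'
#' @param model a \code{denovo_model}
#' @param H hidden states from \code{\link{encode_spectrum}}
#' @param prefix_ids integer vector of residue token ids decoded so far
#' @return numeric vector of log-probabilities (sums to 1 on the
#'   probability scale)
#' @export
decode_step <- function(model, H, prefix_ids = integer(0)) {
  cfg <- model$config
  vocab <- cfg$vocab
  ids_in <- c(vocab$start_id, prefix_ids)
  enc_mask <- attr(H, "key_mask")
  dec <- denovo_decode_fwd(model$params, cfg, H, ids_in, enc_mask = enc_mask,
                           total_mass = attr(H, "precursor_residue_mass"),
                           key_mz = attr(H, "key_mz"))
  logit <- dec$logits[length(ids_in), ]
  logit - log(sum(exp(logit - max(logit)))) - max(logit)
}

#' Teacher-forced perplexity on annotated spectra
#'
#' @param model a \code{denovo_model}
#' @param data list of annotated spectra
#' @return exp of the mean per-token cross-entropy
#' @export
perplexity <- function(model, data) {
  cfg <- model$config
  vocab <- cfg$vocab
  tot <- 0; ntok <- 0L
  for (s in data) {
    ids <- peptide_to_ids(s$peptide, vocab)
    if (cfg$direction == "CN") ids <- rev(ids)
    ein <- denovo_encoder_input(model$params, cfg, s)
    enc <- denovo_encode_fwd(model$params, cfg, ein$x)
    dec <- denovo_decode_fwd(model$params, cfg, enc$H,
                             c(vocab$start_id, ids),
                             total_mass = s$precursor_neutral_mass -
                               MASS_WATER,
                             key_mz = c(NA, NA, ein$mz))
    targets <- c(ids, vocab$end_id)
    P <- softmax_rows(dec$logits)
    tot <- tot - sum(log(pmax(P[cbind(seq_along(targets), targets)], 1e-300)))
    ntok <- ntok + length(targets)
  }
  exp(tot / ntok)
}

#' Save / load a model checkpoint
#'
#' Checkpoints carry the weights, the full configuration (model +
#' embedding), the optimiser state and the vocabulary hash, so training
#' can resume and eval outputs reproduce exactly.
#'
#' @param model a \code{denovo_model} or \code{peptide_bert} object
#' @param path checkpoint file (RDS)
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @return the restored model object
#' @export
load_checkpoint <- function(path) readRDS(path)
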