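# Compact transformer building blocks with explicit forward/backward passes
# and an Adam optimiser. Parameters and gradients are parallel nested lists
# of plain matrices/vectors; every block returns its output plus the cache
# its backward pass needs. Sized for desk-scale models (d_model <= 128),
# where R's BLAS-backed %*% is fast enough and no framework is required.

## ---- parameter-tree utilities -------------------------------------------

tree_map2 <- function(f, a, b) {
  if (!is.list(a)) return(f(a, b))
  for (i in seq_along(a)) a[[i]] <- tree_map2(f, a[[i]], b[[i]])
  a
}

tree_map <- function(f, a) {
  if (!is.list(a)) return(f(a))
  for (i in seq_along(a)) a[[i]] <- tree_map(f, a[[i]])
  a
}

tree_add <- function(a, b) tree_map2(`+`, a, b)

tree_zero <- function(a) tree_map(function(x) x * 0, a)

tree_sumsq <- function(a) {
  if (is.list(a)) sum(vapply(a, tree_sumsq, numeric(1))) else sum(a * a)
}

## ---- initialisers --------------------------------------------------------

nn_linear_init <- function(d_in, d_out) {
  list(W = matrix(stats::rnorm(d_in * d_out, sd = 1 / sqrt(d_in)), d_in, d_out),
       b = numeric(d_out))
}

nn_ln_init <- function(d) list(g = rep(1, d), b = numeric(d))

# identity_qk seeds Wq/Wk near the identity: with sinusoidal mass
# encodings on both sides, Q.K then starts as sum_k cos((m_q - m_k)/s_k),
# a kernel peaked where the two masses agree -- attention begins life as a
# mass-matching peak locator instead of having to discover the sin/cos
# channel pairing from scratch.
# rel_window > 0 adds a learned relative-position bias to the attention
# logits (shared across heads, clipped at +/- rel_window): heads can then
# attend "one position left" regardless of absolute position, which is
# what local-order features (n-grams/motifs) need.
nn_attn_init <- function(d, identity_qk = FALSE, rel_window = 0L) {
  sd <- 1 / sqrt(d)
  qk <- function() {
    if (identity_qk)
      diag(d) + matrix(stats::rnorm(d * d, sd = sd / 4), d, d)
    else matrix(stats::rnorm(d * d, sd = sd), d, d)
  }
  p <- list(Wq = qk(), Wk = qk(),
            Wv = matrix(stats::rnorm(d * d, sd = sd), d, d),
            Wo = matrix(stats::rnorm(d * d, sd = sd), d, d))
  if (rel_window > 0L) p$rel <- numeric(2L * rel_window + 1L)
  p
}

nn_ffn_init <- function(d, d_ff) list(l1 = nn_linear_init(d, d_ff),
                                      l2 = nn_linear_init(d_ff, d))

nn_enc_layer_init <- function(d, d_ff, identity_qk = FALSE,
                              rel_window = 0L) {
  list(ln1 = nn_ln_init(d),
       attn = nn_attn_init(d, identity_qk, rel_window),
       ln2 = nn_ln_init(d), ffn = nn_ffn_init(d, d_ff))
}

nn_dec_layer_init <- function(d, d_ff, identity_qk = FALSE,
                              mass_bias_bins = 0L) {
  cross <- nn_attn_init(d, identity_qk)
  if (mass_bias_bins > 0L)
    cross$ebias <- list(b = numeric(mass_bias_bins),
                        y = numeric(mass_bias_bins))
  list(ln1 = nn_ln_init(d), self = nn_attn_init(d),
       ln2 = nn_ln_init(d), cross = cross,
       ln3 = nn_ln_init(d), ffn = nn_ffn_init(d, d_ff))
}

## ---- primitive forward/backward -----------------------------------------

.bcast_rows <- function(v, n) matrix(v, n, length(v), byrow = TRUE)

lin_fwd <- function(x, p) {
  list(y = x %*% p$W + .bcast_rows(p$b, nrow(x)), x = x)
}

lin_bwd <- function(dy, cache, p) {
  list(dx = tcrossprod(dy, p$W),
       g = list(W = crossprod(cache$x, dy), b = colSums(dy)))
}

ln_fwd <- function(x, p, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  inv <- 1 / sqrt(rowMeans(xc * xc) + eps)
  xh <- xc * inv
  list(y = xh * .bcast_rows(p$g, nrow(x)) + .bcast_rows(p$b, nrow(x)),
       xh = xh, inv = inv)
}

ln_bwd <- function(dy, cache, p) {
  xh <- cache$xh
  n <- nrow(dy)
  dg <- colSums(dy * xh)
  db <- colSums(dy)
  dxh <- dy * .bcast_rows(p$g, n)
  dx <- cache$inv * (dxh - rowMeans(dxh) - xh * rowMeans(dxh * xh))
  list(dx = dx, g = list(g = dg, b = db))
}

softmax_rows <- function(s) {
  # a single global shift is numerically sufficient here: logit spreads
  # are far below the double-precision exp range
  e <- exp(s - max(s))   # -Inf mask entries never dominate the max
  e / rowSums(e)
}

# multi-head attention; key_mask: logical over kv rows (FALSE = padding,
# excluded from attention); causal masks future query>key positions
# (self-attention only, where nrow(xq) == nrow(xkv)).
# extra_bias_idx: named list of integer matrices (nq x nk) indexing the
# learned bias tables in p$ebias (same names); used for mass-offset
# attention biases where the index encodes a binned physical offset
# between query anchor and key.
mha_fwd <- function(xq, xkv, p, n_heads, causal = FALSE, key_mask = NULL,
                    extra_bias_idx = NULL) {
  Q <- xq %*% p$Wq; K <- xkv %*% p$Wk; V <- xkv %*% p$Wv
  d <- ncol(Q); dh <- d %/% n_heads; sc <- 1 / sqrt(dh)
  nq <- nrow(xq); nk <- nrow(xkv)
  off_idx <- NULL
  if (!is.null(p$rel)) {
    w <- (length(p$rel) - 1L) %/% 2L
    off <- pmin(pmax(outer(seq_len(nk), seq_len(nq), `-`), -w), w)
    off_idx <- t(off) + w + 1L   # nq x nk matrix of bias indices
  }
  ebias <- NULL
  if (!is.null(extra_bias_idx) && !is.null(p$ebias)) {
    ebias <- matrix(0, nq, nk)
    for (nm in names(extra_bias_idx))
      ebias <- ebias + p$ebias[[nm]][extra_bias_idx[[nm]]]
  }
  O <- matrix(0, nq, d)
  A <- vector("list", n_heads)
  for (h in seq_len(n_heads)) {
    idx <- ((h - 1L) * dh + 1L):(h * dh)
    S <- tcrossprod(Q[, idx, drop = FALSE], K[, idx, drop = FALSE]) * sc
    if (!is.null(off_idx)) S <- S + p$rel[off_idx]
    if (!is.null(ebias)) S <- S + ebias
    if (causal && nq > 1L) S[upper.tri(S)] <- -Inf
    if (!is.null(key_mask) && !all(key_mask))
      S[, !key_mask] <- -Inf
    A[[h]] <- softmax_rows(S)
    O[, idx] <- A[[h]] %*% V[, idx, drop = FALSE]
  }
  list(y = O %*% p$Wo, Q = Q, K = K, V = V, A = A, O = O,
       xq = xq, xkv = xkv, n_heads = n_heads, sc = sc, off_idx = off_idx,
       extra_bias_idx = extra_bias_idx)
}

mha_bwd <- function(dy, cache, p) {
  nh <- cache$n_heads
  d <- ncol(cache$Q); dh <- d %/% nh; sc <- cache$sc
  dWo <- crossprod(cache$O, dy)
  dO <- tcrossprod(dy, p$Wo)
  dQ <- matrix(0, nrow(cache$Q), d)
  dK <- matrix(0, nrow(cache$K), d)
  dV <- matrix(0, nrow(cache$V), d)
  need_ds_sum <- !is.null(p$rel) ||
    (!is.null(cache$extra_bias_idx) && !is.null(p$ebias))
  dS_sum <- NULL
  for (h in seq_len(nh)) {
    idx <- ((h - 1L) * dh + 1L):(h * dh)
    Ah <- cache$A[[h]]
    dOh <- dO[, idx, drop = FALSE]
    Vh <- cache$V[, idx, drop = FALSE]
    dA <- tcrossprod(dOh, Vh)
    dV[, idx] <- crossprod(Ah, dOh)
    dS <- Ah * (dA - rowSums(Ah * dA))
    if (need_ds_sum)
      dS_sum <- if (is.null(dS_sum)) dS else dS_sum + dS
    dQ[, idx] <- dS %*% cache$K[, idx, drop = FALSE] * sc
    dK[, idx] <- crossprod(dS, cache$Q[, idx, drop = FALSE]) * sc
  }
  g <- list(Wq = crossprod(cache$xq, dQ),
            Wk = crossprod(cache$xkv, dK),
            Wv = crossprod(cache$xkv, dV),
            Wo = dWo)
  if (!is.null(p$rel)) {
    drel <- numeric(length(p$rel))
    rs <- rowsum(as.vector(dS_sum), as.vector(cache$off_idx))
    drel[as.integer(rownames(rs))] <- rs
    g$rel <- drel
  }
  if (!is.null(cache$extra_bias_idx) && !is.null(p$ebias)) {
    g$ebias <- lapply(names(p$ebias), function(nm) {
      w <- numeric(length(p$ebias[[nm]]))
      rs <- rowsum(as.vector(dS_sum),
                   as.vector(cache$extra_bias_idx[[nm]]))
      w[as.integer(rownames(rs))] <- rs
      w
    })
    names(g$ebias) <- names(p$ebias)
  }
  list(dxq = tcrossprod(dQ, p$Wq),
       dxkv = tcrossprod(dK, p$Wk) + tcrossprod(dV, p$Wv),
       g = g)
}

ffn_fwd <- function(x, p) {
  l1 <- lin_fwd(x, p$l1)
  a <- pmax(l1$y, 0)
  l2 <- lin_fwd(a, p$l2)
  list(y = l2$y, l1 = l1, mask = l1$y > 0, l2 = l2)
}

ffn_bwd <- function(dy, cache, p) {
  b2 <- lin_bwd(dy, cache$l2, p$l2)
  da <- b2$dx * cache$mask
  b1 <- lin_bwd(da, cache$l1, p$l1)
  list(dx = b1$dx, g = list(l1 = b1$g, l2 = b2$g))
}

## ---- transformer layers --------------------------------------------------

enc_layer_fwd <- function(x, p, n_heads, key_mask = NULL) {
  n1 <- ln_fwd(x, p$ln1)
  at <- mha_fwd(n1$y, n1$y, p$attn, n_heads, key_mask = key_mask)
  x1 <- x + at$y
  n2 <- ln_fwd(x1, p$ln2)
  ff <- ffn_fwd(n2$y, p$ffn)
  list(y = x1 + ff$y, n1 = n1, at = at, n2 = n2, ff = ff)
}

enc_layer_bwd <- function(dy, cache, p, n_heads) {
  fb <- ffn_bwd(dy, cache$ff, p$ffn)
  nb2 <- ln_bwd(fb$dx, cache$n2, p$ln2)
  dx1 <- dy + nb2$dx
  ab <- mha_bwd(dx1, cache$at, p$attn)
  nb1 <- ln_bwd(ab$dxq + ab$dxkv, cache$n1, p$ln1)
  list(dx = dx1 + nb1$dx,
       g = list(ln1 = nb1$g, attn = ab$g, ln2 = nb2$g, ffn = fb$g))
}

dec_layer_fwd <- function(x, H, p, n_heads, enc_mask = NULL,
                          mass_idx = NULL) {
  n1 <- ln_fwd(x, p$ln1)
  sa <- mha_fwd(n1$y, n1$y, p$self, n_heads, causal = TRUE)
  x1 <- x + sa$y
  n2 <- ln_fwd(x1, p$ln2)
  ca <- mha_fwd(n2$y, H, p$cross, n_heads, key_mask = enc_mask,
                extra_bias_idx = mass_idx)
  x2 <- x1 + ca$y
  n3 <- ln_fwd(x2, p$ln3)
  ff <- ffn_fwd(n3$y, p$ffn)
  list(y = x2 + ff$y, n1 = n1, sa = sa, n2 = n2, ca = ca, n3 = n3, ff = ff)
}

dec_layer_bwd <- function(dy, cache, p, n_heads) {
  fb <- ffn_bwd(dy, cache$ff, p$ffn)
  nb3 <- ln_bwd(fb$dx, cache$n3, p$ln3)
  dx2 <- dy + nb3$dx
  cb <- mha_bwd(dx2, cache$ca, p$cross)
  nb2 <- ln_bwd(cb$dxq, cache$n2, p$ln2)
  dx1 <- dx2 + nb2$dx
  sb <- mha_bwd(dx1, cache$sa, p$self)
  nb1 <- ln_bwd(sb$dxq + sb$dxkv, cache$n1, p$ln1)
  list(dx = dx1 + nb1$dx, dH = cb$dxkv,
       g = list(ln1 = nb1$g, self = sb$g, ln2 = nb2$g, cross = cb$g,
                ln3 = nb3$g, ffn = fb$g))
}

## ---- optimiser -----------------------------------------------------------

adam_init <- function(params) list(m = tree_zero(params), v = tree_zero(params),
                                   t = 0L)

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8, clip = 1.0) {
  if (is.finite(clip)) {
    gn <- sqrt(tree_sumsq(grads))
    if (gn > clip) grads <- tree_map(function(g) g * (clip / gn), grads)
  }
  state$t <- state$t + 1L
  state$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g,
                       state$m, grads)
  state$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g * g,
                       state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  params <- tree_map2(function(p, mv) p - lr * mv,
                      params,
                      tree_map2(function(m, v) (m / bc1) / (sqrt(v / bc2) + eps),
                                state$m, state$v))
  list(params = params, state = state)
}
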