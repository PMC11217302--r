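# The transformer blocks carry hand-written backward passes; these tests
# pin them against central finite differences on small random instances.

fd_check <- function(loss_fn, grad, param, eps = 1e-5, n = 6L, tol = 1e-5) {
  set.seed(99)
  idx <- sample(length(param), min(n, length(param)))
  for (k in idx) {
    pp <- param; pp[k] <- pp[k] + eps
    pm <- param; pm[k] <- pm[k] - eps
    num <- (loss_fn(pp) - loss_fn(pm)) / (2 * eps)
    expect_equal(grad[k], num, tolerance = tol)
  }
}

test_that("layer-norm backward matches finite differences", {
  set.seed(1)
  x <- matrix(rnorm(5 * 8), 5, 8)
  p <- list(g = runif(8, 0.5, 1.5), b = rnorm(8))
  w <- matrix(rnorm(5 * 8), 5, 8)  # random linear functional of output
  loss_x <- function(xv) sum(w * tandemnovo:::ln_fwd(matrix(xv, 5, 8), p)$y)
  fw <- tandemnovo:::ln_fwd(x, p)
  bk <- tandemnovo:::ln_bwd(w, fw, p)
  fd_check(loss_x, bk$dx, as.numeric(x))
  loss_g <- function(gv) sum(w * tandemnovo:::ln_fwd(x, list(g = gv, b = p$b))$y)
  fd_check(loss_g, bk$g$g, p$g)
})

test_that("multi-head attention backward matches finite differences", {
  set.seed(2)
  d <- 8; nq <- 4; nk <- 6
  xq <- matrix(rnorm(nq * d), nq, d)
  xkv <- matrix(rnorm(nk * d), nk, d)
  p <- tandemnovo:::nn_attn_init(d)
  w <- matrix(rnorm(nq * d), nq, d)
  fw <- tandemnovo:::mha_fwd(xq, xkv, p, n_heads = 2)
  bk <- tandemnovo:::mha_bwd(w, fw, p)
  loss_wq <- function(v) {
    p2 <- p; p2$Wq <- matrix(v, d, d)
    sum(w * tandemnovo:::mha_fwd(xq, xkv, p2, n_heads = 2)$y)
  }
  fd_check(loss_wq, as.numeric(bk$g$Wq), as.numeric(p$Wq))
  loss_xkv <- function(v)
    sum(w * tandemnovo:::mha_fwd(xq, matrix(v, nk, d), p, n_heads = 2)$y)
  fd_check(loss_xkv, as.numeric(bk$dxkv), as.numeric(xkv))
})

test_that("causal masking zeroes attention to future positions", {
  set.seed(3)
  d <- 8; n <- 5
  x <- matrix(rnorm(n * d), n, d)
  p <- tandemnovo:::nn_attn_init(d)
  fw <- tandemnovo:::mha_fwd(x, x, p, n_heads = 2, causal = TRUE)
  for (h in 1:2) {
    A <- fw$A[[h]]
    expect_true(all(A[upper.tri(A)] == 0))
    expect_equal(rowSums(A), rep(1, n), tolerance = 1e-12)
  }
  # key mask: masked rows get zero weight
  fw2 <- tandemnovo:::mha_fwd(x, x, p, n_heads = 2,
                              key_mask = c(TRUE, TRUE, TRUE, FALSE, FALSE))
  for (h in 1:2) expect_true(all(fw2$A[[h]][, 4:5] == 0))
})

test_that("full sample gradient matches finite differences end to end", {
  v <- residue_vocab(residues = c(G = 57.021464, A = 71.037114,
                                  L = 113.084064), phospho = FALSE)
  cfg <- model_config(v, d_model = 8L, n_heads = 2L, d_ff = 12L,
                      max_len = 8L, seed = 4L)
  set.seed(5)
  pep <- "GAL"
  fr <- fragment_ions(pep, 1, c("b", "y"), v)
  sp <- spectrum("s", fr$mz, runif(nrow(fr), 1, 10),
                 neutral_to_mz(peptide_mass(pep, v), 2), 2)
  params <- tandemnovo:::denovo_init_params(cfg)
  tids <- tandemnovo:::peptide_to_ids(pep, v)
  base <- tandemnovo:::denovo_sample_grad(params, cfg, sp, tids)
  eps <- 1e-5
  # one coordinate from several structurally different leaves
  probes <- list(
    list(get = function(p) p$out$W[2, 3],
         set = function(p, x) {p$out$W[2, 3] <- x; p},
         g = base$grads$out$W[2, 3]),
    list(get = function(p) p$dec[[1]]$cross$Wk[1, 2],
         set = function(p, x) {p$dec[[1]]$cross$Wk[1, 2] <- x; p},
         g = base$grads$dec[[1]]$cross$Wk[1, 2]),
    list(get = function(p) p$enc[[2]]$ffn$l1$W[3, 4],
         set = function(p, x) {p$enc[[2]]$ffn$l1$W[3, 4] <- x; p},
         g = base$grads$enc[[2]]$ffn$l1$W[3, 4]),
    list(get = function(p) p$int_W[2],
         set = function(p, x) {p$int_W[2] <- x; p},
         g = base$grads$int_W[2]),
    list(get = function(p) p$dec_emb[6, 1],
         set = function(p, x) {p$dec_emb[6, 1] <- x; p},
         g = base$grads$dec_emb[6, 1]))
  for (pr in probes) {
    x0 <- pr$get(params)
    lp <- tandemnovo:::denovo_sample_grad(pr$set(params, x0 + eps), cfg,
                                          sp, tids)$loss
    lm <- tandemnovo:::denovo_sample_grad(pr$set(params, x0 - eps), cfg,
                                          sp, tids)$loss
    expect_equal(pr$g, (lp - lm) / (2 * eps), tolerance = 1e-4)
  }
})

test_that("adam step moves parameters against the gradient and clips", {
  p <- list(a = matrix(1, 2, 2), b = rep(0, 3))
  g <- list(a = matrix(10, 2, 2), b = c(-10, 0, 10))
  st <- tandemnovo:::adam_init(p)
  out <- tandemnovo:::adam_step(p, g, st, lr = 0.1)
  expect_true(all(out$params$a < 1))
  expect_gt(out$params$b[1], 0)
  expect_equal(out$params$b[2], 0)
})

test_that("rescorer joint-loss gradients match finite differences", {
  v <- residue_vocab(phospho = FALSE)
  bc <- bert_config(v, d_model = 16L, n_heads = 2L, n_layers = 2L,
                    d_ff = 24L, max_len = 20L, seed = 3L)
  params <- tandemnovo:::bert_init_params(bc)
  ids <- tandemnovo:::peptide_to_ids("GAVSLTPK", v)
  idc <- ids; idc[3] <- v$mask_id
  g <- tandemnovo:::bert_sample_grad(params, bc, idc, c(3L, 5L),
                                     ids[c(3, 5)], 2L, 1.5)
  eps <- 1e-5
  probes <- list(
    list(get = function(p) p$cls$W[5, 2],
         set = function(p, x) {p$cls$W[5, 2] <- x; p},
         g = g$grads$cls$W[5, 2]),
    list(get = function(p) p$lm$W[3, 7],
         set = function(p, x) {p$lm$W[3, 7] <- x; p},
         g = g$grads$lm$W[3, 7]),
    list(get = function(p) p$enc[[1]]$attn$rel[9],
         set = function(p, x) {p$enc[[1]]$attn$rel[9] <- x; p},
         g = g$grads$enc[[1]]$attn$rel[9]),
    list(get = function(p) p$emb[ids[1], 2],
         set = function(p, x) {p$emb[ids[1], 2] <- x; p},
         g = g$grads$emb[ids[1], 2]))
  for (pr in probes) {
    x0 <- pr$get(params)
    lp <- tandemnovo:::bert_sample_grad(pr$set(params, x0 + eps), bc, idc,
                                        c(3L, 5L), ids[c(3, 5)], 2L,
                                        1.5)$loss
    lm <- tandemnovo:::bert_sample_grad(pr$set(params, x0 - eps), bc, idc,
                                        c(3L, 5L), ids[c(3, 5)], 2L,
                                        1.5)$loss
    expect_equal(pr$g, (lp - lm) / (2 * eps), tolerance = 1e-4)
  }
})
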