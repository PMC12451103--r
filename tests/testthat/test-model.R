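test_that("gcn_propagate follows ReLU(A X W)", {
  X <- matrix(abs(rnorm(12)), 4)
  expect_equal(gcn_propagate(diag(4), X, diag(3)), X)
  # single-edge pair: both rows become the mean of the two input rows
  A <- matrix(0.5, 2, 2)
  X2 <- matrix(rnorm(6), 2)
  out <- gcn_propagate(A, X2, diag(3))
  mid <- colMeans(X2)
  expect_equal(out[1, ], pmax(mid, 0))
  expect_equal(out[2, ], pmax(mid, 0))
  expect_equal(gcn_propagate(A, X2 * 0, diag(3)), matrix(0, 2, 3))
  expect_error(gcn_propagate(diag(3), X2, diag(3)), "shape mismatch")
})

test_that("view fusion is symmetric on identical views and reduces to
           LN(LN(H)) when value path and FFN vanish", {
  d <- 6L
  blk <- mhvf_block(d, seed = 2)
  H <- matrix(rnorm(4 * d), 4)
  fused <- view_fuse(H, H, H, blk, n_heads = 1L)
  expect_equal(fused[, 1:d], fused[, (d + 1):(2 * d)])
  expect_equal(fused[, 1:d], fused[, (2 * d + 1):(3 * d)])
  # zero value projection and zero FFN leave the pure residual path
  blk0 <- blk
  blk0$Wv <- blk$Wv * 0
  blk0$ffn2 <- blk$ffn2 * 0
  blk0$fb2 <- blk$fb2 * 0
  H2 <- matrix(rnorm(3 * d), 3)
  fused0 <- view_fuse(H2, H2 + 1, H2 - 1, blk0, n_heads = 2L)
  ln <- function(v) {
    g <- blk$ln1g[1, ]; b <- blk$ln1b[1, ]
    mu <- mean(v); va <- mean((v - mu)^2)
    g * (v - mu) / sqrt(va + 1e-5) + b
  }
  expected_tok1 <- t(apply(H2, 1, function(v) ln(ln(v))))
  expect_equal(fused0[, 1:d], expected_tok1, tolerance = 1e-12)
  expect_error(view_fuse(H2, H2, H2, mhvf_block(4L), n_heads = 1L),
               "does not match")
})

test_that("multi-scale fusion is idempotent on equal tokens and
           row-stochastic", {
  d <- 5L
  v <- matrix(rnorm(3 * d), 3)
  att_id <- list(Wmq = diag(d), Wmk = diag(d), Wmv = diag(d), Wmo = diag(d))
  out <- multi_scale_fuse(v, v, v, v, att_id)
  expect_equal(out$Z_f, v)
  expect_equal(rowSums(out$weights), rep(1, 3))
  set.seed(8)
  att <- list(Wmq = matrix(rnorm(d * d), d), Wmk = matrix(rnorm(d * d), d),
              Wmv = matrix(rnorm(d * d), d), Wmo = matrix(rnorm(d * d), d))
  Zs <- replicate(4, matrix(rnorm(2 * d), 2), simplify = FALSE)
  out2 <- multi_scale_fuse(Zs[[1]], Zs[[2]], Zs[[3]], Zs[[4]], att)
  expect_equal(rowSums(out2$weights), rep(1, 2), tolerance = 1e-6)
  expect_error(multi_scale_fuse(Zs[[1]], Zs[[2]], Zs[[3]], Zs[[4]][, 1:3],
                                att), "mismatch")
})

test_that("classifier threshold assigns the 0.5 boundary to positive and
           is row-independent", {
  head <- list(Wc1 = matrix(0, 3, 2), bc1 = matrix(0, 1, 2),
               Wc2 = matrix(1, 2, 1), bc2 = matrix(0, 1, 1))
  out <- classify(matrix(rnorm(6), 2), head)
  expect_equal(out$p, c(0.5, 0.5))
  expect_equal(out$y_hat, c(1L, 1L))
  # identical fused rows get identical probabilities
  set.seed(1)
  head$Wc1 <- matrix(rnorm(6), 3)
  head$bc2 <- matrix(0.3, 1, 1)
  Z <- matrix(rnorm(3), 1)[c(1, 1), , drop = FALSE]
  out2 <- classify(Z, head)
  expect_equal(out2$p[1], out2$p[2])
})

test_that("forward pass matches the straight-line equation oracle on random
           5-node graphs", {
  for (s in 1:3) {
    g <- tiny_mvg(5L, seed = s)
    cfg <- small_cfg(g, seed = s)
    params <- init_model(cfg)
    fw <- forward(g, params, cfg)
    or <- oracle_forward(g, params, cfg)
    expect_equal(fw$p, or$p, tolerance = 1e-5)
    expect_equal(fw$Z_f, or$z_f, tolerance = 1e-5)
  }
})

test_that("forward pass is permutation-equivariant", {
  g <- tiny_mvg(6L, seed = 4)
  cfg <- small_cfg(g)
  params <- init_model(cfg)
  p0 <- forward(g, params, cfg)$p
  set.seed(21)
  perm <- sample(6L)
  pp <- forward(permute_mvg(g, perm), params, cfg)$p
  expect_lt(max(abs(pp - p0[perm])), 1e-10)
})

test_that("with all projection weights zero the logits collapse to the
           classifier bias", {
  g <- tiny_mvg(5L, seed = 6)
  cfg <- small_cfg(g)
  params <- lapply(init_model(cfg), function(m) m * 0)
  params$bc2 <- matrix(0.7, 1, 1)
  fw <- forward(g, params, cfg)
  expect_equal(fw$p, rep(1 / (1 + exp(-0.7)), 5), tolerance = 1e-12)
})

test_that("forward is deterministic on the same platform", {
  g <- tiny_mvg(6L, seed = 9)
  cfg <- small_cfg(g, seed = 9)
  params <- init_model(cfg)
  expect_identical(forward(g, params, cfg)$Z_f, forward(g, params, cfg)$Z_f)
})

test_that("autograd gradients match finite differences and reach every
           parameter", {
  ns <- asNamespace("nucsite")
  g <- tiny_mvg(5L, seed = 10)
  cfg <- small_cfg(g, seed = 10)
  params <- init_model(cfg)
  gd <- ns$graph_data(g, cfg)
  tape <- ns$ag_tape_new()
  Pn <- ns$param_nodes(tape, params)
  out <- ns$nn_forward(tape, Pn, gd, cfg)
  ns$ag_backward(tape, out$loss)
  grads <- ns$ag_param_grads(Pn)
  # no dead branch: every parameter tensor receives a nonzero gradient
  for (nm in names(params)) {
    expect_true(!is.null(grads[[nm]]) && any(grads[[nm]] != 0), label = nm)
  }
  loss_of <- function(P) {
    tp <- ns$ag_tape_new()
    ns$nn_forward(tp, ns$param_nodes(tp, P), gd, cfg)$loss$value[1, 1]
  }
  set.seed(10)
  eps <- 1e-6
  for (nm in sample(names(params), 8)) {
    i <- sample(length(params[[nm]]), 1)
    up <- params; up[[nm]][i] <- up[[nm]][i] + eps
    dn <- params; dn[[nm]][i] <- dn[[nm]][i] - eps
    num <- (loss_of(up) - loss_of(dn)) / (2 * eps)
    expect_equal(grads[[nm]][i], num, tolerance = 1e-4, label = nm)
  }
})

test_that("batched block-diagonal forward equals per-graph forwards", {
  ns <- asNamespace("nucsite")
  g1 <- tiny_mvg(5L, seed = 12)
  g2 <- tiny_mvg(7L, seed = 13)
  cfg <- small_cfg(g1)
  params <- init_model(cfg)
  gd <- ns$batch_graph_data(list(ns$graph_data(g1, cfg),
                                 ns$graph_data(g2, cfg)))
  tape <- ns$ag_tape_new()
  out <- ns$nn_forward(tape, ns$param_nodes(tape, params), gd, cfg)
  p_batch <- 1 / (1 + exp(-as.numeric(out$logits$value)))
  p_sep <- c(forward(g1, params, cfg)$p, forward(g2, params, cfg)$p)
  expect_equal(p_batch, p_sep, tolerance = 1e-10)
  # the batch loss is the mean of all 12 per-node cross-entropy terms
  y <- c(g1$y, g2$y)
  bce <- -(y * log(p_batch) + (1 - y) * log(1 - p_batch))
  expect_equal(out$loss$value[1, 1], mean(bce), tolerance = 1e-10)
})

test_that("structure ablation drops the view's branch, token and
           parameters", {
  g <- tiny_mvg(5L, seed = 14)
  cfg_full <- small_cfg(g)
  cfg_wo <- small_cfg(g, views = c("P", "S"))
  p_full <- init_model(cfg_full)
  p_wo <- init_model(cfg_wo)
  expect_true(all(names(p_wo) %in% names(p_full)))
  expect_false(any(grepl("_T$", names(p_wo))))
  fw <- forward(g, p_wo, cfg_wo)
  expect_length(fw$p, 5L)
  # msf ablation: fused embedding is the concatenation of the four scales
  cfg_cat <- small_cfg(g, msf = FALSE)
  p_cat <- init_model(cfg_cat)
  fw2 <- forward(g, p_cat, cfg_cat)
  expect_equal(ncol(fw2$Z_f), 4L * cfg_cat$d_scale)
  expect_equal(fw2$Z_f, do.call(cbind, fw2$Z))
})
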