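test_that("metric computation matches the brute-force oracle on random
           vectors", {
  set.seed(17)
  for (rep in 1:60) {
    n <- sample(5:60, 1)
    y <- rbinom(n, 1, runif(1, 0.2, 0.8))
    p <- round(runif(n), sample(c(1, 6), 1))  # coarse rounding forces ties
    m <- compute_metrics(y, p)
    o <- oracle_metrics(y, p)
    for (f in c("TP", "FP", "TN", "FN", "precision", "recall", "mcc")) {
      expect_equal(m[[f]], o[[f]], tolerance = 1e-12, label = f)
    }
    if (is.na(o$auc)) expect_true(is.na(m$auc))
    else expect_equal(m$auc, o$auc, tolerance = 1e-12)
  }
})

test_that("metric edge cases: perfect prediction, known MCC, constant
           scores, degenerate classes", {
  y <- c(1, 0, 1, 0, 1)
  m <- compute_metrics(y, y)
  expect_equal(c(m$precision, m$recall, m$mcc, m$auc), c(1, 1, 1, 1))
  # (TP, FP, TN, FN) = (2, 1, 3, 1): MCC = 5/12
  y2 <- c(1, 1, 1, 0, 0, 0, 0)
  p2 <- c(0.9, 0.8, 0.1, 0.7, 0.2, 0.2, 0.1)
  m2 <- compute_metrics(y2, p2)
  expect_equal(c(m2$TP, m2$FP, m2$TN, m2$FN), c(2, 1, 3, 1))
  expect_equal(m2$mcc, 5 / 12)
  # constant probabilities: AUC is 0.5 by the tie convention
  expect_equal(compute_metrics(c(0, 1, 0, 1), rep(0.3, 4))$auc, 0.5)
  # single-class labels: AUC missing, not 0.5
  expect_true(is.na(compute_metrics(c(1, 1), c(0.2, 0.9))$auc))
  expect_error(compute_metrics(c(0, 1), c(0.1, 0.2, 0.3)), "length mismatch")
})

test_that("MCC is invariant under swapping (TP,FP) with (TN,FN)", {
  set.seed(23)
  for (rep in 1:20) {
    y <- rbinom(30, 1, 0.4)
    p <- runif(30)
    m1 <- compute_metrics(y, p)
    m2 <- compute_metrics(1 - y, 1 - p + 1e-9)  # strict flip of calls
    expect_equal(m1$mcc, m2$mcc, tolerance = 1e-9)
  }
})

test_that("chain-level split has the prescribed sizes and is
           deterministic", {
  chains <- as.list(seq_len(60))
  sp <- split_dataset(chains, 0.1, seed = 5)
  expect_length(sp$train, 54L)
  expect_length(sp$validation, 6L)
  expect_identical(sp, split_dataset(chains, 0.1, seed = 5))
  expect_false(identical(sp, split_dataset(chains, 0.1, seed = 6)))
  sp2 <- split_dataset(as.list(1:2), 0.5, seed = 1)
  expect_length(sp2$train, 1L)
  expect_length(sp2$validation, 1L)
  expect_error(split_dataset(list(1), 0.5, 1), "at least 2")
})

test_that("ablate flips the named component and rejects unknown variants", {
  cfg <- train_config()
  expect_equal(ablate(cfg, "ter_str")$ablation, "ter_str")
  expect_equal(ablate(cfg, "msf")$ablation, "msf")
  expect_error(ablate(cfg, "quaternary"), "unknown ablation variant")
  ns <- asNamespace("nucsite")
  expect_equal(ns$ablation_views("ter_str"), c("P", "S"))
  expect_equal(ns$ablation_views("prim_feat"), c("P", "S", "T"))
})

test_that("feature ablation zeroes the view's block across a dataset", {
  ns <- asNamespace("nucsite")
  gs <- list(tiny_mvg(5L, seed = 1), tiny_mvg(6L, seed = 2))
  ab <- ns$apply_feature_ablation(gs, "sec_feat")
  for (g in ab) {
    expect_true(all(g$x_init$X[, g$x_init$block_map$secondary] == 0))
  }
  # graphs untouched
  expect_identical(ab[[1]]$graphs, gs[[1]]$graphs)
})

test_that("every ablated variant's parameter set is a strict subset of the
           full model's", {
  g <- tiny_mvg(5L, seed = 3)
  full <- names(init_model(small_cfg(g)))
  for (variant in c("prim_str", "sec_str", "ter_str", "msf")) {
    views <- asNamespace("nucsite")$ablation_views(variant)
    cfg_v <- small_cfg(g, views = views, msf = variant != "msf")
    nms <- names(init_model(cfg_v))
    expect_true(all(nms %in% full), label = variant)
    expect_lt(length(nms), length(full))
  }
})

test_that("training reduces loss on a learnable synthetic set and is
           seed-reproducible", {
  ds <- simulate_dataset(n_rnas = 8L, signal = 2.5, seed = 31,
                         len_range = c(14L, 18L), d_emb = 4L)
  cfg <- train_config(epochs = 12L, batch_size = 4L, seed = 31)
  mo <- list(d_hidden = 16L, n_heads = 2L, d_scale = 16L, clf_hidden = 8L)
  fit <- train_model(ds, cfg, mo)
  expect_lt(mean(tail(fit$history$train_loss, 3)),
            mean(head(fit$history$train_loss, 3)))
  fit2 <- train_model(ds, cfg, mo)
  expect_identical(fit$history, fit2$history)
  expect_identical(fit$params, fit2$params)
  pr <- predict_graphs(fit, ds$test)
  pr2 <- predict_graphs(fit2, ds$test)
  expect_identical(pr$p, pr2$p)
})

test_that("training rejects degenerate single-class labels", {
  ds <- simulate_dataset(n_rnas = 4L, signal = 1, seed = 3,
                         len_range = c(14L, 16L), d_emb = 4L)
  ds$train <- lapply(ds$train, function(g) { g$y[] <- 0L; g })
  expect_error(train_model(ds, train_config(epochs = 1L)), "one class")
})

test_that("sensitivity sweep returns one metrics row per setting", {
  ds_fn <- function(k) simulate_dataset(n_rnas = 6L, signal = 2.5, seed = 41,
                                        len_range = c(14L, 16L), d_emb = 4L,
                                        k_tertiary = k)
  res <- sensitivity_sweep(ds_fn, "n_layers", values = c(1L, 2L),
                           cfg = train_config(epochs = 3L, batch_size = 4L,
                                              seed = 41),
                           model_opts = list(d_hidden = 8L, n_heads = 2L,
                                             d_scale = 8L, clf_hidden = 4L))
  expect_equal(nrow(res), 2L)
  expect_equal(res$value, c(1, 2))
  expect_true(all(res$auc >= 0 & res$auc <= 1))
  # the k sweep rebuilds the tertiary graph per setting
  res_k <- sensitivity_sweep(ds_fn, "k_tertiary", values = 3L,
                             cfg = train_config(epochs = 2L, batch_size = 4L,
                                                seed = 41),
                             model_opts = list(d_hidden = 8L, n_heads = 2L,
                                               d_scale = 8L, clf_hidden = 4L))
  expect_equal(res_k$setting, "k_tertiary")
  expect_equal(res_k$value, 3)
})
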