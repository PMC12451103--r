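#' Training configuration
#'
#' Defaults follow the reference training protocol: Adam at learning rate
#' 6e-5, mini-batches of 30 RNA graphs, 200 epochs, a 9:1 train/validation
#' split at whole-chain granularity, plain (unweighted) binary cross-entropy,
#' three stacked layers, and neighbourhood sizes k = 13 (primary) and k = 8
#' (tertiary).
#'
#' @param learning_rate Adam learning rate.
#' @param batch_size Graphs per mini-batch.
#' @param epochs Training epochs.
#' @param val_fraction Fraction of chains held out for validation.
#' @param seed Seed controlling initialization, shuffling and dropout.
#' @param pos_weight Positive-class weight in the loss (1 = off, the
#'   default; the loss is plain binary cross-entropy despite class
#'   imbalance).
#' @param ablation One of `"none"`, `"prim_str"`, `"sec_str"`, `"ter_str"`,
#'   `"prim_feat"`, `"sec_feat"`, `"ter_feat"`, `"msf"`.
#' @param k_primary,k_tertiary Graph neighbourhood sizes (recorded for
#'   provenance; graphs are built upstream).
#' @param n_layers Stacked multi-view layers.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 6e-5, batch_size = 30L,
                         epochs = 200L, val_fraction = 0.1, seed = 1L,
                         pos_weight = 1, ablation = "none",
                         k_primary = 13L, k_tertiary = 8L, n_layers = 3L) {
  stopifnot(learning_rate > 0, batch_size >= 1L, epochs >= 1L,
            val_fraction > 0, val_fraction < 1, pos_weight > 0)
  ablation <- match.arg(ablation, c("none", ablation_variants()))
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), val_fraction = val_fraction,
                 seed = as.integer(seed), pos_weight = pos_weight,
                 ablation = ablation, k_primary = as.integer(k_primary),
                 k_tertiary = as.integer(k_tertiary),
                 n_layers = as.integer(n_layers)),
            class = "train_config")
}

ablation_variants <- function() {
  c("prim_str", "sec_str", "ter_str", "prim_feat", "sec_feat", "ter_feat", "msf")
}

#' Switch one component off in a training configuration
#'
#' `*_str` variants remove a view's graph branch and its fusion token;
#' `*_feat` variants zero the view's feature block while leaving all graphs
#' intact; `msf` replaces attentive multi-scale fusion with concatenation of
#' the scale embeddings.
#'
#' @param cfg A `train_config`.
#' @param variant Variant name (see [train_config()]).
#' @return The modified `train_config`.
#' @export
ablate <- function(cfg, variant) {
  if (!(variant %in% ablation_variants())) {
    stop("unknown ablation variant '", variant, "'; expected one of: ",
         paste(ablation_variants(), collapse = ", "))
  }
  cfg$ablation <- variant
  cfg
}

# model-side consequences of an ablation flag
ablation_views <- function(ablation) {
  switch(ablation,
         prim_str = c("S", "T"), sec_str = c("P", "T"), ter_str = c("P", "S"),
         c("P", "S", "T"))
}

apply_feature_ablation <- function(graphs, ablation) {
  view <- switch(ablation, prim_feat = "prim", sec_feat = "sec",
                 ter_feat = "ter", NULL)
  if (is.null(view)) return(graphs)
  lapply(graphs, function(g) {
    g$x_init <- zero_feature_block(g$x_init, view)
    g
  })
}

#' Split chains into training and validation sets
#'
#' Whole-RNA-chain granularity: `ceiling((1 - fraction) * m)` chains train,
#' the rest validate; deterministic given the seed.
#'
#' @param chains List of chains (any type).
#' @param fraction Validation fraction (default 0.1).
#' @param seed Seed.
#' @return List with `train` and `validation` sublists.
#' @export
split_dataset <- function(chains, fraction = 0.1, seed = 1L) {
  m <- length(chains)
  if (m < 2L) stop("need at least 2 chains to split, got ", m)
  n_train <- ceiling((1 - fraction) * m)
  set.seed(seed)
  perm <- sample.int(m)
  list(train = chains[perm[seq_len(n_train)]],
       validation = chains[perm[seq.int(n_train + 1L, m)]])
}

adam_new <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

#' Train the multi-view network
#'
#' Minimizes mean per-nucleotide binary cross-entropy with Adam over
#' mini-batches of whole RNA graphs. Graph batching is block-diagonal in
#' effect: each graph is propagated on its own adjacencies so no message ever
#' crosses RNA boundaries, and the batch loss is the mean over all
#' nucleotides in the batch. Per-epoch training loss, validation loss and
#' validation AUC are recorded, and the returned parameters are the
#' checkpoint with the best validation AUC (the final-epoch parameters are
#' also kept).
#'
#' @param dataset List with `train` and `validation` lists of
#'   `multi_view_graph`s (see [split_dataset()], [simulate_dataset()]).
#' @param cfg A `train_config`.
#' @param model_opts Named list overriding [model_config()] widths
#'   (`d_hidden`, `n_heads`, `d_scale`, `ffn_mult`, `dropout`,
#'   `clf_hidden`).
#' @param verbose Print a line every `verbose` epochs (0 = silent).
#' @return A `trained_model`: list with `params` (best checkpoint),
#'   `final_params`, `cfg_model`, `cfg_train`, `history` (data.frame with
#'   epoch, train_loss, val_loss, val_auc), `best_epoch`, `best_val_auc`.
#' @export
train_model <- function(dataset, cfg = train_config(), model_opts = list(),
                        verbose = 0L) {
  train_g <- apply_feature_ablation(dataset$train, cfg$ablation)
  val_g <- apply_feature_ablation(dataset$validation, cfg$ablation)
  if (length(train_g) == 0L) stop("empty training set")
  y_all <- unlist(lapply(train_g, function(g) g$y))
  if (length(unique(y_all)) < 2L) {
    stop("training labels are all one class; the loss is degenerate")
  }
  views <- ablation_views(cfg$ablation)
  msf <- cfg$ablation != "msf"
  d_init <- ncol(train_g[[1]]$x_init$X)
  mo <- utils::modifyList(
    list(d_hidden = 128L, n_heads = 4L, d_scale = 128L, ffn_mult = 4L,
         dropout = 0.1, clf_hidden = 64L), model_opts)
  cfg_model <- model_config(d_init = d_init, d_hidden = mo$d_hidden,
                            n_heads = mo$n_heads, d_scale = mo$d_scale,
                            ffn_mult = mo$ffn_mult, dropout = mo$dropout,
                            clf_hidden = mo$clf_hidden,
                            n_layers = cfg$n_layers, views = views,
                            msf = msf, seed = cfg$seed)
  gd_train <- lapply(train_g, graph_data, cfg = cfg_model)
  gd_val <- lapply(val_g, graph_data, cfg = cfg_model)
  # per-graph loss weights: node counts under the (optional) positive-class
  # weighting, so the batch loss is the weighted mean over all batch nodes
  n_nodes <- vapply(gd_train, function(g)
    sum(ifelse(g$y == 1, cfg$pos_weight, 1)), numeric(1))
  params <- init_model(cfg_model)
  state <- adam_new(params)
  n_tr <- length(gd_train)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0), val_auc = numeric(0))
  best <- list(auc = -Inf, params = params, epoch = 0L)
  set.seed(cfg$seed)
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample.int(n_tr)
    starts <- seq.int(1L, n_tr, by = cfg$batch_size)
    ep_loss <- 0
    ep_nodes <- 0L
    for (s in starts) {
      idx <- ord[seq.int(s, min(s + cfg$batch_size - 1L, n_tr))]
      tape <- ag_tape_new()
      Pn <- param_nodes(tape, params)
      gd <- batch_graph_data(gd_train[idx])
      out <- nn_forward(tape, Pn, gd, cfg_model,
                        training = TRUE, pos_weight = cfg$pos_weight)
      total <- out$loss
      ag_backward(tape, total)
      grads <- ag_param_grads(Pn)
      upd <- adam_step(params, grads, state, cfg$learning_rate)
      params <- upd$params
      state <- upd$state
      ep_loss <- ep_loss + total$value[1, 1] * sum(n_nodes[idx])
      ep_nodes <- ep_nodes + sum(n_nodes[idx])
    }
    val <- evaluate_loss_auc(params, cfg_model, gd_val, cfg$pos_weight)
    history <- rbind(history, data.frame(
      epoch = epoch, train_loss = ep_loss / ep_nodes,
      val_loss = val$loss, val_auc = val$auc))
    if (is.finite(val$auc) && val$auc > best$auc) {
      best <- list(auc = val$auc, params = params, epoch = epoch)
    }
    if (verbose > 0L && epoch %% verbose == 0L) {
      message(sprintf("epoch %4d  train %.4f  val %.4f  val AUC %.4f",
                      epoch, ep_loss / ep_nodes, val$loss, val$auc))
    }
  }
  if (best$epoch == 0L) {
    # no finite validation AUC was ever observed: fall back to final epoch
    best <- list(auc = NA_real_, params = params, epoch = cfg$epochs)
  }
  structure(list(params = best$params, final_params = params,
                 cfg_model = cfg_model, cfg_train = cfg,
                 history = history, best_epoch = best$epoch,
                 best_val_auc = best$auc),
            class = "trained_model")
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf("trained_model: %d epochs, best val AUC %.4f at epoch %d\n",
              nrow(x$history), x$best_val_auc, x$best_epoch))
  invisible(x)
}

evaluate_loss_auc <- function(params, cfg_model, gd_list, pos_weight = 1) {
  if (length(gd_list) == 0L) {
    return(list(loss = NA_real_, auc = NA_real_, p = numeric(0),
                y = integer(0)))
  }
  gd <- batch_graph_data(gd_list)
  tape <- ag_tape_new()
  Pn <- param_nodes(tape, params)
  out <- nn_forward(tape, Pn, gd, cfg_model, training = FALSE,
                    pos_weight = pos_weight)
  ps <- as.numeric(1 / (1 + exp(-out$logits$value)))
  ys <- gd$y
  auc <- if (length(unique(ys)) < 2L) NA_real_ else auc_rank(ys, ps)
  list(loss = out$loss$value[1, 1], auc = auc, p = ps, y = ys)
}

#' Predict binding probabilities for a list of graphs
#'
#' @param model A `trained_model` (or list with `params` and `cfg_model`).
#' @param graphs List of `multi_view_graph`s. Feature ablations recorded in
#'   the model's training config are re-applied so evaluation matches
#'   training.
#' @return List with pooled `p`, `y_hat`, `y` and `per_graph` probabilities.
#' @export
predict_graphs <- function(model, graphs) {
  graphs <- apply_feature_ablation(graphs, model$cfg_train$ablation)
  per_graph <- vector("list", length(graphs))
  ps <- numeric(0); ys <- integer(0)
  for (i in seq_along(graphs)) {
    fw <- forward(graphs[[i]], model$params, model$cfg_model)
    per_graph[[i]] <- fw$p
    ps <- c(ps, fw$p)
    ys <- c(ys, graphs[[i]]$y)
  }
  list(p = ps, y_hat = as.integer(ps >= 0.5), y = ys, per_graph = per_graph)
}

# Mann-Whitney AUC with average ranks for ties
auc_rank <- function(y, p) {
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(p, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Residue-level classification metrics
#'
#' Confusion counts at the given probability threshold (boundary assigned
#' positive), precision `TP/(TP+FP)`, recall `TP/(TP+FN)`, the Matthews
#' correlation coefficient (0 when any denominator factor vanishes), and AUC
#' computed from the probabilities by the Mann-Whitney rank statistic with
#' average ranks for ties. AUC is reported as `NA` when only one class is
#' present.
#'
#' @param y_true 0/1 labels.
#' @param p Predicted probabilities (or scores).
#' @param threshold Decision threshold (default 0.5).
#' @return A `metrics_report` list with `TP`, `FP`, `TN`, `FN`, `precision`,
#'   `recall`, `mcc`, `auc`.
#' @export
compute_metrics <- function(y_true, p, threshold = 0.5) {
  if (length(y_true) != length(p)) {
    stop("length mismatch: ", length(y_true), " labels vs ", length(p),
         " probabilities")
  }
  stopifnot(all(y_true %in% c(0, 1)))
  yh <- as.integer(p >= threshold)
  tp <- sum(yh == 1 & y_true == 1)
  fp <- sum(yh == 1 & y_true == 0)
  tn <- sum(yh == 0 & y_true == 0)
  fn <- sum(yh == 0 & y_true == 1)
  precision <- if (tp + fp == 0L) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0L) 0 else tp / (tp + fn)
  denom <- as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom == 0) 0 else
    (as.numeric(tp) * tn - as.numeric(fp) * fn) / sqrt(denom)
  structure(list(TP = tp, FP = fp, TN = tn, FN = fn, precision = precision,
                 recall = recall, mcc = mcc, auc = auc_rank(y_true, p)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("TP %d  FP %d  TN %d  FN %d\n", x$TP, x$FP, x$TN, x$FN))
  cat(sprintf("precision %.3f  recall %.3f  MCC %.3f  AUC %s\n",
              x$precision, x$recall, x$mcc,
              if (is.na(x$auc)) "NA" else sprintf("%.3f", x$auc)))
  invisible(x)
}

#' Sensitivity sweep over a structural or architectural knob
#'
#' Retrains the model for each value of the knob and evaluates on the test
#' split, mirroring the k-nearest-neighbour and layer-depth sweeps of the
#' method's sensitivity analysis.
#'
#' @param dataset_fn Function taking the current `k_tertiary` value and
#'   returning a dataset (`train` / `validation` / `test` lists); ignored
#'   argument for `what = "n_layers"`, where the first call's dataset is
#'   reused.
#' @param what `"k_tertiary"` or `"n_layers"`.
#' @param values Values to sweep.
#' @param cfg Base `train_config`.
#' @param model_opts Passed to [train_model()].
#' @return data.frame with `setting`, `value`, `precision`, `recall`, `mcc`,
#'   `auc`.
#' @export
sensitivity_sweep <- function(dataset_fn, what = c("k_tertiary", "n_layers"),
                              values, cfg = train_config(), model_opts = list()) {
  what <- match.arg(what)
  rows <- list()
  ds_fixed <- if (what == "n_layers") dataset_fn(cfg$k_tertiary)
  for (v in values) {
    cfg_v <- cfg
    if (what == "k_tertiary") {
      cfg_v$k_tertiary <- as.integer(v)
      ds <- dataset_fn(as.integer(v))
    } else {
      cfg_v$n_layers <- as.integer(v)
      ds <- ds_fixed
    }
    fit <- train_model(ds, cfg_v, model_opts)
    pr <- predict_graphs(fit, ds$test)
    m <- compute_metrics(pr$y, pr$p)
    rows[[length(rows) + 1L]] <- data.frame(
      setting = what, value = v, precision = m$precision, recall = m$recall,
      mcc = m$mcc, auc = m$auc)
  }
  do.call(rbind, rows)
}
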