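# The multi-view network. One RNA enters as an initial feature matrix X_init
# plus three normalized adjacencies (primary/secondary/tertiary). Each of the
# three stacked layers propagates every view with a graph convolution
# H_k = ReLU(A_hat_k X W_k), then fuses the per-view embeddings of each
# nucleotide with multi-head self-attention over the views (the three view
# vectors are the attention tokens, so attention mixes views, never
# nucleotides), a feed-forward transform, and two residual + layer-norm
# steps. The fused matrix feeds the tertiary branch of the next layer, while
# the primary and secondary branches continue from their own per-view
# outputs. Per-layer MLPs yield one embedding per scale; the raw features,
# linearly projected, act as the smallest scale. A shared-projection
# self-attention over the scale tokens followed by average pooling gives the
# fused representation that the classifier head maps to a binding
# probability.

#' Model configuration
#'
#' Widths and switches of the network. The attention model width equals
#' `d_hidden` and must be divisible by `n_heads`.
#'
#' @param d_init Width of the initial feature matrix.
#' @param d_hidden Per-view graph-convolution width.
#' @param n_heads Attention heads in the view-fusion blocks.
#' @param d_scale Common width of the per-scale embeddings.
#' @param ffn_mult Feed-forward inner width as a multiple of `d_hidden`.
#' @param dropout Dropout rate applied to hidden activations during training.
#' @param clf_hidden Classifier hidden width.
#' @param n_layers Number of stacked multi-view layers (3 in the reference
#'   architecture; the sensitivity sweep varies it).
#' @param views Character subset of `c("P","S","T")`; removing a view removes
#'   both its graph branch and its fusion token (structure-ablation switch).
#' @param msf If `FALSE`, attentive multi-scale fusion is replaced by plain
#'   concatenation of the scale embeddings (fusion-ablation switch).
#' @param seed Seed for weight initialization.
#' @return A `model_config` list.
#' @export
model_config <- function(d_init, d_hidden = 128L, n_heads = 4L,
                         d_scale = 128L, ffn_mult = 4L, dropout = 0.1,
                         clf_hidden = 64L, n_layers = 3L,
                         views = c("P", "S", "T"), msf = TRUE, seed = 1L) {
  stopifnot(d_hidden %% n_heads == 0L, d_init > 0L, d_scale > 0L,
            n_layers >= 1L, length(views) >= 1L, all(views %in% c("P", "S", "T")),
            dropout >= 0, dropout < 1)
  structure(list(d_init = as.integer(d_init), d_hidden = as.integer(d_hidden),
                 n_heads = as.integer(n_heads), d_scale = as.integer(d_scale),
                 ffn_mult = as.integer(ffn_mult), dropout = dropout,
                 clf_hidden = as.integer(clf_hidden),
                 n_layers = as.integer(n_layers), views = views,
                 msf = isTRUE(msf), seed = as.integer(seed)),
            class = "model_config")
}

glorot <- function(fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}

#' Initialize model parameters
#'
#' Glorot-uniform projections, unit layer-norm gains, zero biases except
#' that hidden layers followed by a ReLU get a small positive bias (0.01)
#' so no unit starts dead; deterministic given `cfg$seed`.
#'
#' @param cfg A `model_config`.
#' @return Named list of parameter matrices.
#' @export
init_model <- function(cfg) {
  set.seed(cfg$seed)
  d <- cfg$d_hidden
  v <- length(cfg$views)
  P <- list()
  for (l in seq_len(cfg$n_layers)) {
    for (k in cfg$views) {
      d_in <- if (l == 1L) cfg$d_init
              else if (k == "T" && "T" %in% cfg$views) v * d else d
      P[[sprintf("gcn%d_%s", l, k)]] <- glorot(d_in, d)
    }
    for (nm in c("Wq", "Wk", "Wv", "Wo")) {
      P[[sprintf("%s%d", nm, l)]] <- glorot(d, d)
    }
    P[[sprintf("ffn1_%d", l)]] <- glorot(d, cfg$ffn_mult * d)
    P[[sprintf("fb1_%d", l)]] <- matrix(0.01, 1L, cfg$ffn_mult * d)
    P[[sprintf("ffn2_%d", l)]] <- glorot(cfg$ffn_mult * d, d)
    P[[sprintf("fb2_%d", l)]] <- matrix(0, 1L, d)
    P[[sprintf("ln1g_%d", l)]] <- matrix(1, 1L, d)
    P[[sprintf("ln1b_%d", l)]] <- matrix(0, 1L, d)
    P[[sprintf("ln2g_%d", l)]] <- matrix(1, 1L, d)
    P[[sprintf("ln2b_%d", l)]] <- matrix(0, 1L, d)
    P[[sprintf("Wz1_%d", l)]] <- glorot(v * d, cfg$d_scale)
    P[[sprintf("bz1_%d", l)]] <- matrix(0.01, 1L, cfg$d_scale)
    P[[sprintf("Wz2_%d", l)]] <- glorot(cfg$d_scale, cfg$d_scale)
    P[[sprintf("bz2_%d", l)]] <- matrix(0, 1L, cfg$d_scale)
  }
  P$Wnode <- glorot(cfg$d_init, cfg$d_scale)
  P$bnode <- matrix(0, 1L, cfg$d_scale)
  if (cfg$msf) {
    P$Wmq <- glorot(cfg$d_scale, cfg$d_scale)
    P$Wmk <- glorot(cfg$d_scale, cfg$d_scale)
    P$Wmv <- glorot(cfg$d_scale, cfg$d_scale)
    P$Wmo <- glorot(cfg$d_scale, cfg$d_scale)
  }
  d_clf <- if (cfg$msf) cfg$d_scale else (cfg$n_layers + 1L) * cfg$d_scale
  P$Wc1 <- glorot(d_clf, cfg$clf_hidden)
  P$bc1 <- matrix(0.01, 1L, cfg$clf_hidden)
  P$Wc2 <- glorot(cfg$clf_hidden, 1L)
  P$bc2 <- matrix(0, 1L, 1L)
  P
}

# wrap every parameter matrix as a tracked tape leaf
param_nodes <- function(tape, params) {
  out <- vector("list", length(params))
  names(out) <- names(params)
  for (nm in names(params)) out[[nm]] <- ag_param(tape, params[[nm]], nm)
  out
}

# Self-attention over a short list of per-nucleotide tokens (each n x d).
# Shared Q/K/V/O projections; heads slice the feature axis. Returns the list
# of attended tokens (post output projection) and, on request, the attention
# weight matrices (n x m per query token) for diagnostics.
token_attention <- function(tape, tokens, Wq, Wk, Wv, Wo, n_heads,
                            keep_weights = FALSE) {
  m <- length(tokens)
  d <- ncol(tokens[[1]]$value)
  dh <- d %/% n_heads
  Q <- lapply(tokens, function(t) ag_mm(tape, t, Wq))
  K <- lapply(tokens, function(t) ag_mm(tape, t, Wk))
  V <- lapply(tokens, function(t) ag_mm(tape, t, Wv))
  weights <- if (keep_weights) rep(list(vector("list", n_heads)), m)
  outs <- vector("list", m)
  for (a in seq_len(m)) {
    head_outs <- vector("list", n_heads)
    for (h in seq_len(n_heads)) {
      cols <- ((h - 1L) * dh + 1L):(h * dh)
      Qa <- ag_slice_cols(tape, Q[[a]], cols)
      scores <- vector("list", m)
      for (b in seq_len(m)) {
        Kb <- ag_slice_cols(tape, K[[b]], cols)
        scores[[b]] <- ag_scale(tape, ag_rowsums(tape, ag_mul(tape, Qa, Kb)),
                                1 / sqrt(dh))
      }
      W <- ag_softmax_rows(tape, ag_concat_cols(tape, scores))
      if (keep_weights) weights[[a]][[h]] <- W$value
      acc <- NULL
      for (b in seq_len(m)) {
        Vb <- ag_slice_cols(tape, V[[b]], cols)
        wb <- ag_slice_cols(tape, W, b)
        term <- ag_colscale(tape, Vb, wb)
        acc <- if (is.null(acc)) term else ag_add(tape, acc, term)
      }
      head_outs[[h]] <- acc
    }
    cat_heads <- if (n_heads == 1L) head_outs[[1]] else ag_concat_cols(tape, head_outs)
    outs[[a]] <- ag_mm(tape, cat_heads, Wo)
  }
  list(outs = outs, weights = weights)
}

# One view-fusion stage on the tape: tokens are the per-view embeddings of
# each nucleotide; output is the per-token fused embeddings (list) following
# X = LN2(LN1(H + Attention) + FFN(Attention)).
mhvf_on_tape <- function(tape, tokens, Pn, l, cfg, training = FALSE,
                         keep_weights = FALSE) {
  att <- token_attention(tape, tokens,
                         Pn[[sprintf("Wq%d", l)]], Pn[[sprintf("Wk%d", l)]],
                         Pn[[sprintf("Wv%d", l)]], Pn[[sprintf("Wo%d", l)]],
                         cfg$n_heads, keep_weights = keep_weights)
  fused <- vector("list", length(tokens))
  for (a in seq_along(tokens)) {
    attn <- att$outs[[a]]
    res1 <- ag_layernorm(tape, ag_add(tape, tokens[[a]], attn),
                         Pn[[sprintf("ln1g_%d", l)]], Pn[[sprintf("ln1b_%d", l)]])
    hid <- ag_relu(tape, ag_addbias(tape, ag_mm(tape, attn, Pn[[sprintf("ffn1_%d", l)]]),
                                    Pn[[sprintf("fb1_%d", l)]]))
    if (training) hid <- ag_dropout(tape, hid, cfg$dropout)
    ffn <- ag_addbias(tape, ag_mm(tape, hid, Pn[[sprintf("ffn2_%d", l)]]),
                      Pn[[sprintf("fb2_%d", l)]])
    fused[[a]] <- ag_layernorm(tape, ag_add(tape, res1, ffn),
                               Pn[[sprintf("ln2g_%d", l)]], Pn[[sprintf("ln2b_%d", l)]])
  }
  list(fused = fused, weights = att$weights)
}

# Full forward pass on an existing tape. g_data: list(X = matrix,
# A = named list of normalized adjacencies for cfg$views, y = labels or NULL).
# Returns nodes for logits, per-scale embeddings, fused embedding, loss.
nn_forward <- function(tape, Pn, g_data, cfg, training = FALSE,
                       pos_weight = 1) {
  views <- cfg$views
  X0 <- ag_const(tape, g_data$X)
  A <- lapply(g_data$A[views], function(m) ag_const(tape, m))
  inputs <- stats::setNames(rep(list(X0), length(views)), views)
  fused_prev <- NULL
  scale_nodes <- vector("list", cfg$n_layers)
  for (l in seq_len(cfg$n_layers)) {
    H <- list()
    for (k in views) {
      x_in <- if (l > 1L && k == "T") fused_prev else inputs[[k]]
      h <- ag_relu(tape, ag_mm(tape, ag_mm(tape, A[[k]], x_in),
                               Pn[[sprintf("gcn%d_%s", l, k)]]))
      if (training) h <- ag_dropout(tape, h, cfg$dropout)
      H[[k]] <- h
    }
    mh <- mhvf_on_tape(tape, unname(H[views]), Pn, l, cfg, training = training)
    fused_prev <- ag_concat_cols(tape, mh$fused)
    inputs <- H
    z <- ag_relu(tape, ag_addbias(tape, ag_mm(tape, fused_prev,
                                              Pn[[sprintf("Wz1_%d", l)]]),
                                  Pn[[sprintf("bz1_%d", l)]]))
    scale_nodes[[l]] <- ag_addbias(tape, ag_mm(tape, z, Pn[[sprintf("Wz2_%d", l)]]),
                                   Pn[[sprintf("bz2_%d", l)]])
    if (any(!is.finite(scale_nodes[[l]]$value))) {
      stop("non-finite activation in layer ", l)
    }
  }
  z_node <- ag_addbias(tape, ag_mm(tape, X0, Pn$Wnode), Pn$bnode)
  scales <- c(list(z_node), scale_nodes)
  if (cfg$msf) {
    att <- token_attention(tape, scales, Pn$Wmq, Pn$Wmk, Pn$Wmv, Pn$Wmo,
                           n_heads = 1L)
    acc <- att$outs[[1]]
    for (b in seq_along(att$outs)[-1]) acc <- ag_add(tape, acc, att$outs[[b]])
    z_f <- ag_scale(tape, acc, 1 / length(att$outs))
  } else {
    z_f <- ag_concat_cols(tape, scales)
  }
  hid <- ag_relu(tape, ag_addbias(tape, ag_mm(tape, z_f, Pn$Wc1), Pn$bc1))
  if (training) hid <- ag_dropout(tape, hid, cfg$dropout)
  logits <- ag_addbias(tape, ag_mm(tape, hid, Pn$Wc2), Pn$bc2)
  loss <- if (!is.null(g_data$y)) {
    ag_bce_logits(tape, logits, g_data$y, pos_weight = pos_weight)
  }
  list(logits = logits, scales = scales, z_f = z_f, loss = loss)
}

# Stack several graphs into one block-diagonal problem. Messages cannot
# cross RNA boundaries because the off-diagonal adjacency blocks are zero,
# and every remaining operation in the network is row-wise, so the batched
# forward pass equals the per-graph passes; the batch loss is the mean over
# all nucleotides in the batch.
batch_graph_data <- function(gd_list) {
  if (length(gd_list) == 1L) return(gd_list[[1]])
  ns <- vapply(gd_list, function(g) nrow(g$X), integer(1))
  offs <- cumsum(c(0L, ns))
  N <- sum(ns)
  A <- lapply(names(gd_list[[1]]$A), function(v) {
    M <- matrix(0, N, N)
    for (i in seq_along(gd_list)) {
      at <- offs[i] + seq_len(ns[i])
      M[at, at] <- gd_list[[i]]$A[[v]]
    }
    M
  })
  names(A) <- names(gd_list[[1]]$A)
  list(X = do.call(rbind, lapply(gd_list, function(g) g$X)), A = A,
       y = unlist(lapply(gd_list, function(g) g$y)))
}

# normalized adjacencies for the views a config uses; structure-ablated views
# are simply absent
graph_data <- function(g, cfg) {
  A <- lapply(stats::setNames(cfg$views, cfg$views), function(k)
    normalized_adjacency(g$graphs[[k]]))
  list(X = g$x_init$X, A = A, y = g$y)
}

#' Run the network on one RNA
#'
#' Executes the full forward pass and returns the four per-nucleotide scale
#' embeddings, the fused representation, binding probabilities and binary
#' calls (threshold 0.5, boundary assigned positive).
#'
#' @param g A `multi_view_graph`.
#' @param params Parameter list from [init_model()] or [train_model()].
#' @param cfg The matching `model_config`.
#' @return A `scale_embeddings` list with `Z` (named list: `Z_Node` then one
#'   embedding per layer, `Z_NA`/`Z_Loc`/`Z_Glob` for the three-layer
#'   architecture), `Z_f`, `p` and `y_hat`.
#' @export
forward <- function(g, params, cfg) {
  if (ncol(g$x_init$X) != cfg$d_init) {
    stop("feature width ", ncol(g$x_init$X), " does not match cfg$d_init = ",
         cfg$d_init)
  }
  tape <- ag_tape_new()
  Pn <- param_nodes(tape, params)
  out <- nn_forward(tape, Pn, graph_data(g, cfg), cfg, training = FALSE)
  p <- as.numeric(1 / (1 + exp(-out$logits$value)))
  nm <- if (cfg$n_layers == 3L) c("Z_Node", "Z_NA", "Z_Loc", "Z_Glob")
        else c("Z_Node", sprintf("Z_scale%d", seq_len(cfg$n_layers)))
  structure(list(Z = stats::setNames(lapply(out$scales, function(s) s$value), nm),
                 Z_f = out$z_f$value, p = p,
                 y_hat = as.integer(p >= 0.5)),
            class = "scale_embeddings")
}

#' Single graph-convolution propagation step
#'
#' @param A_hat Normalized adjacency (see [normalized_adjacency()]).
#' @param X Node feature matrix.
#' @param W Weight matrix.
#' @return `ReLU(A_hat X W)`.
#' @export
gcn_propagate <- function(A_hat, X, W) {
  if (ncol(A_hat) != nrow(X) || ncol(X) != nrow(W)) {
    stop("shape mismatch: A_hat ", paste(dim(A_hat), collapse = "x"),
         ", X ", paste(dim(X), collapse = "x"),
         ", W ", paste(dim(W), collapse = "x"))
  }
  out <- A_hat %*% X %*% W
  out * (out > 0)
}

#' Fuse per-view embeddings of each nucleotide (one view-fusion stage)
#'
#' The view embeddings are treated as a short token sequence per nucleotide;
#' multi-head self-attention mixes the views, a feed-forward network
#' transforms the attention output, and two residual + layer-norm steps give
#' the fused tokens, re-concatenated to width `3 d`.
#'
#' @param H_P,H_S,H_T n x d per-view embeddings (pass `NULL` to drop a view).
#' @param block Named list with `Wq`, `Wk`, `Wv`, `Wo`, `ffn1`, `fb1`,
#'   `ffn2`, `fb2`, `ln1g`, `ln1b`, `ln2g`, `ln2b`.
#' @param n_heads Number of attention heads.
#' @return n x (v d) fused matrix, v the number of non-`NULL` views.
#' @export
view_fuse <- function(H_P, H_S, H_T, block, n_heads = 4L) {
  Hs <- Filter(Negate(is.null), list(H_P, H_S, H_T))
  d <- ncol(Hs[[1]])
  if (nrow(block$Wq) != d) {
    stop("block width ", nrow(block$Wq), " does not match input width ", d)
  }
  tape <- ag_tape_new()
  Pn <- list()
  for (nm in c("Wq", "Wk", "Wv", "Wo")) {
    Pn[[paste0(nm, "1")]] <- ag_const(tape, block[[nm]])
  }
  for (nm in c("ffn1", "fb1", "ffn2", "fb2")) {
    Pn[[paste0(nm, "_1")]] <- ag_const(tape, block[[nm]])
  }
  for (nm in c("ln1g", "ln1b", "ln2g", "ln2b")) {
    Pn[[paste0(nm, "_1")]] <- ag_const(tape, block[[nm]])
  }
  tokens <- lapply(Hs, function(h) ag_const(tape, h))
  cfg <- list(n_heads = as.integer(n_heads), dropout = 0)
  out <- mhvf_on_tape(tape, tokens, Pn, 1L, cfg)
  do.call(cbind, lapply(out$fused, function(f) f$value))
}

#' Build one randomly initialized view-fusion block
#' @param d Model width. @param ffn_mult Inner feed-forward multiple.
#' @param seed Seed.
#' @return Named parameter list accepted by [view_fuse()].
#' @export
mhvf_block <- function(d, ffn_mult = 4L, seed = 1L) {
  set.seed(seed)
  list(Wq = glorot(d, d), Wk = glorot(d, d), Wv = glorot(d, d),
       Wo = glorot(d, d),
       ffn1 = glorot(d, ffn_mult * d), fb1 = matrix(0, 1L, ffn_mult * d),
       ffn2 = glorot(ffn_mult * d, d), fb2 = matrix(0, 1L, d),
       ln1g = matrix(1, 1L, d), ln1b = matrix(0, 1L, d),
       ln2g = matrix(1, 1L, d), ln2b = matrix(0, 1L, d))
}

#' Attentive multi-scale fusion
#'
#' Shared-projection self-attention over the four scale embeddings of each
#' nucleotide, followed by average pooling of the attended tokens.
#'
#' @param Z_Node,Z_NA,Z_Loc,Z_Glob n x d_scale scale embeddings.
#' @param att Named list with projections `Wmq`, `Wmk`, `Wmv`, `Wmo`.
#' @return List with `Z_f` (n x d_scale), the attended tokens `Z_a` and the
#'   attention weight matrix rows for the first token (`weights`, n x 4).
#' @export
multi_scale_fuse <- function(Z_Node, Z_NA, Z_Loc, Z_Glob, att) {
  Zs <- list(Z_Node, Z_NA, Z_Loc, Z_Glob)
  d <- unique(vapply(Zs, ncol, integer(1)))
  if (length(d) != 1L) stop("scale embeddings have mismatched widths")
  tape <- ag_tape_new()
  tokens <- lapply(Zs, function(z) ag_const(tape, z))
  res <- token_attention(tape, tokens,
                         ag_const(tape, att$Wmq), ag_const(tape, att$Wmk),
                         ag_const(tape, att$Wmv), ag_const(tape, att$Wmo),
                         n_heads = 1L, keep_weights = TRUE)
  Z_a <- lapply(res$outs, function(o) o$value)
  list(Z_f = Reduce(`+`, Z_a) / 4, Z_a = Z_a, weights = res$weights[[1]][[1]])
}

#' Classifier head: fused embedding to probability and call
#'
#' @param Z_f n x d fused representation.
#' @param head Named list with `Wc1`, `bc1`, `Wc2`, `bc2`.
#' @return List with `p` (sigmoid probabilities) and `y_hat`
#'   (`p >= 0.5`, boundary positive).
#' @export
classify <- function(Z_f, head) {
  stopifnot(all(is.finite(Z_f)))
  h <- sweep(Z_f %*% head$Wc1, 2L, as.numeric(head$bc1), "+")
  h <- h * (h > 0)
  logit <- as.numeric(h %*% head$Wc2) + as.numeric(head$bc2)
  p <- 1 / (1 + exp(-logit))
  list(p = p, y_hat = as.integer(p >= 0.5))
}
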