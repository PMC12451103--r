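# Minimal reverse-mode automatic differentiation over dense matrices.
#
# Nodes are environments holding a value, an accumulated gradient and a
# backward closure. Nodes are appended to a tape in creation order, which is
# by construction a topological order, so backpropagation is a single reverse
# sweep. Only the operations the network needs are provided; everything works
# on plain numeric matrices.

ag_tape_new <- function() {
  tape <- new.env(parent = emptyenv())
  tape$last <- NULL
  tape
}

# Nodes form a reverse-linked list through $prev: O(1) append, and the
# backward sweep just walks the chain from the most recent node.
ag_node <- function(tape, value, parents = NULL, backfn = NULL, param_name = NULL) {
  node <- new.env(parent = emptyenv())
  node$value <- value
  node$grad <- NULL
  node$backfn <- backfn
  node$param_name <- param_name
  node$rg <- !is.null(parents) &&
    any(vapply(parents, function(p) isTRUE(p$rg), logical(1)))
  node$prev <- tape$last
  tape$last <- node
  node
}

# Gradient accumulation is skipped for nodes that no parameter feeds
# (constants such as adjacency matrices and input features), which keeps the
# backward sweep from materializing large useless gradients.
ag_accum <- function(node, g) {
  if (!isTRUE(node$rg)) return(invisible(NULL))
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
  invisible(NULL)
}

#' @noRd
ag_const <- function(tape, x) {
  ag_node(tape, as.matrix(x))
}

# Leaf tracked as a trainable parameter; gradients are collected by name.
ag_param <- function(tape, x, name) {
  node <- ag_node(tape, as.matrix(x), param_name = name)
  node$rg <- TRUE
  node
}

ag_mm <- function(tape, a, b) {
  out <- ag_node(tape, a$value %*% b$value, list(a, b))
  out$backfn <- function(g) {
    ag_accum(a, g %*% t(b$value))
    ag_accum(b, t(a$value) %*% g)
  }
  out
}

ag_add <- function(tape, a, b) {
  out <- ag_node(tape, a$value + b$value, list(a, b))
  out$backfn <- function(g) {
    ag_accum(a, g)
    ag_accum(b, g)
  }
  out
}

# a is n x d, bias is 1 x d, added to every row
ag_addbias <- function(tape, a, bias) {
  out <- ag_node(tape, sweep(a$value, 2L, as.numeric(bias$value), "+"),
                 list(a, bias))
  out$backfn <- function(g) {
    ag_accum(a, g)
    ag_accum(bias, matrix(colSums(g), nrow = 1L))
  }
  out
}

ag_mul <- function(tape, a, b) {
  out <- ag_node(tape, a$value * b$value, list(a, b))
  out$backfn <- function(g) {
    ag_accum(a, g * b$value)
    ag_accum(b, g * a$value)
  }
  out
}

ag_scale <- function(tape, a, s) {
  out <- ag_node(tape, a$value * s, list(a))
  out$backfn <- function(g) ag_accum(a, g * s)
  out
}

ag_relu <- function(tape, a) {
  mask <- a$value > 0
  out <- ag_node(tape, a$value * mask, list(a))
  out$backfn <- function(g) ag_accum(a, g * mask)
  out
}

# Inverted dropout; identity when rate == 0. Mask drawn from the session RNG
# so training runs are reproducible under set.seed().
ag_dropout <- function(tape, a, rate) {
  if (rate <= 0) return(a)
  keep <- matrix(stats::runif(length(a$value)) >= rate, nrow(a$value))
  scl <- 1 / (1 - rate)
  out <- ag_node(tape, a$value * keep * scl, list(a))
  out$backfn <- function(g) ag_accum(a, g * keep * scl)
  out
}

# column-broadcast: multiply every column of a (n x d) by s (n x 1)
ag_colscale <- function(tape, a, s) {
  sv <- as.numeric(s$value)
  out <- ag_node(tape, a$value * sv, list(a, s))
  out$backfn <- function(g) {
    ag_accum(a, g * sv)
    ag_accum(s, matrix(rowSums(g * a$value), ncol = 1L))
  }
  out
}

ag_rowsums <- function(tape, a) {
  out <- ag_node(tape, matrix(rowSums(a$value), ncol = 1L), list(a))
  out$backfn <- function(g) {
    ag_accum(a, matrix(as.numeric(g), nrow(a$value), ncol(a$value)))
  }
  out
}

ag_concat_cols <- function(tape, xs) {
  vals <- lapply(xs, function(x) x$value)
  widths <- vapply(vals, ncol, integer(1))
  out <- ag_node(tape, do.call(cbind, vals), xs)
  out$backfn <- function(g) {
    at <- 0L
    for (i in seq_along(xs)) {
      ag_accum(xs[[i]], g[, at + seq_len(widths[i]), drop = FALSE])
      at <- at + widths[i]
    }
  }
  out
}

ag_slice_cols <- function(tape, a, cols) {
  out <- ag_node(tape, a$value[, cols, drop = FALSE], list(a))
  out$backfn <- function(g) {
    full <- matrix(0, nrow(a$value), ncol(a$value))
    full[, cols] <- g
    ag_accum(a, full)
  }
  out
}

ag_softmax_rows <- function(tape, a) {
  z <- a$value - apply(a$value, 1L, max)
  e <- exp(z)
  p <- e / rowSums(e)
  out <- ag_node(tape, p, list(a))
  out$backfn <- function(g) {
    dot <- rowSums(g * p)
    ag_accum(a, p * (g - dot))
  }
  out
}

# Layer normalization over the feature (column) axis of each row, with
# learnable gain/bias (1 x d each).
ag_layernorm <- function(tape, a, gamma, beta, eps = 1e-5) {
  x <- a$value
  d <- ncol(x)
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  gam <- as.numeric(gamma$value)
  out <- ag_node(tape, sweep(xhat, 2L, gam, "*") +
                   matrix(as.numeric(beta$value), nrow(x), d, byrow = TRUE),
                 list(a, gamma, beta))
  out$backfn <- function(g) {
    ag_accum(gamma, matrix(colSums(g * xhat), nrow = 1L))
    ag_accum(beta, matrix(colSums(g), nrow = 1L))
    gh <- sweep(g, 2L, gam, "*")
    # d xhat/dx of row-wise standardization
    term1 <- gh
    term2 <- rowMeans(gh)
    term3 <- xhat * rowMeans(gh * xhat)
    ag_accum(a, inv * (term1 - term2 - term3))
  }
  out
}

# Weighted mean binary cross-entropy with logits; y is a plain numeric
# vector in {0,1}. Positive examples carry weight pos_weight (1 = plain
# BCE). Numerically stable log(1 + exp(-|z|)) form. Returns a 1x1 node.
ag_bce_logits <- function(tape, logits, y, pos_weight = 1) {
  z <- as.numeric(logits$value)
  n <- length(z)
  stopifnot(length(y) == n)
  w <- ifelse(y == 1, pos_weight, 1)
  sw <- sum(w)
  loss <- sum(w * (pmax(z, 0) - z * y + log1p(exp(-abs(z))))) / sw
  p <- 1 / (1 + exp(-z))
  out <- ag_node(tape, matrix(loss), list(logits))
  out$backfn <- function(g) {
    ag_accum(logits, matrix(w * (p - y) * as.numeric(g) / sw, ncol = 1L))
  }
  out
}

# Sum of scalar (1x1) nodes, each with a numeric weight.
ag_wsum <- function(tape, xs, w) {
  out <- ag_node(tape, matrix(sum(vapply(seq_along(xs), function(i)
    xs[[i]]$value[1L, 1L] * w[i], numeric(1)))), xs)
  out$backfn <- function(g) {
    for (i in seq_along(xs)) ag_accum(xs[[i]], matrix(w[i] * as.numeric(g)))
  }
  out
}

# Reverse sweep from the most recent node back to the leaves. Gradients of
# tracked parameters are read off their nodes afterwards (ag_param_grads).
ag_backward <- function(tape, root) {
  stopifnot(length(root$value) == 1L)
  root$grad <- matrix(1)
  node <- tape$last
  while (!is.null(node)) {
    if (!is.null(node$backfn) && !is.null(node$grad)) node$backfn(node$grad)
    node <- node$prev
  }
  invisible(NULL)
}

# Named gradient list from the parameter nodes created by param_nodes().
ag_param_grads <- function(param_node_list) {
  out <- lapply(param_node_list, function(nd) nd$grad)
  out[!vapply(out, is.null, logical(1))]
}
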