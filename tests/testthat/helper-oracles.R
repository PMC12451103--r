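# Independent brute-force oracles. These deliberately avoid the package's
# own code paths (and igraph): metrics from direct formulas and pairwise
# counting, graph measures from explicit BFS / path enumeration, and a
# straight-line, loop-based evaluation of the network equations.

## ---- classification metrics ----

oracle_metrics <- function(y, p, threshold = 0.5) {
  yh <- ifelse(p >= threshold, 1L, 0L)
  tp <- sum(yh == 1 & y == 1); fp <- sum(yh == 1 & y == 0)
  tn <- sum(yh == 0 & y == 0); fn <- sum(yh == 0 & y == 1)
  prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
  rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
  den <- sqrt(as.numeric(tp + fp)) * sqrt(as.numeric(tp + fn)) *
    sqrt(as.numeric(tn + fp)) * sqrt(as.numeric(tn + fn))
  mcc <- if (den == 0) 0 else (as.numeric(tp) * tn - as.numeric(fp) * fn) / den
  # AUC by exhaustive positive-negative pair counting (ties count 1/2)
  pos <- p[y == 1]; neg <- p[y == 0]
  auc <- if (length(pos) == 0 || length(neg) == 0) NA_real_ else {
    s <- 0
    for (a in pos) for (b in neg) s <- s + (a > b) + 0.5 * (a == b)
    s / (length(pos) * length(neg))
  }
  list(TP = tp, FP = fp, TN = tn, FN = fn, precision = prec, recall = rec,
       mcc = mcc, auc = auc)
}

## ---- graph topology ----

# adjacency list from a 0-based edge matrix
oracle_adj <- function(edges, n) {
  adj <- rep(list(integer(0)), n)
  if (NROW(edges) > 0) {
    for (r in seq_len(nrow(edges))) {
      i <- edges[r, 1] + 1L; j <- edges[r, 2] + 1L
      adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
    }
  }
  adj
}

oracle_bfs_dist <- function(adj, s) {
  n <- length(adj)
  d <- rep(NA_integer_, n); d[s] <- 0L
  q <- s
  while (length(q) > 0) {
    v <- q[1]; q <- q[-1]
    for (w in adj[[v]]) if (is.na(d[w])) { d[w] <- d[v] + 1L; q <- c(q, w) }
  }
  d
}

# enumerate all shortest paths between s and t by depth-first search over
# simple paths, then count how many pass through each interior vertex
oracle_shortest_paths <- function(adj, s, t, dmat) {
  if (is.na(dmat[s, t])) return(list())
  paths <- list()
  walk <- function(path) {
    v <- path[length(path)]
    if (v == t) { paths[[length(paths) + 1L]] <<- path; return(invisible()) }
    for (w in adj[[v]]) {
      # only extend along shortest-path structure
      if (!is.na(dmat[w, t]) && dmat[v, t] == dmat[w, t] + 1L) {
        walk(c(path, w))
      }
    }
  }
  walk(s)
  paths
}

oracle_topology <- function(edges, n) {
  adj <- oracle_adj(edges, n)
  deg <- vapply(adj, length, integer(1))
  nc <- vapply(seq_len(n), function(i)
    if (deg[i] == 0) 0 else mean(deg[adj[[i]]]), numeric(1))
  dmat <- t(vapply(seq_len(n), function(s) oracle_bfs_dist(adj, s),
                   integer(n)))
  # betweenness via explicit shortest-path enumeration
  btw <- numeric(n)
  if (n > 2) {
    for (s in 1:(n - 1)) for (t in (s + 1):n) {
      paths <- oracle_shortest_paths(adj, s, t, dmat)
      if (length(paths) == 0) next
      for (pth in paths) {
        interior <- setdiff(pth, c(s, t))
        btw[interior] <- btw[interior] + 1 / length(paths)
      }
    }
    btw <- btw / ((n - 1) * (n - 2) / 2)
  }
  cc <- vapply(seq_len(n), function(i) {
    if (deg[i] < 2) return(0)
    nb <- adj[[i]]
    links <- 0
    for (a in seq_along(nb)) for (b in seq_along(nb)) {
      if (a < b && nb[b] %in% adj[[nb[a]]]) links <- links + 1
    }
    2 * links / (deg[i] * (deg[i] - 1))
  }, numeric(1))
  ecc <- vapply(seq_len(n), function(i) {
    max(dmat[i, !is.na(dmat[i, ])])
  }, numeric(1))
  cbind(degree = deg, nbr_connectivity = nc, betweenness = btw,
        clustering = cc, eccentricity = ecc)
}

# every labeled simple graph on n nodes, as a list of edge matrices
all_graphs <- function(n) {
  pairs <- t(combn(n, 2)) - 1L
  m <- nrow(pairs)
  lapply(0:(2^m - 1), function(code) {
    keep <- bitwAnd(code, 2^(seq_len(m) - 1)) > 0
    pairs[keep, , drop = FALSE]
  })
}

random_graph <- function(n, p = 0.4) {
  pairs <- t(combn(n, 2)) - 1L
  pairs[runif(nrow(pairs)) < p, , drop = FALSE]
}

## ---- binding-site labels ----

oracle_labels <- function(record, cutoff = 4.0) {
  lig <- do.call(rbind, lapply(record$ligands, function(l)
    cbind(l$atoms$x, l$atoms$y, l$atoms$z)))
  vapply(record$residues, function(res) {
    best <- Inf
    for (a in seq_len(nrow(res$atoms))) {
      for (b in seq_len(nrow(lig))) {
        d <- sqrt((res$atoms$x[a] - lig[b, 1])^2 +
                    (res$atoms$y[a] - lig[b, 2])^2 +
                    (res$atoms$z[a] - lig[b, 3])^2)
        best <- min(best, d)
      }
    }
    as.integer(best <= cutoff)
  }, integer(1))
}

## ---- straight-line network oracle ----

oracle_mm <- function(a, b) {
  out <- matrix(0, nrow(a), ncol(b))
  for (i in seq_len(nrow(a))) for (j in seq_len(ncol(b))) {
    out[i, j] <- sum(a[i, ] * b[, j])
  }
  out
}

oracle_norm_adj <- function(edges, n) {
  A <- diag(n)
  if (NROW(edges) > 0) {
    for (r in seq_len(nrow(edges))) {
      A[edges[r, 1] + 1, edges[r, 2] + 1] <- 1
      A[edges[r, 2] + 1, edges[r, 1] + 1] <- 1
    }
  }
  out <- matrix(0, n, n)
  dg <- rowSums(A)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    out[i, j] <- A[i, j] / sqrt(dg[i] * dg[j])
  }
  out
}

oracle_ln <- function(v, gamma, beta, eps = 1e-5) {
  mu <- mean(v)
  va <- mean((v - mu)^2)
  gamma * (v - mu) / sqrt(va + eps) + beta
}

# one view-fusion stage for a list of per-view matrices, nucleotide by
# nucleotide and head by head
oracle_mhvf <- function(H_list, P, l, n_heads) {
  m <- length(H_list)
  n <- nrow(H_list[[1]])
  d <- ncol(H_list[[1]])
  dh <- d / n_heads
  Wq <- P[[paste0("Wq", l)]]; Wk <- P[[paste0("Wk", l)]]
  Wv <- P[[paste0("Wv", l)]]; Wo <- P[[paste0("Wo", l)]]
  fused <- vector("list", m)
  for (a in seq_len(m)) fused[[a]] <- matrix(0, n, d)
  for (i in seq_len(n)) {
    toks <- lapply(H_list, function(H) H[i, ])
    q <- lapply(toks, function(t) as.numeric(oracle_mm(matrix(t, 1), Wq)))
    k <- lapply(toks, function(t) as.numeric(oracle_mm(matrix(t, 1), Wk)))
    v <- lapply(toks, function(t) as.numeric(oracle_mm(matrix(t, 1), Wv)))
    for (a in seq_len(m)) {
      head_cat <- numeric(0)
      for (h in seq_len(n_heads)) {
        cols <- ((h - 1) * dh + 1):(h * dh)
        scores <- vapply(seq_len(m), function(b)
          sum(q[[a]][cols] * k[[b]][cols]) / sqrt(dh), numeric(1))
        w <- exp(scores - max(scores)); w <- w / sum(w)
        ho <- numeric(dh)
        for (b in seq_len(m)) ho <- ho + w[b] * v[[b]][cols]
        head_cat <- c(head_cat, ho)
      }
      attn <- as.numeric(oracle_mm(matrix(head_cat, 1), Wo))
      res1 <- oracle_ln(toks[[a]] + attn, P[[paste0("ln1g_", l)]][1, ],
                        P[[paste0("ln1b_", l)]][1, ])
      hid <- as.numeric(oracle_mm(matrix(attn, 1), P[[paste0("ffn1_", l)]])) +
        P[[paste0("fb1_", l)]][1, ]
      hid <- pmax(hid, 0)
      ffn <- as.numeric(oracle_mm(matrix(hid, 1), P[[paste0("ffn2_", l)]])) +
        P[[paste0("fb2_", l)]][1, ]
      fused[[a]][i, ] <- oracle_ln(res1 + ffn, P[[paste0("ln2g_", l)]][1, ],
                                   P[[paste0("ln2b_", l)]][1, ])
    }
  }
  fused
}

# full forward pass: graph convolutions, view fusion with the asymmetric
# layer wiring, scale embeddings, multi-scale attention, classifier
oracle_forward <- function(g, P, cfg) {
  views <- cfg$views
  X <- g$x_init$X
  n <- nrow(X)
  Ah <- lapply(g$graphs[views], function(vg) oracle_norm_adj(vg$edges, vg$n))
  inputs <- setNames(rep(list(X), length(views)), views)
  fused_prev <- NULL
  Zs <- list()
  for (l in seq_len(cfg$n_layers)) {
    H <- list()
    for (k in views) {
      x_in <- if (l > 1 && k == "T") fused_prev else inputs[[k]]
      h <- oracle_mm(oracle_mm(Ah[[k]], x_in), P[[sprintf("gcn%d_%s", l, k)]])
      H[[k]] <- pmax(h, 0)
    }
    fused_toks <- oracle_mhvf(unname(H[views]), P, l, cfg$n_heads)
    fused_prev <- do.call(cbind, fused_toks)
    inputs <- H
    z <- oracle_mm(fused_prev, P[[paste0("Wz1_", l)]])
    z <- sweep(z, 2, P[[paste0("bz1_", l)]][1, ], "+")
    z <- pmax(z, 0)
    z <- oracle_mm(z, P[[paste0("Wz2_", l)]])
    Zs[[l]] <- sweep(z, 2, P[[paste0("bz2_", l)]][1, ], "+")
  }
  z_node <- sweep(oracle_mm(X, P$Wnode), 2, P$bnode[1, ], "+")
  scales <- c(list(z_node), Zs)
  if (cfg$msf) {
    ds <- cfg$d_scale
    z_f <- matrix(0, n, ds)
    for (i in seq_len(n)) {
      toks <- lapply(scales, function(Z) Z[i, ])
      q <- lapply(toks, function(t) as.numeric(oracle_mm(matrix(t, 1), P$Wmq)))
      k <- lapply(toks, function(t) as.numeric(oracle_mm(matrix(t, 1), P$Wmk)))
      v <- lapply(toks, function(t) as.numeric(oracle_mm(matrix(t, 1), P$Wmv)))
      acc <- numeric(ds)
      for (a in seq_along(toks)) {
        scores <- vapply(seq_along(toks), function(b)
          sum(q[[a]] * k[[b]]) / sqrt(ds), numeric(1))
        w <- exp(scores - max(scores)); w <- w / sum(w)
        att <- numeric(ds)
        for (b in seq_along(toks)) att <- att + w[b] * v[[b]]
        acc <- acc + as.numeric(oracle_mm(matrix(att, 1), P$Wmo))
      }
      z_f[i, ] <- acc / length(toks)
    }
  } else {
    z_f <- do.call(cbind, scales)
  }
  hid <- sweep(oracle_mm(z_f, P$Wc1), 2, P$bc1[1, ], "+")
  hid <- pmax(hid, 0)
  logit <- as.numeric(oracle_mm(hid, P$Wc2)) + P$bc2[1, 1]
  list(p = 1 / (1 + exp(-logit)), z_f = z_f)
}
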