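#' Per-position evolutionary conservation from an MSA
#'
#' For each alignment column mapped to a non-gap query position, nucleotide
#' frequencies `f_i` are computed over A/U/G/C, ignoring gaps, and the score is
#' `1 - H / Hmax` with `H = -sum f_i log2 f_i` the Shannon entropy and
#' `Hmax = log2(4) = 2` the maximum for a four-letter alphabet. Fully
#' conserved columns score 1, maximally variable columns 0. Gaps are excluded
#' from the frequencies so that they sum to one over the four nucleotides,
#' keeping 2 bits the correct normalizer. Columns where the query is the only
#' non-gap row carry no evolutionary signal and score 0 with a warning.
#'
#' @param msa An `msa_record`.
#' @return Numeric vector of scores in [0, 1], one per ungapped query
#'   position.
#' @export
conservation_scores <- function(msa) {
  stopifnot(inherits(msa, "msa_record"))
  m <- msa$seqs
  if (nrow(m) == 0L || ncol(m) == 0L) stop("empty alignment")
  qpos <- which(m[msa$query_row, ] != "-")
  scores <- numeric(length(qpos))
  lonely <- 0L
  for (k in seq_along(qpos)) {
    col <- m[, qpos[k]]
    nucs <- col[col %in% c("A", "U", "G", "C")]
    if (sum(col != "-") <= 1L) {
      lonely <- lonely + 1L
      scores[k] <- 0
      next
    }
    f <- table(factor(nucs, levels = c("A", "U", "G", "C"))) / length(nucs)
    f <- f[f > 0]
    H <- -sum(f * log2(f))
    scores[k] <- min(max(1 - H / 2, 0), 1)
  }
  if (lonely > 0L) {
    warning(lonely, " column(s) had no aligned sequence besides the query; scored 0")
  }
  scores
}

#' One-hot encode a nucleotide sequence
#'
#' Channel order is fixed as (A, U, G, C); any base outside the four standard
#' nucleotides (reported as `"other"`) yields an all-zero row.
#'
#' @param bases Character vector of base symbols.
#' @return n x 4 binary matrix with columns A, U, G, C.
#' @export
one_hot_encode <- function(bases) {
  lv <- c("A", "U", "G", "C")
  out <- matrix(0, length(bases), 4L, dimnames = list(NULL, lv))
  hit <- match(bases, lv)
  ok <- !is.na(hit)
  out[cbind(which(ok), hit[ok])] <- 1
  out
}

#' Five-column secondary-structure feature block
#'
#' Column 1 is the nucleotide's integer degree in the secondary-structure
#' graph (backbone plus annotated interactions); columns 2-5 are presence
#' flags for base-ribose contacts, base-phosphate contacts, non-canonical
#' pairs and loop membership.
#'
#' @param annotation A `secondary_annotation`.
#' @return n x 5 matrix with columns `degree`, `base_ribose`,
#'   `base_phosphate`, `noncanonical`, `loop`.
#' @export
secondary_feature_vector <- function(annotation) {
  n <- annotation$n
  g <- build_secondary_graph(annotation)
  deg <- numeric(n)
  if (nrow(g$edges) > 0L) {
    tab <- table(factor(c(g$edges[, 1], g$edges[, 2]), levels = 0:(n - 1L)))
    deg <- as.numeric(tab)
  }
  inter <- annotation$interactions
  flag_of <- function(kind) {
    f <- numeric(n)
    sel <- inter$kind == kind
    f[c(inter$i[sel], inter$j[sel]) + 1L] <- 1
    f
  }
  out <- cbind(degree = deg,
               base_ribose = flag_of("base_ribose"),
               base_phosphate = flag_of("base_phosphate"),
               noncanonical = flag_of("noncanonical_pair"),
               loop = as.numeric(annotation$loop_member))
  out
}

#' Graph-topological node properties
#'
#' Per node: degree; neighborhood connectivity (mean degree of neighbours, 0
#' for isolated nodes); betweenness centrality normalized by
#' `(n-1)(n-2)/2`; local clustering coefficient (0 when degree < 2); and
#' eccentricity within the node's connected component. These are the
#' network-topology descriptors used as tertiary-structure features,
#' conventionally computed on the spatial proximity graph.
#'
#' @param edges m x 2 matrix of 0-based undirected edges (no self-loops).
#' @param n Node count.
#' @return n x 5 matrix with columns `degree`, `nbr_connectivity`,
#'   `betweenness`, `clustering`, `eccentricity`.
#' @export
topological_properties <- function(edges, n) {
  if (n == 0L) stop("empty graph (n = 0)")
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (NROW(edges) > 0L) {
    g <- igraph::add_edges(g, as.integer(t(edges)) + 1L)
  }
  deg <- igraph::degree(g)
  adj <- igraph::as_adj_list(g)
  nc <- vapply(seq_len(n), function(i) {
    nb <- as.integer(adj[[i]])
    if (length(nb) == 0L) 0 else mean(deg[nb])
  }, numeric(1))
  btw <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  btw <- if (n > 2L) btw / ((n - 1) * (n - 2) / 2) else numeric(n)
  cc <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  cc[deg < 2] <- 0
  ecc <- igraph::eccentricity(g, mode = "all")
  cbind(degree = deg, nbr_connectivity = nc, betweenness = btw,
        clustering = cc, eccentricity = as.numeric(ecc))
}

# layout of the initial feature matrix; conservation, embeddings and ASA are
# optional and zero-filled when absent
feature_block_map <- function(d_emb) {
  widths <- c(conservation = 1L, embedding = as.integer(d_emb),
              one_hot = 4L, secondary = 5L, topological = 5L, asa = 1L)
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  map <- Map(function(s, e) s:e, starts, ends)
  names(map) <- names(widths)
  map
}

#' Column means/sds of the continuous feature columns
#'
#' Computed over the rows of the supplied raw feature matrices (typically the
#' training split only, so that evaluation data never leaks into the
#' standardization) and passed to [assemble_features()] / applied with
#' [standardize_features()]. Flag columns (one-hot, secondary presence flags)
#' are excluded.
#'
#' @param X_list List of raw `node_feature_matrix` objects sharing a layout.
#' @return List with `mean`, `sd` (per continuous column) and `cols`.
#' @export
feature_stats <- function(X_list) {
  stopifnot(length(X_list) >= 1L)
  map <- X_list[[1]]$block_map
  cols <- continuous_cols(map)
  X <- do.call(rbind, lapply(X_list, function(x) x$X[, cols, drop = FALSE]))
  s <- apply(X, 2L, stats::sd)
  s[s == 0 | !is.finite(s)] <- 1
  list(mean = colMeans(X), sd = s, cols = cols)
}

continuous_cols <- function(map) {
  c(map$conservation, map$embedding, map$secondary[1], map$topological, map$asa)
}

#' Assemble the initial per-nucleotide feature matrix
#'
#' Concatenates the feature blocks in the fixed layout
#' `[conservation | embedding | one_hot | secondary | topological | asa]`.
#' Optional blocks (`conservation`, `embeddings`, `asa`) may be `NULL` and
#' are zero-filled, keeping the width stable; the block map records which
#' blocks were supplied. When `stats` (from [feature_stats()]) is given,
#' continuous columns are z-scored with those frozen statistics; flag columns
#' are never touched.
#'
#' @param one_hot n x 4 one-hot block.
#' @param secondary n x 5 secondary block.
#' @param topological n x 5 topological block.
#' @param conservation Optional length-n score vector.
#' @param embeddings Optional n x d_emb matrix of precomputed embeddings.
#' @param asa Optional length-n solvent-accessibility vector.
#' @param d_emb Embedding width used when `embeddings` is `NULL`.
#' @param stats Optional output of [feature_stats()].
#' @return A `node_feature_matrix`: list with matrix `X`, `block_map` and
#'   `provided` flags.
#' @export
assemble_features <- function(one_hot, secondary, topological,
                              conservation = NULL, embeddings = NULL,
                              asa = NULL, d_emb = 120L, stats = NULL) {
  n <- nrow(one_hot)
  check <- function(block, name, width = NULL) {
    if (is.null(block)) return(invisible(NULL))
    rows <- if (is.matrix(block)) nrow(block) else length(block)
    if (rows != n) stop("block '", name, "' has ", rows, " rows, expected ", n)
    if (!is.null(width) && is.matrix(block) && ncol(block) != width) {
      stop("block '", name, "' has width ", ncol(block), ", expected ", width)
    }
    invisible(NULL)
  }
  check(secondary, "secondary", 5L)
  check(topological, "topological", 5L)
  check(conservation, "conservation")
  check(embeddings, "embedding")
  check(asa, "asa")
  if (!is.null(embeddings)) d_emb <- ncol(embeddings)
  map <- feature_block_map(d_emb)
  X <- matrix(0, n, max(map$asa))
  X[, map$one_hot] <- one_hot
  X[, map$secondary] <- secondary
  X[, map$topological] <- topological
  if (!is.null(conservation)) X[, map$conservation] <- conservation
  if (!is.null(embeddings)) X[, map$embedding] <- embeddings
  if (!is.null(asa)) X[, map$asa] <- asa
  if (any(!is.finite(X))) stop("non-finite feature values")
  out <- structure(list(
    X = X, block_map = map,
    provided = c(conservation = !is.null(conservation),
                 embedding = !is.null(embeddings), asa = !is.null(asa))),
    class = "node_feature_matrix")
  if (!is.null(stats)) out <- standardize_features(out, stats)
  out
}

#' Apply frozen standardization statistics to a feature matrix
#' @param nfm A `node_feature_matrix`.
#' @param stats Output of [feature_stats()].
#' @return The standardized `node_feature_matrix`.
#' @export
standardize_features <- function(nfm, stats) {
  cols <- stats$cols
  nfm$X[, cols] <- sweep(sweep(nfm$X[, cols, drop = FALSE], 2L, stats$mean), 2L,
                         stats$sd, "/")
  nfm
}

#' Zero one view's feature block (feature-ablation switch)
#'
#' `"prim"` zeroes conservation, embedding and one-hot columns; `"sec"` the
#' secondary block; `"ter"` the topological and ASA columns.
#'
#' @param nfm A `node_feature_matrix`.
#' @param view One of `"prim"`, `"sec"`, `"ter"`.
#' @return The modified `node_feature_matrix`.
#' @export
zero_feature_block <- function(nfm, view) {
  map <- nfm$block_map
  cols <- switch(view,
    prim = c(map$conservation, map$embedding, map$one_hot),
    sec = map$secondary,
    ter = c(map$topological, map$asa),
    stop("unknown view '", view, "'"))
  nfm$X[, cols] <- 0
  nfm
}

#' Geometric stand-in for solvent accessibility
#'
#' Counts neighbouring residues within `radius` Angstrom of each
#' representative coordinate and negates the count, so exposed residues
#' score high like a true accessible-surface area would. This is a
#' non-canonical geometric proxy for use when no precomputed accessibility
#' table is available; it is not an ASA calculation.
#'
#' @param coords n x 3 representative coordinates (Angstrom).
#' @param radius Neighbourhood radius, Angstrom (default 8).
#' @return Numeric vector of length n (negated burial counts).
#' @export
asa_geometric_proxy <- function(coords, radius = 8) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 3L, all(is.finite(coords)))
  d <- as.matrix(stats::dist(coords))
  unname(-(rowSums(d <= radius) - 1))
}
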