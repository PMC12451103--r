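# View graphs over nucleotides. Edges are stored as an m x 2 integer matrix
# of 0-based unordered pairs with i < j and no self-loops; self-loops enter
# only inside normalized_adjacency() (Kipf-style renormalization).

view_graph <- function(view, n, edges) {
  stopifnot(view %in% c("P", "S", "T"), n >= 1L)
  edges <- unique(edges)
  if (nrow(edges) > 0L) {
    stopifnot(all(edges[, 1] < edges[, 2]), all(edges >= 0L), all(edges < n))
  }
  structure(list(view = view, n = as.integer(n),
                 edges = matrix(as.integer(edges), ncol = 2L)),
            class = "view_graph")
}

#' @export
print.view_graph <- function(x, ...) {
  cat(sprintf("view_graph [%s]: %d nodes, %d edges\n", x$view, x$n, nrow(x$edges)))
  invisible(x)
}

# union-symmetrized k-nearest-neighbour selection under a distance matrix,
# ties broken toward the lower index
knn_edges <- function(dist_mat, k) {
  n <- nrow(dist_mat)
  if (n < 2L) return(matrix(integer(0), ncol = 2L))
  kk <- min(k, n - 1L)
  pairs <- matrix(integer(0), ncol = 2L)
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    ord <- others[order(dist_mat[i, others], others)]
    sel <- ord[seq_len(kk)]
    pairs <- rbind(pairs, cbind(pmin(i, sel) - 1L, pmax(i, sel) - 1L))
  }
  unique(pairs)
}

#' Primary-structure (sequence) k-nearest-neighbour graph
#'
#' Connects each nucleotide to its `min(k, n-1)` nearest neighbours by
#' sequence separation `|i - j|`, ties broken toward the lower index, and
#' symmetrizes the union of the directed selections.
#'
#' @param n Number of nucleotides.
#' @param k Neighbourhood size (default 13).
#' @return A `view_graph` with view `"P"`.
#' @export
build_primary_graph <- function(n, k = 13L) {
  stopifnot(n >= 1L, k >= 1L)
  idx <- seq_len(n)
  d <- abs(outer(idx, idx, "-"))
  view_graph("P", n, knn_edges(d, k))
}

#' Tertiary-structure (3D) k-nearest-neighbour graph
#'
#' @param coords n x 3 matrix of representative coordinates (Angstrom), one
#'   per nucleotide (see [representative_coords()]).
#' @param k Neighbourhood size (default 8).
#' @return A `view_graph` with view `"T"`.
#' @export
build_tertiary_graph <- function(coords, k = 8L) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 3L, k >= 1L)
  if (any(!is.finite(coords))) stop("non-finite coordinates")
  d <- as.matrix(stats::dist(coords))
  view_graph("T", nrow(coords), knn_edges(d, k))
}

#' Secondary-structure graph
#'
#' Backbone adjacency `(i, i+1)` plus every annotated interaction pair
#' (canonical and non-canonical base pairs, base-ribose and base-phosphate
#' contacts), deduplicated.
#'
#' @param annotation A `secondary_annotation`.
#' @return A `view_graph` with view `"S"`.
#' @export
build_secondary_graph <- function(annotation) {
  n <- annotation$n
  backbone <- if (n >= 2L) cbind(0:(n - 2L), 1:(n - 1L)) else matrix(integer(0), ncol = 2L)
  inter <- annotation$interactions
  extra <- if (nrow(inter) > 0L) cbind(inter$i, inter$j) else matrix(integer(0), ncol = 2L)
  view_graph("S", n, unique(rbind(backbone, extra)))
}

#' Representative coordinate per nucleotide
#'
#' C4' atom when present, otherwise the centroid of the residue's atoms.
#' `atom` may be set to `"C1'"` or `"centroid"` instead.
#'
#' @param record A `structure_record`.
#' @param atom Atom choice: `"C4'"` (default), `"C1'"` or `"centroid"`.
#' @return n x 3 coordinate matrix.
#' @export
representative_coords <- function(record, atom = "C4'") {
  stopifnot(atom %in% c("C4'", "C1'", "centroid"))
  t(vapply(record$residues, function(res) {
    a <- res$atoms
    if (atom != "centroid") {
      hit <- which(a$atom_name == atom)
      if (length(hit) > 0L) return(c(a$x[hit[1]], a$y[hit[1]], a$z[hit[1]]))
    }
    c(mean(a$x), mean(a$y), mean(a$z))
  }, numeric(3)))
}

#' Label binding-site nucleotides by ligand contact distance
#'
#' A nucleotide is a binding site (label 1) when at least one of its atoms
#' lies within `cutoff` Angstrom (inclusive) of any ligand heavy atom. All
#' residue atoms, backbone included, participate.
#'
#' @param record A `structure_record`.
#' @param cutoff Contact distance in Angstrom (default 4.0).
#' @return Integer vector of 0/1 labels, one per residue.
#' @export
assign_labels <- function(record, cutoff = 4.0) {
  n <- n_residues(record)
  if (length(record$ligands) == 0L) {
    warning("no ligand present; all labels 0")
    return(integer(n))
  }
  lig <- do.call(rbind, lapply(record$ligands, function(l)
    cbind(l$atoms$x, l$atoms$y, l$atoms$z)))
  vapply(record$residues, function(res) {
    ra <- cbind(res$atoms$x, res$atoms$y, res$atoms$z)
    d2 <- outer(rowSums(ra^2), rowSums(lig^2), "+") - 2 * ra %*% t(lig)
    as.integer(min(d2) <= cutoff^2 + 1e-12)
  }, integer(1))
}

#' Symmetric degree-normalized adjacency with self-loops
#'
#' Computes `D^{-1/2} (A + I) D^{-1/2}` with `D` the degree matrix of
#' `A + I`, the renormalized propagation operator of graph convolutional
#' networks.
#'
#' @param graph A `view_graph`.
#' @return Dense n x n matrix.
#' @export
normalized_adjacency <- function(graph) {
  n <- graph$n
  A <- diag(n)
  if (nrow(graph$edges) > 0L) {
    ii <- graph$edges[, 1] + 1L
    jj <- graph$edges[, 2] + 1L
    A[cbind(ii, jj)] <- 1
    A[cbind(jj, ii)] <- 1
  }
  dinv <- 1 / sqrt(rowSums(A))
  A * outer(dinv, dinv)
}

#' Bundle one RNA's three view graphs, features and labels
#'
#' @param chain_id Chain identifier.
#' @param x_init A `node_feature_matrix` (see [assemble_features()]).
#' @param graphs Named list with elements `P`, `S`, `T` of `view_graph`s
#'   sharing the same node count.
#' @param y Integer 0/1 label vector of length n.
#' @return A `multi_view_graph`.
#' @export
multi_view_graph <- function(chain_id, x_init, graphs, y) {
  stopifnot(all(c("P", "S", "T") %in% names(graphs)))
  n <- graphs$P$n
  stopifnot(graphs$S$n == n, graphs$T$n == n,
            nrow(x_init$X) == n, length(y) == n, all(y %in% c(0L, 1L)))
  structure(list(chain_id = chain_id, x_init = x_init, graphs = graphs,
                 y = as.integer(y)),
            class = "multi_view_graph")
}

#' @export
print.multi_view_graph <- function(x, ...) {
  cat(sprintf("multi_view_graph '%s': %d nucleotides (%d binding), d_init = %d\n",
              x$chain_id, length(x$y), sum(x$y), ncol(x$x_init$X)))
  invisible(x)
}
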