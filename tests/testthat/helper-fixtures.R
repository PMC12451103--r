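# Fixture builders shared across the test files. Everything is generated in
# code; no binary or downloaded data.

# hand-written minimal PDB text: `residues` rows of (base, x, y, z) with one
# C4' atom each, plus optional ligand atoms as HETATM records
tiny_pdb_text <- function(residues, ligand_atoms = NULL, het_code = "LIG",
                          chain = "A", extra_lines = character(0)) {
  lines <- character(0)
  serial <- 0L
  for (r in seq_len(nrow(residues))) {
    serial <- serial + 1L
    lines <- c(lines, sprintf(
      "ATOM  %5d  C4' %-3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
      serial, residues$base[r], chain, r,
      residues$x[r], residues$y[r], residues$z[r]))
  }
  if (!is.null(ligand_atoms)) {
    for (r in seq_len(nrow(ligand_atoms))) {
      serial <- serial + 1L
      lines <- c(lines, sprintf(
        "HETATM%5d  C%-2d %-3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
        serial, r, het_code, "L", 900L,
        ligand_atoms$x[r], ligand_atoms$y[r], ligand_atoms$z[r]))
    }
  }
  paste(c(lines, extra_lines, "END"), collapse = "\n")
}

three_res_pdb <- function(with_water = FALSE) {
  res <- data.frame(base = c("A", "C", "G"),
                    x = c(0, 6, 12), y = 0, z = 0)
  lig <- data.frame(x = c(2, 3), y = 3, z = 0)
  extra <- if (with_water) {
    "HETATM   99  O   HOH L 950      50.000  50.000  50.000  1.00  0.00"
  } else character(0)
  tiny_pdb_text(res, lig, extra_lines = extra)
}

# a small multi-view graph with random features, suitable for forward-pass
# and equivariance checks
tiny_mvg <- function(n = 6L, seed = 1L, d_emb = 3L) {
  set.seed(seed)
  sim <- simulate_structure(synthetic_spec(n_residues = max(n, 12L),
                                           pocket_size = 3L, seed = seed))
  # keep only the first n residues worth of features but reuse real graphs
  coords <- representative_coords(sim$record)[seq_len(n), , drop = FALSE]
  ann <- read_secondary_annotation(
    if (n >= 4L) "1 4 canonical_pair" else "", n)
  bases <- sample(c("A", "U", "G", "C"), n, replace = TRUE)
  gT <- build_tertiary_graph(coords, 3L)
  nfm <- assemble_features(one_hot_encode(bases),
                           secondary_feature_vector(ann),
                           topological_properties(gT$edges, n),
                           conservation = runif(n),
                           embeddings = matrix(rnorm(n * d_emb), n),
                           asa = rnorm(n), d_emb = d_emb)
  y <- rep_len(c(0L, 1L), n)
  multi_view_graph("FIX", nfm, list(P = build_primary_graph(n, 3L),
                                    S = build_secondary_graph(ann),
                                    T = gT), y)
}

small_cfg <- function(g, ...) {
  model_config(d_init = ncol(g$x_init$X), d_hidden = 8L, n_heads = 2L,
               d_scale = 8L, clf_hidden = 4L, dropout = 0, ...)
}

# permute a multi_view_graph by a node relabeling
permute_mvg <- function(g, perm) {
  n <- length(g$y)
  inv <- order(perm)
  relabel <- function(vg) {
    e <- vg$edges
    if (nrow(e) > 0L) {
      e <- cbind(inv[e[, 1] + 1L] - 1L, inv[e[, 2] + 1L] - 1L)
      e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    }
    view_graph_internal(vg$view, n, e)
  }
  nfm <- g$x_init
  nfm$X <- nfm$X[perm, , drop = FALSE]
  multi_view_graph(g$chain_id, nfm,
                   lapply(g$graphs, relabel), g$y[perm])
}

view_graph_internal <- function(view, n, edges) {
  asNamespace("nucsite")$view_graph(view, n, edges)
}

# desk-scale training width used across training/acceptance tests
desk_model_opts <- function() {
  list(d_hidden = 32L, n_heads = 2L, d_scale = 32L, clf_hidden = 32L)
}
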