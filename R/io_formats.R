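#' Read one RNA chain and its ligands from PDB text
#'
#' Parses ATOM records of the requested chain into an ordered residue list and
#' collects every non-water HETATM group in the file as a candidate ligand.
#' Water (HOH) is excluded because crystallographic waters are not small
#' molecules of interest. Alternate locations are resolved to the first
#' conformer and only the first model of multi-model (NMR) files is read;
#' picking among conformations is left to the caller, which treats each
#' conformer as its own entry.
#'
#' Residues are ordered by (residue number, insertion code) and re-indexed
#' densely from 0, the package-wide internal convention. Residue names outside
#' A/C/G/U (modified or unknown nucleotides) are kept as base `"other"` so
#' that sequence adjacency is preserved.
#'
#' @param pdb_text Character scalar (or vector of lines) of PDB-format text.
#' @param chain_id Single chain identifier to extract.
#' @return A `structure_record`: list with `chain_id`, `residues` (list of
#'   `residue_index`, `base`, `atoms` data.frame with `atom_name,x,y,z`) and
#'   `ligands` (list of `het_code` plus an atom data.frame).
#' @examples
#' pdb <- simulate_structure(synthetic_spec(n_residues = 12, seed = 1))$pdb_text
#' rec <- read_structure(pdb, "A")
#' length(rec$residues)
#' @export
read_structure <- function(pdb_text, chain_id) {
  stopifnot(is.character(pdb_text), length(chain_id) == 1L)
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(if (length(pdb_text) == 1L) strsplit(pdb_text, "\n", fixed = TRUE)[[1]] else pdb_text, tmp)
  pdb <- bio3d::read.pdb(tmp, multi = FALSE, verbose = FALSE)
  atoms <- pdb$atom
  # first-conformer rule for alternate locations
  if (!is.null(atoms$alt)) {
    alt <- atoms$alt
    alt[is.na(alt)] <- ""
    keep_alt <- alt %in% c("", unique(alt[alt != ""])[1])
    atoms <- atoms[keep_alt, , drop = FALSE]
  }
  ca <- atoms[atoms$type == "ATOM", , drop = FALSE]
  chains <- sort(unique(ca$chain))
  if (!(chain_id %in% chains)) {
    stop("chain '", chain_id, "' not found; available chains: ",
         paste(chains, collapse = ", "))
  }
  ca <- ca[ca$chain == chain_id, , drop = FALSE]
  if (nrow(ca) == 0L) stop("chain '", chain_id, "' has no polymer residues")
  ins <- ca$insert
  ins[is.na(ins)] <- ""
  key <- paste(ca$resno, ins, sep = "\r")
  ord_keys <- unique(key[order(ca$resno, ins)])
  residues <- vector("list", length(ord_keys))
  for (i in seq_along(ord_keys)) {
    rows <- ca[key == ord_keys[i], , drop = FALSE]
    base <- trimws(rows$resid[1])
    if (!(base %in% c("A", "C", "G", "U"))) base <- "other"
    residues[[i]] <- list(
      residue_index = i - 1L,
      base = base,
      atoms = data.frame(atom_name = trimws(rows$elety),
                         x = rows$x, y = rows$y, z = rows$z,
                         stringsAsFactors = FALSE))
    if (any(!is.finite(c(rows$x, rows$y, rows$z)))) {
      stop("non-finite coordinates in residue ", ord_keys[i])
    }
  }
  het <- atoms[atoms$type == "HETATM", , drop = FALSE]
  het <- het[trimws(het$resid) != "HOH", , drop = FALSE]
  ligands <- list()
  if (nrow(het) > 0L) {
    hkey <- paste(trimws(het$resid), het$chain, het$resno, sep = "\r")
    for (k in unique(hkey)) {
      rows <- het[hkey == k, , drop = FALSE]
      ligands[[length(ligands) + 1L]] <- list(
        het_code = trimws(rows$resid[1]),
        atoms = data.frame(atom_name = trimws(rows$elety),
                           x = rows$x, y = rows$y, z = rows$z,
                           stringsAsFactors = FALSE))
    }
  }
  structure(list(chain_id = chain_id, residues = residues, ligands = ligands),
            class = "structure_record")
}

#' @export
print.structure_record <- function(x, ...) {
  cat("RNA chain", x$chain_id, "with", length(x$residues), "residues and",
      length(x$ligands), "ligand group(s)\n")
  invisible(x)
}

n_residues <- function(record) length(record$residues)

#' Read a secondary-structure interaction annotation
#'
#' Parses a whitespace/tab-separated edge list with one interaction per line:
#' `i j kind`, 1-based nucleotide indices, `kind` one of `canonical_pair`,
#' `noncanonical_pair`, `base_ribose`, `base_phosphate`. Lines of the form
#' `loop i` flag nucleotide `i` as lying in a loop region. Comment lines
#' starting with `#` and blank lines are ignored. Indices are converted to the
#' 0-based internal convention and each pair stored with `i < j`.
#'
#' @param text Annotation text (scalar or lines).
#' @param n Nucleotide count of the chain the annotation describes.
#' @return A `secondary_annotation`: list with `n`, `interactions`
#'   (data.frame `i`, `j`, `kind`, 0-based) and logical `loop_member` of
#'   length `n`.
#' @export
read_secondary_annotation <- function(text, n) {
  stopifnot(n >= 1L)
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kinds <- c("canonical_pair", "noncanonical_pair", "base_ribose", "base_phosphate")
  loop <- logical(n)
  ii <- integer(0); jj <- integer(0); kk <- character(0)
  for (ln in lines) {
    parts <- strsplit(ln, "[ \t]+")[[1]]
    if (identical(parts[1], "loop")) {
      idx <- as.integer(parts[-1])
      if (any(is.na(idx)) || any(idx < 1L | idx > n)) {
        stop("loop index out of range in line: ", ln)
      }
      loop[idx] <- TRUE
      next
    }
    if (length(parts) != 3L) stop("malformed annotation line: ", ln)
    a <- as.integer(parts[1]); b <- as.integer(parts[2])
    if (is.na(a) || is.na(b) || a < 1L || a > n || b < 1L || b > n || a == b) {
      stop("interaction index out of [1, ", n, "] in line: ", ln)
    }
    if (!(parts[3] %in% kinds)) {
      stop("unknown interaction kind '", parts[3], "'; expected one of: ",
           paste(kinds, collapse = ", "))
    }
    ii <- c(ii, min(a, b) - 1L)
    jj <- c(jj, max(a, b) - 1L)
    kk <- c(kk, parts[3])
  }
  inter <- unique(data.frame(i = ii, j = jj, kind = kk, stringsAsFactors = FALSE))
  structure(list(n = as.integer(n), interactions = inter, loop_member = loop),
            class = "secondary_annotation")
}

#' Read an aligned FASTA multiple sequence alignment
#'
#' All rows must have equal length; T is normalized to U and lowercase to
#' uppercase. The query (study) sequence is located by exact header match on
#' the first whitespace-delimited token.
#'
#' @param fasta_text Aligned FASTA text (scalar or lines).
#' @param query_id Header token identifying the query row.
#' @return An `msa_record`: list with `seqs` (character matrix, rows =
#'   sequences, columns = alignment positions) and `query_row`.
#' @export
read_msa <- function(fasta_text, query_id) {
  lines <- if (length(fasta_text) == 1L) strsplit(fasta_text, "\n", fixed = TRUE)[[1]] else fasta_text
  lines <- lines[nzchar(trimws(lines))]
  hdr_at <- grep("^>", lines)
  if (length(hdr_at) == 0L) stop("no FASTA headers found")
  ids <- vapply(lines[hdr_at], function(h)
    strsplit(sub("^>", "", h), "[ \t]")[[1]][1], character(1), USE.NAMES = FALSE)
  ends <- c(hdr_at[-1] - 1L, length(lines))
  seqs <- vapply(seq_along(hdr_at), function(k) {
    paste(lines[seq.int(hdr_at[k] + 1L, ends[k])], collapse = "")
  }, character(1))
  seqs <- toupper(gsub("[ \t]", "", seqs))
  seqs <- chartr("T", "U", seqs)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    stop("ragged alignment: row lengths ", paste(unique(lens), collapse = ", "))
  }
  q <- match(query_id, ids)
  if (is.na(q)) stop("query id '", query_id, "' not found among: ",
                     paste(utils::head(ids, 10), collapse = ", "))
  mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  bad <- setdiff(unique(mat[q, ]), c("A", "C", "G", "U", "-"))
  if (length(bad) > 0L) {
    stop("query row contains characters outside {A,C,G,U,-}: ",
         paste(bad, collapse = ", "))
  }
  structure(list(seqs = mat, query_row = q), class = "msa_record")
}

#' Write per-nucleotide predictions as TSV
#'
#' @param record data.frame with columns `chain`, `residue_index`, `base`,
#'   `probability`, `predicted_label` and optionally `true_label`.
#' @return TSV text (single string, trailing newline), probabilities printed
#'   to 6 decimals.
#' @export
write_predictions <- function(record) {
  cols <- c("chain", "residue_index", "base", "probability", "predicted_label")
  stopifnot(all(cols %in% names(record)))
  has_true <- "true_label" %in% names(record)
  header <- c(cols, if (has_true) "true_label")
  body <- character(nrow(record))
  for (r in seq_len(nrow(record))) {
    fields <- c(as.character(record$chain[r]),
                as.character(record$residue_index[r]),
                as.character(record$base[r]),
                sprintf("%.6f", record$probability[r]),
                as.character(record$predicted_label[r]),
                if (has_true) as.character(record$true_label[r]))
    body[r] <- paste(fields, collapse = "\t")
  }
  paste0(paste(c(paste(header, collapse = "\t"), body), collapse = "\n"), "\n")
}

#' Parse a prediction TSV back into a data.frame
#' @param text TSV text produced by [write_predictions()].
#' @return data.frame with the same columns.
#' @export
read_predictions <- function(text) {
  utils::read.delim(text = text, sep = "\t", stringsAsFactors = FALSE)
}
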