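# Fibril structure parsing and minimal side-chain heavy-atom distances
# (scHA_min): per-chain residue atom sets, monomer and cross-filament dimer
# distance matrices, and contact maps at a distance threshold.

BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

#' Parse a fibril structure from PDB
#'
#' Reads ATOM records (via bio3d), drops hydrogens, resolves alternate
#' locations to the highest-occupancy conformer, and classifies atoms into
#' backbone and side chain. The side chain is every heavy atom outside
#' N/CA/C/O/OXT; glycine, having no side chain, is assigned its C-alpha as
#' the designated atom. Residues lacking any side-chain heavy atom are
#' flagged, not dropped.
#'
#' @param pdb Path to a PDB file, or PDB text (detected by an embedded
#'   newline).
#' @param chains Chain identifiers to keep (`NULL` = all).
#' @param offset Added to author residue numbers to align to peptide
#'   numbering 1-42 (deposited fibril structures often start mid-sequence).
#' @param id Structure identifier recorded in results (default: file stem).
#' @return A `nuc_structure`: atom tibble (`chain`, `resno`, `resname`,
#'   `atom`, `element`, `x`, `y`, `z`, `side_chain`), available chains, and
#'   flags for residues without side-chain atoms.
#' @export
parse_structure <- function(pdb, chains = NULL, offset = 0, id = NULL) {
  path <- pdb
  if (grepl("\n", pdb, fixed = TRUE)) {
    path <- tempfile(fileext = ".pdb")
    writeLines(pdb, path)
    on.exit(unlink(path))
    if (is.null(id)) id <- "fixture"
  }
  if (is.null(id)) id <- sub("\\.pdb$", "", basename(path))
  parsed <- bio3d::read.pdb(path, verbose = FALSE)
  at <- parsed$atom[parsed$atom$type == "ATOM", , drop = FALSE]
  available <- sort(unique(at$chain))
  if (!is.null(chains)) {
    missing <- setdiff(chains, available)
    if (length(missing) > 0L) {
      stop("chain(s) ", paste(missing, collapse = ", "),
           " not in structure; available chains: ",
           paste(available, collapse = ", "))
    }
    at <- at[at$chain %in% chains, , drop = FALSE]
  }
  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem) | elem == "")) {
    elem <- substr(gsub("^[0-9]", "", at$elety), 1L, 1L)
  }
  at <- at[toupper(elem) != "H", , drop = FALSE]
  elem <- elem[toupper(elem) != "H"]
  # altloc: keep the highest-occupancy conformer per atom
  key <- paste(at$chain, at$resno, at$elety)
  ord <- order(key, -at$o)
  keep <- sort(ord[!duplicated(key[ord])])  # dedup, then restore file order
  at <- at[keep, , drop = FALSE]
  atoms <- tibble::tibble(
    chain = at$chain,
    resno = as.integer(at$resno) + as.integer(offset),
    resname = at$resid,
    atom = at$elety,
    element = toupper(substr(gsub("^[0-9]", "", at$elety), 1L, 1L)),
    x = at$x, y = at$y, z = at$z
  )
  atoms$side_chain <- !(atoms$atom %in% BACKBONE_ATOMS) |
    (atoms$resname == "GLY" & atoms$atom == "CA")
  flags <- atoms |>
    dplyr::group_by(.data$chain, .data$resno, .data$resname) |>
    dplyr::summarise(has_side_chain = any(.data$side_chain), .groups = "drop") |>
    dplyr::filter(!.data$has_side_chain)
  structure(
    list(id = id, atoms = atoms, chains = sort(unique(atoms$chain)),
         missing_side_chains = flags),
    class = "nuc_structure"
  )
}

#' @export
print.nuc_structure <- function(x, ...) {
  cat("<nuc_structure> ", x$id, ": ", nrow(x$atoms), " heavy atoms, chains {",
      paste(x$chains, collapse = ","), "}\n", sep = "")
  invisible(x)
}

# list of side-chain coordinate matrices keyed by residue number, one chain
side_chain_sets <- function(struct, chain) {
  sc <- struct$atoms[struct$atoms$chain == chain & struct$atoms$side_chain, ,
                     drop = FALSE]
  m <- split(seq_len(nrow(sc)), sc$resno)
  lapply(m, function(i) cbind(sc$x[i], sc$y[i], sc$z[i]))
}

min_cross_distance <- function(a, b) {
  # minimum Euclidean distance over all cross pairs of rows of a and b
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(max(min(d2), 0))
}

#' Minimal side-chain heavy-atom distance between two residues
#'
#' The minimum Euclidean distance over all pairs of side-chain heavy atoms
#' of the two residues (C-alpha standing in for glycine).
#'
#' @param struct A `nuc_structure`.
#' @param pos_i,pos_j Residue numbers (after any parse offset).
#' @param chain Chain to use (default: the first).
#' @return Distance in Angstrom.
#' @export
schamin_distance <- function(struct, pos_i, pos_j, chain = NULL) {
  stopifnot(inherits(struct, "nuc_structure"))
  chain <- chain %||% struct$chains[[1]]
  sets <- side_chain_sets(struct, chain)
  a <- sets[[as.character(pos_i)]]
  b <- sets[[as.character(pos_j)]]
  if (is.null(a) || is.null(b)) {
    stop("residue ", if (is.null(a)) pos_i else pos_j,
         " has no side-chain heavy atoms in chain ", chain)
  }
  min_cross_distance(a, b)
}

#' Pairwise scHA_min distance matrix of a structure
#'
#' Monomer mode computes within-chain distances for one chain. Dimer mode
#' takes two chains (monomers in facing filaments) and reports, for each
#' residue pair (i, j), the minimum over both cross-chain assignments
#' (i in the first chain vs j in the second, and vice versa).
#'
#' @param struct A `nuc_structure`.
#' @param mode `"monomer"` or `"dimer"`.
#' @param chains One chain (monomer) or two (dimer); default: first one/two.
#' @return A `nuc_distances`: symmetric matrix of scHA_min values (Angstrom)
#'   with residue-number dimnames, plus `mode` and `structure`.
#' @export
distance_matrix <- function(struct, mode = c("monomer", "dimer"),
                            chains = NULL) {
  stopifnot(inherits(struct, "nuc_structure"))
  mode <- match.arg(mode)
  need <- if (mode == "monomer") 1L else 2L
  chains <- chains %||% utils::head(struct$chains, need)
  if (length(chains) != need) {
    stop(mode, " mode needs exactly ", need, " chain(s), got ",
         length(chains))
  }
  if (mode == "monomer") {
    sets <- side_chain_sets(struct, chains[[1]])
    res <- as.integer(names(sets))
    n <- length(res)
    m <- matrix(0, n, n, dimnames = list(res, res))
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (j > i) {
          m[i, j] <- min_cross_distance(sets[[i]], sets[[j]])
          m[j, i] <- m[i, j]
        }
      }
    }
  } else {
    sa <- side_chain_sets(struct, chains[[1]])
    sb <- side_chain_sets(struct, chains[[2]])
    res <- sort(intersect(as.integer(names(sa)), as.integer(names(sb))))
    n <- length(res)
    m <- matrix(NA_real_, n, n, dimnames = list(res, res))
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        ri <- as.character(res[[i]]); rj <- as.character(res[[j]])
        m[i, j] <- min(min_cross_distance(sa[[ri]], sb[[rj]]),
                       min_cross_distance(sb[[ri]], sa[[rj]]))
      }
    }
    m <- pmin(m, t(m))
  }
  structure(list(matrix = m, mode = mode, structure = struct$id,
                 chains = chains),
            class = "nuc_distances")
}

#' @export
print.nuc_distances <- function(x, ...) {
  cat("<nuc_distances> ", x$structure, " (", x$mode, ", chains ",
      paste(x$chains, collapse = "+"), "): ", nrow(x$matrix),
      " residues\n", sep = "")
  invisible(x)
}

#' @export
tidy.nuc_distances <- function(x, ...) {
  res <- as.integer(rownames(x$matrix))
  idx <- which(upper.tri(x$matrix), arr.ind = TRUE)
  tibble::tibble(
    pos_i = res[idx[, 1]], pos_j = res[idx[, 2]],
    scha_min = x$matrix[idx],
    mode = x$mode, structure = x$structure
  )
}

#' Contact map at a distance threshold
#'
#' A residue pair is in contact iff its scHA_min is strictly below the
#' threshold (default 8 Angstrom).
#'
#' @param distances A `nuc_distances` (or bare numeric matrix).
#' @param threshold Angstrom.
#' @return Logical matrix of the same shape (diagonal `FALSE`).
#' @export
contact_map <- function(distances, threshold = 8) {
  m <- if (inherits(distances, "nuc_distances")) distances$matrix else distances
  cm <- m < threshold
  diag(cm) <- FALSE
  cm
}
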