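# Degenerate-codon schemes, mutagenesis library designs, variant-space and
# model-parameter combinatorics for the Abeta42 nucleation selections.

IUPAC_NT <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Wild-type amyloid-beta 42 sequence
#'
#' The 42-residue amyloid-beta peptide, 1-based numbering (residue 1 = D,
#' residue 42 = A). All library designs and mutation identifiers in the
#' package use this numbering; a mutation is written WT-residue, position,
#' mutant residue, e.g. `"I32M"`.
#'
#' @return A length-one character string of 42 amino acids.
#' @export
ab42_sequence <- function() {
  "DAEFRHDSGYEVHHQKLVFFAEDVGSNKGAIIGLMVGGVVIA"
}

#' Expand a degenerate codon into concrete codons and amino acids
#'
#' Expands a three-letter IUPAC degenerate codon (e.g. NNK, DTS) into the
#' Cartesian product of its per-position nucleotide sets and translates each
#' concrete codon under the standard genetic code.
#'
#' @param code Three IUPAC nucleotide symbols, e.g. `"NNK"`.
#' @return An object of class `codon_scheme`: a list with `code`, `codons`
#'   (character vector of concrete triplets), `amino_acids` (residues encoded,
#'   stop excluded), and `includes_stop` (flag: at least one codon is a stop).
#' @examples
#' expand_degenerate_codon("NNK")  # 32 codons, all 20 amino acids + TAG stop
#' expand_degenerate_codon("DTS")$amino_acids  # F, L, I, M, V
#' @export
expand_degenerate_codon <- function(code) {
  stopifnot(is.character(code), length(code) == 1L)
  code <- toupper(code)
  if (nchar(code) != 3L) {
    stop("a codon must have exactly three nucleotide symbols, got '", code, "'")
  }
  sym <- strsplit(code, "")[[1]]
  bad <- setdiff(sym, names(IUPAC_NT))
  if (length(bad) > 0L) {
    stop("invalid IUPAC nucleotide symbol: '", bad[[1]], "' in '", code, "'")
  }
  sets <- IUPAC_NT[sym]
  grid <- expand.grid(sets[[1]], sets[[2]], sets[[3]],
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  codons <- sort(paste0(grid[[1]], grid[[2]], grid[[3]]))
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  structure(
    list(
      code = code,
      codons = codons,
      amino_acids = sort(unique(aa[aa != "*"])),
      includes_stop = any(aa == "*")
    ),
    class = "codon_scheme"
  )
}

#' @export
print.codon_scheme <- function(x, ...) {
  cat("<codon_scheme> ", x$code, ": ", length(x$codons), " codons -> {",
      paste(x$amino_acids, collapse = ""), "}",
      if (x$includes_stop) " (+stop)" else "", "\n", sep = "")
  invisible(x)
}

#' Define a mutagenesis library design
#'
#' A design is a wild-type sequence, an ordered set of mutable positions, a
#' per-position amino-acid alphabet, and the maximum number of simultaneous
#' substitutions. Double-mutant designs use `max_order = 2` with all 20 amino
#' acids allowed per site (19 non-WT alternatives); combinatorial designs use
#' `max_order = length(positions)` with a restricted alphabet that includes
#' the wild-type residue.
#'
#' @param name Design identifier.
#' @param positions Integer vector of 1-based mutable positions.
#' @param alphabet Either a `codon_scheme`, a character vector of amino acids
#'   applied to every position, or `NULL` for all 20 amino acids. Stop codons
#'   are never part of the amino-acid alphabet.
#' @param max_order Maximum simultaneous amino-acid substitutions.
#' @param sequence Wild-type amino-acid sequence (default amyloid-beta 42).
#' @return A `library_design` object with a per-position tibble of wild-type
#'   residues and allowed alphabets.
#' @export
library_design <- function(name, positions, alphabet = NULL, max_order = 2L,
                           sequence = ab42_sequence()) {
  stopifnot(is.character(name), length(positions) >= 1L)
  positions <- as.integer(positions)
  n <- nchar(sequence)
  if (any(positions < 1L) || any(positions > n)) {
    stop("mutable positions must lie within 1..", n)
  }
  if (anyDuplicated(positions)) stop("duplicated mutable positions")
  wt <- strsplit(sequence, "")[[1]]
  if (inherits(alphabet, "codon_scheme")) alphabet <- alphabet$amino_acids
  if (is.null(alphabet)) {
    alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  }
  if (!is.list(alphabet)) alphabet <- rep(list(sort(unique(alphabet))), length(positions))
  stopifnot(length(alphabet) == length(positions))
  sites <- tibble::tibble(
    position = positions,
    wt = wt[positions],
    alphabet = alphabet
  )
  max_order <- as.integer(max_order)
  stopifnot(max_order >= 0L, max_order <= length(positions))
  structure(
    list(name = name, sequence = sequence, sites = sites, max_order = max_order),
    class = "library_design"
  )
}

#' @export
print.library_design <- function(x, ...) {
  cat("<library_design> ", x$name, ": ", nrow(x$sites), " mutable positions (",
      paste(range(x$sites$position), collapse = "-"), "), max order ",
      x$max_order, "\n", sep = "")
  invisible(x)
}

is_combinatorial <- function(design) design$max_order >= nrow(design$sites)

# non-WT alternatives per site (character list)
site_alternatives <- function(design) {
  purrr::map2(design$sites$alphabet, design$sites$wt, setdiff)
}

#' The five amyloid-beta 42 library designs
#'
#' Returns the designs used throughout the package: three double-mutant
#' libraries (`shallow`, whole sequence; `nterm`, residues 1-28; `cterm`,
#' residues 28-42, NNK-programmed) and two combinatorial libraries
#' (`comb1`, 8 hydrophobic-core positions; `comb2`, 6 positions spanning both
#' aggregation-prone regions), both programmed with the DTS degenerate codon
#' encoding F, L, I, M and V.
#'
#' @return Named list of `library_design` objects.
#' @export
abeta_designs <- function() {
  dts <- expand_degenerate_codon("DTS")$amino_acids
  list(
    shallow = library_design("shallow", 1:42, max_order = 2L),
    nterm   = library_design("nterm", 1:28, max_order = 2L),
    cterm   = library_design("cterm", 28:42, alphabet = expand_degenerate_codon("NNK"),
                             max_order = 2L),
    comb1   = library_design("comb1", c(31L, 32L, 34L, 35L, 36L, 39L, 40L, 41L),
                             alphabet = dts, max_order = 8L),
    comb2   = library_design("comb2", c(19L, 20L, 24L, 31L, 32L, 34L),
                             alphabet = dts, max_order = 6L)
  )
}

#' Count the variant space of a library design
#'
#' Closed-form combinatorics: `singles` is the number of single amino-acid
#' mutants (sum over mutable positions of non-WT alternatives), `doubles` the
#' number of double mutants (sum over position pairs of alternative products).
#' For combinatorial designs `total_genotypes` is the product of per-position
#' alphabet sizes (WT residue included in the alphabet); otherwise it is the
#' number of genotypes up to `max_order`.
#'
#' @param design A `library_design`.
#' @return A one-row tibble: `design`, `singles`, `doubles`, `total_genotypes`.
#' @examples
#' count_variant_space(abeta_designs()$cterm)  # 285 singles, 37,905 doubles
#' @export
count_variant_space <- function(design) {
  stopifnot(inherits(design, "library_design"))
  n_alt <- lengths(site_alternatives(design))
  singles <- sum(n_alt)
  doubles <- if (length(n_alt) >= 2L && design$max_order >= 2L) {
    (sum(n_alt)^2 - sum(n_alt^2)) / 2
  } else 0
  total <- if (is_combinatorial(design)) {
    prod(lengths(design$sites$alphabet))
  } else {
    1 + singles + if (design$max_order >= 2L) doubles else 0
  }
  tibble::tibble(
    design = design$name,
    singles = as.numeric(singles),
    doubles = as.numeric(doubles),
    total_genotypes = as.numeric(total)
  )
}

#' Nucleotide-sequence space of a two-site degenerate-codon oligo pool
#'
#' For an oligo pool tiling all pairs of `n_positions` sites with a degenerate
#' codon at each of `k` sites: `choose(n_positions, k) * codons_per_site^k`
#' unique nucleotide sequences (e.g. 15 positions, NNK at 2 sites:
#' 105 x 32^2 = 107,520).
#'
#' @param n_positions Number of mutable positions tiled by the pool.
#' @param codons_per_site Concrete codons encoded by the degenerate codon.
#' @param k Number of degenerate sites per oligo.
#' @return Number of unique nucleotide sequences.
#' @export
oligo_pool_space <- function(n_positions, codons_per_site = 32, k = 2) {
  choose(n_positions, k) * codons_per_site^k
}

#' Count energy-model parameters implied by joint library designs
#'
#' For a set of designs over the same wild-type sequence, counts the distinct
#' first-order terms (position, non-WT amino acid), the unordered position
#' pairs co-mutable within at least one design, and the pairwise couplings
#' (sum over pairs of the product of alternative-set sizes). Genotype-space
#' size uses the non-WT-alternatives-per-site convention with
#' inclusion-exclusion over design overlaps (two combinatorial designs with
#' 8 and 6 sites sharing 3 give 4^8 + 4^6 - 4^3), and the compression factor
#' is genotype space over parameter count, rounded to the nearest integer.
#'
#' @param designs A `library_design` or list of them (same wild-type sequence).
#' @param order 1 (additive terms only) or 2 (additive + pairwise couplings).
#' @return A one-row tibble: `first_order`, `pairs`, `couplings`,
#'   `genotype_space`, `n_parameters`, `compression`.
#' @examples
#' d <- abeta_designs()
#' count_model_parameters(d[c("comb1", "comb2")], order = 1)  # 44 terms, x1581
#' @export
count_model_parameters <- function(designs, order = 1L) {
  if (inherits(designs, "library_design")) designs <- list(designs)
  stopifnot(length(designs) >= 1L, order %in% c(1L, 2L))
  seqs <- unique(purrr::map_chr(designs, "sequence"))
  if (length(seqs) != 1L) {
    stop("all designs must share the same wild-type sequence")
  }

  # distinct (position, alternative) terms across designs
  alts <- purrr::map(designs, function(d) {
    purrr::map2(site_alternatives(d), d$sites$position,
                function(a, p) if (length(a)) paste0(p, ":", a) else character())
  })
  first_order_keys <- unique(unlist(alts))
  first_order <- length(first_order_keys)

  # per-design co-mutable pairs, with merged alternative sets per position
  alt_by_pos <- list()
  pair_keys <- character()
  for (d in designs) {
    pos <- d$sites$position
    a <- site_alternatives(d)
    for (i in seq_along(pos)) {
      key <- as.character(pos[[i]])
      alt_by_pos[[key]] <- union(alt_by_pos[[key]], a[[i]])
    }
    if (d$max_order >= 2L && length(pos) >= 2L) {
      cmb <- utils::combn(sort(pos), 2L)
      pair_keys <- union(pair_keys, paste(cmb[1, ], cmb[2, ], sep = "-"))
    }
  }
  n_pairs <- length(pair_keys)
  couplings <- if (n_pairs == 0L) 0 else sum(purrr::map_dbl(pair_keys, function(k) {
    ij <- strsplit(k, "-")[[1]]
    length(alt_by_pos[[ij[[1]]]]) * length(alt_by_pos[[ij[[2]]]])
  }))

  # genotype space: inclusion-exclusion over design subsets; a genotype lies
  # in every design of a subset iff it varies only at positions mutable in
  # all of them, counted with the non-WT alternatives convention
  n_d <- length(designs)
  pos_sets <- purrr::map(designs, function(d) d$sites$position)
  alt_sets <- purrr::map(designs, function(d) {
    stats::setNames(site_alternatives(d), d$sites$position)
  })
  genotype_space <- 0
  for (mask in seq_len(2^n_d - 1L)) {
    members <- which(bitwAnd(mask, 2^(seq_len(n_d) - 1L)) > 0L)
    shared <- Reduce(intersect, pos_sets[members])
    if (length(shared) == 0L) {
      size <- 1  # only the reference genotype
    } else {
      size <- prod(purrr::map_dbl(shared, function(p) {
        length(Reduce(intersect, purrr::map(alt_sets[members], function(a) {
          a[[as.character(p)]] %||% character()
        })))
      }))
    }
    genotype_space <- genotype_space + (-1)^(length(members) + 1L) * size
  }

  n_par <- if (order == 1L) first_order else first_order + couplings
  tibble::tibble(
    order = as.integer(order),
    first_order = as.numeric(first_order),
    pairs = as.numeric(n_pairs),
    couplings = as.numeric(couplings),
    genotype_space = genotype_space,
    n_parameters = as.numeric(n_par),
    compression = round(genotype_space / n_par)
  )
}

mutation_id <- function(wt, pos, alt) paste0(wt, pos, alt)

#' Parse mutation identifiers
#'
#' Splits identifiers like `"I32M"` or `"I31M:V40L"` (colon-joined for
#' multi-mutants) into positions, wild-type and mutant residues.
#'
#' @param mutations Character vector; `""` denotes the wild type.
#' @return Tibble with `variant_index`, `wt`, `position`, `alt`.
#' @export
parse_mutations <- function(mutations) {
  idx <- rep(seq_along(mutations), times = ifelse(mutations == "", 0L,
             stringr::str_count(mutations, ":") + 1L))
  muts <- unlist(strsplit(mutations[mutations != ""], ":", fixed = TRUE))
  if (length(muts) == 0L) {
    return(tibble::tibble(variant_index = integer(), wt = character(),
                          position = integer(), alt = character()))
  }
  m <- stringr::str_match(muts, "^([A-Z\\*])(\\d+)([A-Z\\*])$")
  if (anyNA(m[, 1])) {
    stop("malformed mutation identifier: '", muts[which(is.na(m[, 1]))[1]], "'")
  }
  tibble::tibble(
    variant_index = idx,
    wt = m[, 2],
    position = as.integer(m[, 3]),
    alt = m[, 4]
  )
}

apply_mutations <- function(sequence, mutations) {
  wt <- strsplit(sequence, "")[[1]]
  parsed <- parse_mutations(mutations)
  if (nrow(parsed) > 0L && any(wt[parsed$position] != parsed$wt)) {
    bad <- which(wt[parsed$position] != parsed$wt)[[1]]
    stop("mutation wild-type residue mismatch at position ",
         parsed$position[[bad]])
  }
  m <- matrix(rep(wt, each = length(mutations)),
              nrow = length(mutations), ncol = length(wt))
  if (nrow(parsed) > 0L) {
    m[cbind(parsed$variant_index, parsed$position)] <- parsed$alt
  }
  do.call(paste0, lapply(seq_len(ncol(m)), function(j) m[, j]))
}

#' Enumerate the variants of a library design
#'
#' Materializes all variants up to a mutation order, as mutation-identifier
#' strings and (optionally) full amino-acid sequences. Counts agree with
#' [count_variant_space()].
#'
#' @param design A `library_design`.
#' @param up_to_order Maximum number of substitutions (capped at the design's
#'   `max_order`). For combinatorial designs any value `>= 2` enumerates the
#'   full per-position alphabet product.
#' @param cap Refuse to materialize more than this many variants.
#' @param include_sequence Attach the full mutant sequence column.
#' @return Tibble with `mutations` (`""` = wild type), `order`, and optionally
#'   `sequence`, ordered by increasing mutation order.
#' @export
enumerate_variants <- function(design, up_to_order = design$max_order,
                               cap = 1e6, include_sequence = TRUE) {
  stopifnot(inherits(design, "library_design"))
  up_to_order <- min(as.integer(up_to_order), design$max_order)
  cvs <- count_variant_space(design)
  expected <- if (is_combinatorial(design) && up_to_order >= 2L) {
    cvs$total_genotypes
  } else if (up_to_order <= 0L) 1 else if (up_to_order == 1L) {
    1 + cvs$singles
  } else 1 + cvs$singles + cvs$doubles
  if (expected > cap) {
    stop("enumeration would materialize ", format(expected, big.mark = ","),
         " variants; raise `cap` to at least ", ceiling(expected))
  }

  pos <- design$sites$position
  wt <- design$sites$wt
  alts <- site_alternatives(design)

  if (is_combinatorial(design) && up_to_order >= 2L) {
    grid <- expand.grid(design$sites$alphabet, stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)
    muts <- character(nrow(grid))
    ord <- integer(nrow(grid))
    for (j in seq_along(pos)) {
      sel <- grid[[j]] != wt[[j]]
      id <- mutation_id(wt[[j]], pos[[j]], grid[[j]][sel])
      muts[sel] <- ifelse(ord[sel] == 0L, id, paste(muts[sel], id, sep = ":"))
      ord[sel] <- ord[sel] + 1L
    }
    out <- tibble::tibble(mutations = muts, order = as.integer(ord))
  } else {
    rows <- list(tibble::tibble(mutations = "", order = 0L))
    if (up_to_order >= 1L) {
      singles <- purrr::map2(seq_along(pos), alts, function(i, a) {
        if (length(a)) mutation_id(wt[[i]], pos[[i]], a) else character()
      })
      rows[[2]] <- tibble::tibble(mutations = unlist(singles), order = 1L)
      if (up_to_order >= 2L && length(pos) >= 2L) {
        dbl <- utils::combn(seq_along(pos), 2L, simplify = FALSE)
        dmuts <- purrr::map(dbl, function(ij) {
          i <- ij[[1]]; j <- ij[[2]]
          if (!length(alts[[i]]) || !length(alts[[j]])) return(character())
          g <- expand.grid(alts[[i]], alts[[j]], stringsAsFactors = FALSE)
          paste(mutation_id(wt[[i]], pos[[i]], g[[1]]),
                mutation_id(wt[[j]], pos[[j]], g[[2]]), sep = ":")
        })
        rows[[3]] <- tibble::tibble(mutations = unlist(dmuts), order = 2L)
      }
    }
    out <- dplyr::bind_rows(rows)
  }
  out <- dplyr::arrange(out, .data$order, .data$mutations)
  if (anyDuplicated(out$mutations)) stop("internal error: duplicated variants")
  if (include_sequence) {
    out$sequence <- apply_mutations(design$sequence, out$mutations)
    out <- dplyr::relocate(out, "sequence")
  }
  out
}
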