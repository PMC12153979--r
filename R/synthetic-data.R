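# Ground-truth landscapes, simulated selections, surrogate stability tables
# and fibril-structure fixtures with the statistical structure the inference
# chain assumes, so every downstream stage is testable without external data.

#' Construct an energy landscape
#'
#' A landscape holds per-mutation changes in free energy of activation
#' (first-order terms, kcal/mol), sparse pairwise energetic couplings
#' (kcal/mol), and the bounded sigmoid linking the additive energy trait to
#' relative growth rate.
#'
#' @param first_order Tibble with columns `mutation` (e.g. `"I32M"`) and
#'   `ddg_act` (kcal/mol).
#' @param couplings Tibble with columns `mut1`, `mut2`, `coupling` (kcal/mol);
#'   only nonzero couplings need be listed.
#' @param sigmoid Named numeric: `L` (lower growth-rate bound), `U` (upper
#'   bound, `L < U`), `s` (trait scale, > 0). The sigmoid is decreasing in the
#'   energy trait: raising the activation barrier slows nucleation.
#' @param temperature Kelvin (default 303, the selection temperature).
#' @return A `nuc_landscape` object.
#' @export
landscape <- function(first_order,
                      couplings = tibble::tibble(mut1 = character(),
                                                 mut2 = character(),
                                                 coupling = numeric()),
                      sigmoid = c(L = -2, U = 0, s = 1),
                      temperature = 303) {
  stopifnot(all(c("mutation", "ddg_act") %in% names(first_order)),
            all(c("mut1", "mut2", "coupling") %in% names(couplings)))
  if (!(sigmoid[["L"]] < sigmoid[["U"]]) || sigmoid[["s"]] <= 0) {
    stop("sigmoid must satisfy L < U and s > 0")
  }
  structure(
    list(first_order = tibble::as_tibble(first_order),
         couplings = tibble::as_tibble(couplings),
         sigmoid = sigmoid, temperature = temperature),
    class = "nuc_landscape"
  )
}

#' @export
print.nuc_landscape <- function(x, ...) {
  cat("<nuc_landscape> ", nrow(x$first_order), " first-order terms, ",
      sum(x$couplings$coupling != 0), " nonzero couplings; sigmoid L=",
      x$sigmoid[["L"]], " U=", x$sigmoid[["U"]], " s=", x$sigmoid[["s"]],
      "\n", sep = "")
  invisible(x)
}

# decreasing bounded sigmoid: g(phi) = L + (U - L) / (1 + exp(s * phi))
sigmoid_gr <- function(phi, sigmoid) {
  sigmoid[["L"]] + (sigmoid[["U"]] - sigmoid[["L"]]) *
    stats::plogis(-sigmoid[["s"]] * phi)
}

pair_key <- function(mut1, mut2) {
  p1 <- as.integer(stringr::str_extract(mut1, "\\d+"))
  p2 <- as.integer(stringr::str_extract(mut2, "\\d+"))
  swap <- p1 > p2
  ifelse(swap, paste(mut2, mut1, sep = ":"), paste(mut1, mut2, sep = ":"))
}

#' Sample a random ground-truth landscape for a set of designs
#'
#' First-order effects are drawn from a two-component mixture calibrated to
#' the observed sign split of mutational effects on nucleation: most
#' mutations slow nucleation (positive change in activation energy), a
#' minority accelerate it, and the rest are near-neutral. Pairwise couplings
#' are sparse with heavy-tailed magnitudes, placed only between co-mutable
#' position pairs.
#'
#' @param designs A `library_design` or list of them.
#' @param coupling_density Fraction of possible couplings that are nonzero.
#' @param effects List of mixture parameters: `p_increase`, `p_decrease`
#'   (probabilities of barrier-raising / barrier-lowering effects),
#'   `mean_increase`, `mean_decrease` (mean |effect| in kcal/mol, gamma with
#'   shape 2), `sd_null` (sd of the near-neutral component).
#' @param coupling_scale Scale of the heavy-tailed (Student-t, 3 df) coupling
#'   magnitude distribution, kcal/mol.
#' @param sigmoid,temperature Passed to [landscape()].
#' @param seed Integer seed; identical seeds give identical landscapes.
#' @return A `nuc_landscape`.
#' @export
sample_landscape <- function(designs, coupling_density = 0.1,
                             effects = list(p_increase = 0.72,
                                            p_decrease = 0.14,
                                            mean_increase = 1.2,
                                            mean_decrease = 0.5,
                                            sd_null = 0.05),
                             coupling_scale = 0.5,
                             sigmoid = c(L = -2, U = 0, s = 1),
                             temperature = 303, seed = 1) {
  if (inherits(designs, "library_design")) designs <- list(designs)
  stopifnot(coupling_density >= 0, coupling_density <= 1)
  withr::local_seed(seed)

  uni <- model_terms(designs, order = 2L)
  n1 <- length(uni$first_order)
  cls <- sample(c("up", "down", "null"), n1, replace = TRUE,
                prob = c(effects$p_increase, effects$p_decrease,
                         1 - effects$p_increase - effects$p_decrease))
  dd <- numeric(n1)
  dd[cls == "up"] <- stats::rgamma(sum(cls == "up"), shape = 2,
                                   scale = effects$mean_increase / 2)
  dd[cls == "down"] <- -stats::rgamma(sum(cls == "down"), shape = 2,
                                      scale = effects$mean_decrease / 2)
  dd[cls == "null"] <- stats::rnorm(sum(cls == "null"), 0, effects$sd_null)
  fo <- tibble::tibble(mutation = uni$first_order, ddg_act = dd)

  cp <- tibble::tibble(mut1 = character(), mut2 = character(),
                       coupling = numeric())
  if (length(uni$couplings) > 0L && coupling_density > 0) {
    on <- stats::runif(length(uni$couplings)) < coupling_density
    if (any(on)) {
      keys <- uni$couplings[on]
      parts <- stringr::str_split_fixed(keys, ":", 2)
      cp <- tibble::tibble(
        mut1 = parts[, 1], mut2 = parts[, 2],
        coupling = stats::rt(sum(on), df = 3) * coupling_scale
      )
    }
  }
  landscape(fo, cp, sigmoid = sigmoid, temperature = temperature)
}

variant_column <- function(variants) {
  if (is.data.frame(variants)) {
    col <- intersect(c("variant", "mutations"), names(variants))[1]
    if (is.na(col)) stop("variant table needs a `variant` or `mutations` column")
    variants[[col]]
  } else as.character(variants)
}

# additive energy trait: sum of first-order terms plus applicable couplings
energy_trait <- function(land, variants) {
  muts <- variant_column(variants)
  parsed <- parse_mutations(muts)
  ids <- mutation_id(parsed$wt, parsed$position, parsed$alt)
  lookup <- stats::setNames(land$first_order$ddg_act, land$first_order$mutation)
  unknown <- setdiff(unique(ids), names(lookup))
  if (length(unknown) > 0L) {
    stop("mutation not in landscape: '", unknown[[1]], "'")
  }
  phi <- numeric(length(muts))
  if (nrow(parsed) > 0L) {
    contrib <- rowsum(lookup[ids], parsed$variant_index)
    phi[as.integer(rownames(contrib))] <- contrib[, 1]
  }
  if (nrow(land$couplings) > 0L && nrow(parsed) > 0L) {
    ck <- stats::setNames(land$couplings$coupling,
                          pair_key(land$couplings$mut1, land$couplings$mut2))
    pj <- dplyr::inner_join(
      dplyr::select(parsed, "variant_index", id1 = "position") |>
        dplyr::mutate(m1 = ids),
      dplyr::select(parsed, "variant_index", id2 = "position") |>
        dplyr::mutate(m2 = ids),
      by = "variant_index", relationship = "many-to-many"
    )
    pj <- pj[pj$id1 < pj$id2, , drop = FALSE]
    if (nrow(pj) > 0L) {
      val <- ck[paste(pj$m1, pj$m2, sep = ":")]
      val[is.na(val)] <- 0
      add <- rowsum(val, pj$variant_index)
      phi[as.integer(rownames(add))] <- phi[as.integer(rownames(add))] + add[, 1]
    }
  }
  phi
}

#' Noise-free relative growth rate of variants under a landscape
#'
#' The energy trait of a variant is the sum of its first-order activation
#' energy terms plus any couplings among its mutation pairs; the relative
#' growth rate is the decreasing bounded sigmoid of the trait, centered so
#' the wild type (trait 0) has growth rate 0.
#'
#' @param land A `nuc_landscape`.
#' @param variants Character vector of mutation strings (`""` = wild type) or
#'   a tibble with a `variant`/`mutations` column.
#' @return Numeric vector of centered relative growth rates.
#' @export
growth_rate_from_energy <- function(land, variants) {
  stopifnot(inherits(land, "nuc_landscape"))
  phi <- energy_trait(land, variants)
  sigmoid_gr(phi, land$sigmoid) - sigmoid_gr(0, land$sigmoid)
}

#' Simulate a pooled selection experiment
#'
#' Input counts are multinomial over a log-normal library-composition draw
#' (shared across replicates, as for a single transformed library); output
#' counts are multinomial with weights proportional to realized input
#' frequency times `exp(growth rate)`, i.e. one effective exponential growth
#' round. Replicates are sampled independently; everything is deterministic
#' given the seed.
#'
#' @param land A `nuc_landscape`.
#' @param variants Character vector of mutation strings or tibble with a
#'   `variant`/`mutations` column. `""` is the wild type.
#' @param depth Reads per pool (default 100 per variant).
#' @param replicates Number of selection replicates.
#' @param overdispersion Sd of a per-variant log-normal jitter on the expected
#'   output frequency (0 = pure multinomial noise).
#' @param n_wt_synonyms Extra synonymous wild-type entries (distinct
#'   nucleotide sequences with wild-type growth), used downstream to center
#'   growth rates.
#' @param input_spread Sd of the log-normal library-composition draw.
#' @param seed Integer seed.
#' @return A tibble (class `nuc_counts`): `variant`, `is_wt_synonym`, and
#'   `input_rep*` / `output_rep*` columns; attributes `depth`, `seed`,
#'   `true_gr`.
#' @export
simulate_selection <- function(land, variants, depth = NULL, replicates = 3,
                               overdispersion = 0, n_wt_synonyms = 0,
                               input_spread = 0.5, seed = 1) {
  stopifnot(inherits(land, "nuc_landscape"), replicates >= 1)
  muts <- variant_column(variants)
  if (!is.null(depth) && depth <= 0) stop("sequencing depth must be positive")
  vtab <- tibble::tibble(id = muts, variant = muts, is_wt_synonym = FALSE)
  if (n_wt_synonyms > 0L) {
    vtab <- dplyr::bind_rows(vtab, tibble::tibble(
      id = paste0("WT_syn", seq_len(n_wt_synonyms)),
      variant = "", is_wt_synonym = TRUE
    ))
  }
  n <- nrow(vtab)
  if (is.null(depth)) depth <- 100L * n
  withr::local_seed(seed)
  gr <- growth_rate_from_energy(land, vtab$variant)
  p0 <- exp(stats::rnorm(n, 0, input_spread))
  p0 <- p0 / sum(p0)
  for (r in seq_len(replicates)) {
    n_in <- as.vector(stats::rmultinom(1, depth, p0))
    w <- n_in * exp(gr)
    if (overdispersion > 0) w <- w * exp(stats::rnorm(n, 0, overdispersion))
    n_out <- as.vector(stats::rmultinom(1, depth, w / sum(w)))
    vtab[[paste0("input_rep", r)]] <- n_in
    vtab[[paste0("output_rep", r)]] <- n_out
  }
  attr(vtab, "depth") <- depth
  attr(vtab, "seed") <- seed
  attr(vtab, "true_gr") <- gr
  class(vtab) <- c("nuc_counts", class(vtab))
  vtab
}

#' Surrogate per-mutation fibril-stability tables
#'
#' Generates per-structure tables of assembly stability changes standing in
#' for predicted fibril free-energy changes. Within `region`, the per-monomer
#' stability change is `correlation * ddg_act + (1 - correlation) * z` with
#' `z` an independent draw of matching scale, so `correlation = 1` yields
#' activation/stability ratios of exactly 1 there; outside the region values
#' are independent. Assembly values are per-monomer times the chain count.
#'
#' @param land A `nuc_landscape` (first-order terms provide `ddg_act`).
#' @param structures Tibble with `structure` (id) and `n_chains` (stacked
#'   chains per filament, e.g. 4, or 3 for trimer-only structures), and
#'   optionally `correlation` per structure overriding the global value.
#' @param region Integer positions where stability tracks activation energy.
#' @param correlation In `[0, 1]`; agreement inside `region`.
#' @param noise_sd Additional Gaussian noise sd on per-monomer values.
#' @param seed Integer seed.
#' @return Tibble: `structure`, `mutation`, `position`, `assembly_ddg`,
#'   `n_chains`.
#' @export
generate_stability_table <- function(land, structures, region = 29:42,
                                     correlation = 1, noise_sd = 0, seed = 1) {
  stopifnot(inherits(land, "nuc_landscape"),
            all(c("structure", "n_chains") %in% names(structures)))
  withr::local_seed(seed)
  fo <- land$first_order
  pos <- parse_mutations(fo$mutation)$position
  purrr::pmap_dfr(structures, function(structure, n_chains, ...) {
    rho <- list(...)$correlation %||% correlation
    z <- sample(abs(fo$ddg_act)) * sample(c(-1, 1), nrow(fo), replace = TRUE)
    per_mono <- ifelse(pos %in% region,
                       rho * fo$ddg_act + (1 - rho) * z,
                       z)
    per_mono <- per_mono + stats::rnorm(nrow(fo), 0, noise_sd)
    tibble::tibble(
      structure = structure,
      mutation = fo$mutation,
      position = pos,
      assembly_ddg = per_mono * n_chains,
      n_chains = n_chains
    )
  })
}

#' Write a minimal fibril-structure fixture in PDB format
#'
#' Builds a valid PDB text from either an explicit atom table (columns
#' `chain`, `resno`, `resname`, `atom`, `x`, `y`, `z`) or a residue table
#' (columns `chain`, `resno`, `resname`, `x`, `y`, `z` giving the C-alpha,
#' plus optional `scx`, `scy`, `scz` placing a CB side-chain atom). Backbone
#' N, C and O atoms are laid out around each C-alpha; glycine is emitted with
#' no side-chain atoms so its designated atom downstream is the C-alpha.
#'
#' @param spec Residue or atom tibble as described above.
#' @param path Optional file to write; when `NULL` the PDB text is returned.
#' @return The PDB text, invisibly when written to `path`.
#' @export
generate_fixture_structure <- function(spec, path = NULL) {
  stopifnot(is.data.frame(spec))
  base <- c("chain", "resno", "resname", "x", "y", "z")
  if (!all(base %in% names(spec))) {
    stop("structure specification must have columns: ",
         paste(setdiff(base, names(spec)), collapse = ", "))
  }
  if (!all(is.finite(spec$x) & is.finite(spec$y) & is.finite(spec$z))) {
    stop("structure specification contains non-finite coordinates")
  }
  if ("atom" %in% names(spec)) {
    atoms <- tibble::as_tibble(spec)
  } else {
    atoms <- purrr::pmap_dfr(spec, function(chain, resno, resname, x, y, z, ...) {
      extra <- list(...)
      rows <- tibble::tribble(
        ~atom, ~x, ~y, ~z,
        "N", x - 1.2, y - 0.8, z,
        "CA", x, y, z,
        "C", x + 1.2, y - 0.8, z,
        "O", x + 1.9, y - 1.8, z
      )
      if (toupper(resname) != "GLY") {
        sc <- c(extra$scx %||% x, extra$scy %||% (y + 1.5), extra$scz %||% z)
        rows <- dplyr::bind_rows(rows, tibble::tibble(
          atom = "CB", x = sc[[1]], y = sc[[2]], z = sc[[3]]
        ))
      }
      dplyr::mutate(rows, chain = chain, resno = resno,
                    resname = toupper(resname), .before = 1)
    })
  }
  atoms <- dplyr::arrange(atoms, .data$chain, .data$resno)
  lines <- character(0)
  serial <- 0L
  for (ch in unique(atoms$chain)) {
    sub <- atoms[atoms$chain == ch, , drop = FALSE]
    for (k in seq_len(nrow(sub))) {
      serial <- serial + 1L
      nm <- sub$atom[[k]]
      name_field <- if (nchar(nm) < 4L) sprintf(" %-3s", nm) else nm
      lines <- c(lines, sprintf(
        "ATOM  %5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial, name_field, sub$resname[[k]], ch, sub$resno[[k]],
        sub$x[[k]], sub$y[[k]], sub$z[[k]], 1, 0,
        substr(nm, 1L, 1L)
      ))
    }
    lines <- c(lines, "TER")
  }
  txt <- paste(c(lines, "END", ""), collapse = "\n")
  if (!is.null(path)) {
    writeLines(txt, path, sep = "")
    return(invisible(txt))
  }
  txt
}
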