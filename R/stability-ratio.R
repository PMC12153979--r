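# Phi-like ratio analysis: per-mutation changes in activation energy divided
# by changes in mature-fibril stability, after per-monomer normalization and
# a moderate-effect filter, with per-position means and polymorph ranking by
# root-mean-square distance of ratios to 1.

#' Per-monomer fibril stability change
#'
#' Assembly-level stability changes are computed on a stacked single-filament
#' multimer (four chains, or three where only three stacked chains are
#' deposited) and divided by the chain count to obtain per-monomer values.
#'
#' @param assembly_ddg Assembly stability change, kcal/mol.
#' @param n_chains Stacked chains used (>= 1).
#' @return Per-monomer stability change, kcal/mol.
#' @export
per_monomer_ddg <- function(assembly_ddg, n_chains) {
  if (any(n_chains < 1)) stop("chain count must be at least 1")
  assembly_ddg / n_chains
}

#' Moderate-effect filter for stability changes
#'
#' A mutation contributes a ratio only when its per-monomer stability change
#' is moderate: `lower < |ddg| < upper` (default 0.6 and 10 kcal/mol). Below
#' the lower bound the ratio denominator is unreliable; above the upper bound
#' the mutation likely perturbs the fibril structure itself.
#'
#' @param ddg Per-monomer stability changes, kcal/mol.
#' @param lower,upper Bounds on `|ddg|`, kcal/mol.
#' @return Tibble: `ddg`, `pass`, `reason` (`NA` when passing).
#' @export
filter_moderate <- function(ddg, lower = 0.6, upper = 10) {
  pass <- abs(ddg) > lower & abs(ddg) < upper
  tibble::tibble(
    ddg = ddg,
    pass = pass,
    reason = dplyr::case_when(
      pass ~ NA_character_,
      abs(ddg) <= lower ~ "below_lower_bound",
      TRUE ~ "structure_perturbing"
    )
  )
}

#' Activation/stability energy ratio table
#'
#' Joins first-order activation energy terms with a per-structure stability
#' table, normalizes stability to per-monomer values, applies the
#' moderate-effect filter and forms the ratio `R = ddg_act / ddg_stability`
#' per passing mutation. A ratio near 1 indicates the mutation affects the
#' activation barrier as much as mature-fibril stability, i.e. a fibril-like
#' environment of that residue in the transition state.
#'
#' @param ddg_act Tibble of calibrated first-order terms: `term` (or
#'   `mutation`) and `estimate` (or `ddg_act`), kcal/mol.
#' @param stability Tibble: `structure`, `mutation`, `assembly_ddg`,
#'   `n_chains`.
#' @param lower,upper Moderate-effect bounds passed to [filter_moderate()].
#' @return Tibble (one row per structure x passing mutation): `structure`,
#'   `mutation`, `position`, `ddg_act`, `ddg_stab`, `ratio`; the full
#'   pre-filter join is attached as attribute `"unfiltered"`.
#' @export
compute_ratios <- function(ddg_act, stability, lower = 0.6, upper = 10) {
  names(ddg_act)[names(ddg_act) == "term"] <- "mutation"
  names(ddg_act)[names(ddg_act) == "estimate"] <- "ddg_act"
  stopifnot(all(c("mutation", "ddg_act") %in% names(ddg_act)),
            all(c("structure", "mutation", "assembly_ddg", "n_chains") %in%
                  names(stability)))
  joined <- dplyr::inner_join(
    dplyr::select(ddg_act, "mutation", "ddg_act"),
    stability, by = "mutation"
  )
  if (nrow(joined) == 0L) {
    stop("no shared mutations between activation terms and stability table")
  }
  joined$ddg_stab <- per_monomer_ddg(joined$assembly_ddg, joined$n_chains)
  flt <- filter_moderate(joined$ddg_stab, lower = lower, upper = upper)
  joined$pass <- flt$pass
  joined$position <- parse_mutations(joined$mutation)$position
  out <- joined |>
    dplyr::filter(.data$pass) |>
    dplyr::mutate(ratio = .data$ddg_act / .data$ddg_stab) |>
    dplyr::select("structure", "mutation", "position", "ddg_act",
                  "ddg_stab", "ratio")
  attr(out, "unfiltered") <- joined
  out
}

#' Per-position mean ratios
#'
#' Ratios are computed per mutation and then averaged per position over the
#' mutations passing the moderate-effect filter (mean of ratios, not ratio
#' of means).
#'
#' @param ratios Output of [compute_ratios()].
#' @return Tibble: `structure`, `position`, `mean_ratio`, `mean_ddg_act`,
#'   `mean_ddg_stab`, `n_mutations`.
#' @export
position_ratio_summary <- function(ratios) {
  ratios |>
    dplyr::group_by(.data$structure, .data$position) |>
    dplyr::summarise(
      mean_ratio = mean(.data$ratio),
      mean_ddg_act = mean(.data$ddg_act),
      mean_ddg_stab = mean(.data$ddg_stab),
      n_mutations = dplyr::n(),
      .groups = "drop"
    )
}

#' Rank fibril polymorphs by agreement of ratios with 1
#'
#' For each structure, the root mean square distance of its (optionally
#' region-masked) ratios to 1; the best-ranked polymorph is the one whose
#' mutations affect nucleation and fibril stability most alike, i.e. the
#' most transition-state-like fold in that region.
#'
#' @param ratios Output of [compute_ratios()].
#' @param region Optional integer positions to restrict to (e.g. 29:42 for
#'   the C-terminal aggregation-prone region).
#' @return Tibble ranked ascending by `rmsd`: `structure`, `rmsd`, `n`,
#'   `rank`. Structures with no masked ratios are dropped with a warning.
#' @export
rank_polymorphs <- function(ratios, region = NULL) {
  all_structures <- unique(ratios$structure)
  if (!is.null(region)) {
    ratios <- ratios[ratios$position %in% region, , drop = FALSE]
  }
  dropped <- setdiff(all_structures, unique(ratios$structure))
  if (length(dropped) > 0L) {
    warning("structure(s) without ratios in the masked region dropped: ",
            paste(dropped, collapse = ", "))
  }
  ratios |>
    dplyr::group_by(.data$structure) |>
    dplyr::summarise(
      rmsd = sqrt(mean((.data$ratio - 1)^2)),
      n = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$rmsd) |>
    dplyr::mutate(rank = dplyr::row_number())
}
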