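# Aggregating pairwise energetic couplings into per-position-pair
# interaction scores, extracting top interacting pairs, and correlating
# scores with inverse structural distances.

#' Interaction scores from energetic couplings
#'
#' Couplings are grouped by unordered position pair; the interaction score
#' of a pair is the mean absolute coupling over all its mutation
#' combinations (16 for designs with 4 alternatives per site).
#'
#' @param couplings Tibble with `mut1`, `mut2`, `coupling` (e.g. from
#'   [coupling_table()] on an order-2 model).
#' @return Tibble: `pos_i`, `pos_j` (`pos_i < pos_j`), `score`
#'   (mean |coupling|, kcal/mol), `n_couplings`, `percentile` (percentile
#'   rank of the score among all pairs).
#' @export
interaction_scores <- function(couplings) {
  stopifnot(all(c("mut1", "mut2", "coupling") %in% names(couplings)))
  if (nrow(couplings) == 0L) stop("no couplings to aggregate")
  p1 <- as.integer(stringr::str_extract(couplings$mut1, "\\d+"))
  p2 <- as.integer(stringr::str_extract(couplings$mut2, "\\d+"))
  out <- tibble::tibble(
    pos_i = pmin(p1, p2), pos_j = pmax(p1, p2),
    coupling = couplings$coupling
  ) |>
    dplyr::group_by(.data$pos_i, .data$pos_j) |>
    dplyr::summarise(score = mean(abs(.data$coupling)),
                     n_couplings = dplyr::n(), .groups = "drop")
  out$percentile <- 100 * (rank(out$score) - 1) / max(nrow(out) - 1, 1)
  out
}

#' Top interacting position pairs
#'
#' Pairs whose interaction score reaches the given percentile of the
#' empirical score distribution (linear-interpolation quantile); ties at the
#' threshold are all kept. Forty pairs at the 90th percentile yield the top
#' four.
#'
#' @param scores Output of [interaction_scores()].
#' @param percentile Percentile threshold in `[0, 100]`.
#' @return The qualifying rows of `scores`, sorted by decreasing score.
#' @export
top_pairs <- function(scores, percentile = 90) {
  stopifnot(nrow(scores) >= 1L, percentile >= 0, percentile <= 100)
  thr <- stats::quantile(scores$score, percentile / 100, names = FALSE)
  scores |>
    dplyr::filter(.data$score >= thr) |>
    dplyr::arrange(dplyr::desc(.data$score))
}

#' Correlate interaction scores with inverse structural distance
#'
#' Spearman rank correlation between per-pair interaction scores and the
#' inverse of scHA_min from a fibril structure, with a two-sided p-value
#' (exact where the sample permits, t-approximation otherwise). Pairs
#' missing a distance are dropped.
#'
#' @param scores Output of [interaction_scores()].
#' @param distances A `nuc_distances` or a long tibble with `pos_i`, `pos_j`,
#'   `scha_min` (and optionally `structure`).
#' @return One-row tibble: `structure`, `rho`, `p_value`, `n_pairs`,
#'   `n_dropped`.
#' @export
correlate_with_distance <- function(scores, distances) {
  dl <- if (inherits(distances, "nuc_distances")) tidy(distances) else distances
  stopifnot(all(c("pos_i", "pos_j", "scha_min") %in% names(dl)))
  joined <- dplyr::inner_join(scores, dl, by = c("pos_i", "pos_j"))
  n_dropped <- nrow(scores) - nrow(joined)
  if (nrow(joined) < 3L) stop("need at least 3 pairs with distances")
  sid <- if ("structure" %in% names(dl)) dl$structure[[1]] else NA_character_
  if (stats::sd(joined$score) == 0 || stats::sd(joined$scha_min) == 0) {
    return(tibble::tibble(structure = sid, rho = NA_real_, p_value = NA_real_,
                          n_pairs = nrow(joined), n_dropped = n_dropped))
  }
  ct <- suppressWarnings(
    stats::cor.test(joined$score, 1 / joined$scha_min, method = "spearman")
  )
  tibble::tibble(
    structure = sid,
    rho = unname(ct$estimate),
    p_value = ct$p.value,
    n_pairs = nrow(joined),
    n_dropped = n_dropped
  )
}

#' Per-position mean first-order activation energies
#'
#' Arithmetic mean of the first-order terms over the substitutions at each
#' position (up to 19 per position for fully mutagenized sites).
#'
#' @param terms A `nuc_model` or a tibble with `term`/`mutation` and
#'   `estimate` columns.
#' @return Tibble: `position`, `mean_ddg_act`, `n_substitutions`.
#' @export
position_summary <- function(terms) {
  if (inherits(terms, "nuc_model")) {
    terms <- terms$terms[terms$terms$type == "first_order", , drop = FALSE]
  }
  names(terms)[names(terms) == "mutation"] <- "term"
  names(terms)[names(terms) == "ddg_act"] <- "estimate"
  stopifnot(all(c("term", "estimate") %in% names(terms)))
  tibble::tibble(
    position = parse_mutations(terms$term)$position,
    estimate = terms$estimate
  ) |>
    dplyr::group_by(.data$position) |>
    dplyr::summarise(mean_ddg_act = mean(.data$estimate),
                     n_substitutions = dplyr::n(), .groups = "drop")
}
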