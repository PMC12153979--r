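# ggplot2 views of the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Observed versus predicted growth rates for a fitted energy model
#'
#' @param object A `nuc_model`.
#' @param growth The growth-rate tibble the model was fitted to.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.nuc_model <- function(object, growth, ...) {
  df <- tibble::tibble(
    observed = growth$gr,
    predicted = predict_growth(object, growth$variant)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$predicted, .data$observed)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.6) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "red") +
    ggplot2::labs(
      x = "Predicted relative growth rate",
      y = "Observed relative growth rate",
      title = sprintf("Order-%d energy model%s", object$order,
                      if (!is.na(object$r2_heldout))
                        sprintf(" (held-out R² = %.2f)", object$r2_heldout)
                      else "")
    ) +
    ggplot2::theme_minimal()
}

#' Heatmap of first-order activation energy terms
#'
#' Position by substitution heatmap of the inferred changes in free energy
#' of activation, with per-position means along the top.
#'
#' @param model A `nuc_model` (or tibble with `term`, `estimate`).
#' @return A ggplot.
#' @export
plot_energy_heatmap <- function(model) {
  terms <- if (inherits(model, "nuc_model")) {
    model$terms[model$terms$type == "first_order", ]
  } else model
  parsed <- parse_mutations(terms$term)
  df <- tibble::tibble(position = parsed$position, alt = parsed$alt,
                       estimate = terms$estimate)
  ggplot2::ggplot(df, ggplot2::aes(.data$position, .data$alt,
                                   fill = .data$estimate)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  name = "ΔΔG‡") +
    ggplot2::labs(x = "Position", y = "Substitution") +
    ggplot2::theme_minimal()
}

#' Interaction-score matrix plot
#'
#' @param scores Output of [interaction_scores()].
#' @param contacts Optional logical contact matrix from [contact_map()];
#'   contacting pairs are marked.
#' @return A ggplot.
#' @export
plot_interaction_matrix <- function(scores, contacts = NULL) {
  p <- ggplot2::ggplot(scores, ggplot2::aes(.data$pos_i, .data$pos_j,
                                            fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "mean |ΔΔΔG‡|") +
    ggplot2::labs(x = "Position i", y = "Position j") +
    ggplot2::theme_minimal()
  if (!is.null(contacts)) {
    res <- as.integer(rownames(contacts))
    idx <- which(contacts & upper.tri(contacts), arr.ind = TRUE)
    cdf <- tibble::tibble(pos_i = res[idx[, 1]], pos_j = res[idx[, 2]])
    cdf <- dplyr::semi_join(cdf, scores, by = c("pos_i", "pos_j"))
    p <- p + ggplot2::geom_point(data = cdf, ggplot2::aes(.data$pos_i, .data$pos_j),
                                 inherit.aes = FALSE, shape = 8, size = 2)
  }
  p
}

#' Per-position mean activation/stability ratios across polymorphs
#'
#' @param ratios Output of [compute_ratios()].
#' @return A ggplot of per-position mean ratios, one line per structure,
#'   with the transition-state-like reference ratio of 1 marked.
#' @export
plot_ratio_positions <- function(ratios) {
  summ <- position_ratio_summary(ratios)
  ggplot2::ggplot(summ, ggplot2::aes(.data$position, .data$mean_ratio,
                                     colour = .data$structure)) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "Position",
                  y = "Mean ΔΔG‡/ΔΔG ratio") +
    ggplot2::theme_minimal()
}
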