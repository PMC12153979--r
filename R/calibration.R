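# Kinetic calibration: transition-state theory links nucleation rate
# constants to changes in free energy of activation; a linear fit of model
# trait values against rate-derived energies converts trait units to
# kcal/mol. Combinatorial-model terms are recentered onto the double-mutant
# energy scale by an affine map fitted over shared terms.

#' Universal gas constant in kcal/(mol K)
#' @export
GAS_CONSTANT_KCAL <- 1.987e-3

#' Change in free energy of activation from nucleation rate constants
#'
#' Transition-state theory with a mutation-invariant pre-factor:
#' `ddG_act = R T ln(k_wt / k_var)`, so a variant nucleating slower than the
#' wild type has a positive change in activation energy. Multiplicative rate
#' terms (nucleation times elongation) may be used directly provided
#' elongation is mutation-invariant, in which case it cancels in the ratio.
#'
#' @param k_wt,k_var Positive rate constants (any consistent units).
#' @param temperature Kelvin (default 303).
#' @return Change in free energy of activation, kcal/mol.
#' @examples
#' ddg_from_rates(2, 1)  # halving the rate costs R*T*ln(2) ~ 0.417 kcal/mol
#' @export
ddg_from_rates <- function(k_wt, k_var, temperature = 303) {
  if (any(k_wt <= 0) || any(k_var <= 0)) {
    stop("rate constants must be positive")
  }
  GAS_CONSTANT_KCAL * temperature * log(k_wt / k_var)
}

#' Fit the trait-to-energy calibration regression
#'
#' Ordinary least squares of model trait values on experimentally derived
#' activation energies (that orientation: trait as response). The slope is
#' the trait change per kcal/mol and is used by [apply_calibration()] to
#' convert model terms into energy units.
#'
#' @param data Tibble with columns `trait` and `ddg_exp` (kcal/mol), one row
#'   per variant shared between the model and the kinetic data.
#' @param rate_type Label recorded in the result (`"secondary"` nucleation
#'   rates are the default calibration source).
#' @return A `nuc_calibration`: `slope`, `intercept`, `r2`, `n`, `rate_type`.
#' @export
fit_calibration <- function(data, rate_type = "secondary") {
  stopifnot(all(c("trait", "ddg_exp") %in% names(data)))
  data <- data[is.finite(data$trait) & is.finite(data$ddg_exp), , drop = FALSE]
  if (nrow(data) < 2L) stop("calibration needs at least 2 shared variants")
  if (stats::sd(data$ddg_exp) == 0) {
    stop("experimental activation energies have zero variance")
  }
  fit <- stats::lm(trait ~ ddg_exp, data = data)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((data$trait - mean(data$trait))^2)
  structure(
    list(
      slope = unname(stats::coef(fit)[["ddg_exp"]]),
      intercept = unname(stats::coef(fit)[["(Intercept)"]]),
      r2 = if (ss_tot == 0) 1 else 1 - ss_res / ss_tot,
      n = nrow(data),
      rate_type = rate_type
    ),
    class = "nuc_calibration"
  )
}

#' @export
print.nuc_calibration <- function(x, ...) {
  cat("<nuc_calibration> trait = ", signif(x$slope, 3), " * ddG_act + ",
      signif(x$intercept, 3), "  (R^2 = ", signif(x$r2, 3), ", n = ", x$n,
      ", ", x$rate_type, " rates)\n", sep = "")
  invisible(x)
}

#' @export
glance.nuc_calibration <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept, r2 = x$r2,
                 n = x$n, rate_type = x$rate_type)
}

#' Convert model terms to kcal/mol using a calibration fit
#'
#' Every first-order term and coupling is divided by the calibration slope.
#' Energy terms are differences, so the regression intercept does not enter.
#'
#' @param model A `nuc_model` in trait units.
#' @param calibration A `nuc_calibration` (or a bare nonzero slope).
#' @return The model with terms and sigmoid-free quantities in kcal/mol.
#' @export
apply_calibration <- function(model, calibration) {
  stopifnot(inherits(model, "nuc_model"))
  slope <- if (inherits(calibration, "nuc_calibration")) {
    calibration$slope
  } else as.numeric(calibration)
  if (!is.finite(slope) || slope == 0) {
    stop("calibration slope must be finite and nonzero")
  }
  model$terms$estimate <- model$terms$estimate / slope
  model$terms$se <- model$terms$se / abs(slope)
  model$units <- "kcal/mol"
  model$calibration_slope <- slope
  model
}

#' Recenter combinatorial-model energies onto the double-mutant scale
#'
#' Combinatorial libraries are anchored by an artificial reference, leaving
#' their energy terms on a shifted, rescaled axis. A linear regression of
#' double-mutant-scale energies on combinatorial-scale energies over the
#' shared terms gives an affine map which is applied to all combinatorial
#' first-order terms; couplings, being double differences, receive the slope
#' only.
#'
#' @param comb_terms Tibble (`term`, `estimate`) on the combinatorial scale.
#' @param double_terms Tibble (`term`, `estimate`) on the double-mutant
#'   (calibrated) scale.
#' @return List: `slope`, `intercept`, `n_shared`, and `terms` (all
#'   combinatorial terms remapped, with a `type` column when present).
#' @export
recenter_combinatorial <- function(comb_terms, double_terms) {
  shared <- dplyr::inner_join(
    dplyr::select(comb_terms, "term", comb = "estimate"),
    dplyr::select(double_terms, "term", dbl = "estimate"),
    by = "term"
  )
  if (nrow(shared) < 2L) {
    stop("need at least 2 shared terms to recenter; found: ",
         paste(shared$term, collapse = ", "))
  }
  if (stats::sd(shared$comb) == 0) {
    stop("combinatorial terms have zero variance over the shared set")
  }
  fit <- stats::lm(dbl ~ comb, data = shared)
  a <- unname(stats::coef(fit)[["comb"]])
  b <- unname(stats::coef(fit)[["(Intercept)"]])
  out <- comb_terms
  is_cpl <- if ("type" %in% names(out)) out$type == "coupling" else
    grepl(":", out$term, fixed = TRUE)
  out$estimate <- ifelse(is_cpl, a * out$estimate, a * out$estimate + b)
  list(slope = a, intercept = b, n_shared = nrow(shared), terms = out)
}
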