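# Global-epistasis energy model: additive activation-energy terms with
# optional pairwise couplings, composed with a decreasing bounded sigmoid
# mapping the energy trait to relative growth rate. Fitting is weighted
# nonlinear least squares with elastic (L1 + L2) regularization, 10-fold
# cross-validation for held-out accuracy and across-fold term dispersion as
# the term standard error.

#' Model term universe implied by library designs
#'
#' First-order terms are the distinct (position, non-WT amino acid)
#' substitutions across the designs; coupling terms (order 2) are all
#' alternative pairs at position pairs co-mutable within at least one design.
#'
#' @param designs A `library_design` or list of them.
#' @param order 1 or 2.
#' @return List with `first_order` (mutation ids) and `couplings` (pair keys
#'   `"mut1:mut2"`, position-sorted; empty for order 1).
#' @export
model_terms <- function(designs, order = 1L) {
  if (inherits(designs, "library_design")) designs <- list(designs)
  fo <- character(0)
  pair_map <- list()
  for (d in designs) {
    pos <- d$sites$position
    wt <- d$sites$wt
    alts <- site_alternatives(d)
    ids <- purrr::pmap(list(wt, pos, alts), function(w, p, a) {
      if (length(a)) mutation_id(w, p, a) else character()
    })
    fo <- union(fo, unlist(ids))
    if (order >= 2L && d$max_order >= 2L && length(pos) >= 2L) {
      ord <- order(pos)
      for (ii in seq_along(pos)[-length(pos)]) {
        for (jj in (ii + 1L):length(pos)) {
          i <- ord[[ii]]; j <- ord[[jj]]
          if (!length(ids[[i]]) || !length(ids[[j]])) next
          key <- paste(pos[[i]], pos[[j]], sep = "-")
          g <- expand.grid(ids[[i]], ids[[j]], stringsAsFactors = FALSE)
          pair_map[[key]] <- union(pair_map[[key]], paste(g[[1]], g[[2]], sep = ":"))
        }
      }
    }
  }
  list(first_order = sort(fo),
       couplings = sort(unique(unlist(pair_map))) %||% character(0))
}

#' Encode variants as a sparse binary feature matrix
#'
#' One indicator column per first-order term and (order 2) one per coupling;
#' the wild type is the all-zero row.
#'
#' @param variants Character vector of mutation strings (`""` = wild type).
#' @param terms Term universe from [model_terms()]; `NULL` derives first-order
#'   terms and (order 2) co-occurring pairs from the variants themselves.
#' @param order 1 or 2.
#' @return A sparse `dgCMatrix` with mutation / pair-key column names.
#' @export
encode_variants <- function(variants, terms = NULL, order = 1L) {
  muts <- variant_column(variants)
  parsed <- parse_mutations(muts)
  ids <- mutation_id(parsed$wt, parsed$position, parsed$alt)
  pj <- NULL
  if (order >= 2L && nrow(parsed) > 0L) {
    pj <- dplyr::inner_join(
      tibble::tibble(variant_index = parsed$variant_index,
                     p1 = parsed$position, m1 = ids),
      tibble::tibble(variant_index = parsed$variant_index,
                     p2 = parsed$position, m2 = ids),
      by = "variant_index", relationship = "many-to-many"
    )
    pj <- pj[pj$p1 < pj$p2, , drop = FALSE]
    pj$key <- paste(pj$m1, pj$m2, sep = ":")
  }
  if (is.null(terms)) {
    terms <- list(first_order = sort(unique(ids)),
                  couplings = if (is.null(pj)) character(0) else
                    sort(unique(pj$key)))
  }
  cols <- c(terms$first_order,
            if (order >= 2L) terms$couplings else character(0))
  fo_idx <- match(ids, terms$first_order)
  if (anyNA(fo_idx)) {
    stop("mutation outside the declared term space: '",
         ids[which(is.na(fo_idx))[1]], "'")
  }
  i <- parsed$variant_index
  j <- fo_idx
  if (!is.null(pj) && nrow(pj) > 0L) {
    cp_idx <- match(pj$key, terms$couplings)
    known <- !is.na(cp_idx)
    i <- c(i, pj$variant_index[known])
    j <- c(j, length(terms$first_order) + cp_idx[known])
  }
  Matrix::sparseMatrix(
    i = i, j = j, x = 1,
    dims = c(length(muts), length(cols)),
    dimnames = list(NULL, cols)
  )
}

#' Append an artificial reference variant to a growth-rate table
#'
#' Combinatorial libraries may not contain the wild type; the reference is
#' then introduced artificially with relative growth rate 0 and a large
#' error (default 100) so it anchors the model without constraining the fit.
#'
#' @param growth Merged growth-rate tibble (`variant`, `gr`, `sigma`).
#' @param reference Mutation string of the reference (default `""`, wild
#'   type).
#' @param sigma Error assigned to the artificial row.
#' @return Growth table with the reference present exactly once.
#' @export
add_reference_variant <- function(growth, reference = "", sigma = 100) {
  if (any(growth$variant == reference)) {
    warning("reference variant already present; table unchanged")
    return(growth)
  }
  dplyr::bind_rows(growth, tibble::tibble(
    variant = reference, gr = 0, sigma = sigma
  ))
}

# objective + analytic gradient for the penalized weighted fit.
# par = c(theta, [a = L, b = log(U - L)]); sigmoid g(phi) = a + e^b * plogis(-phi)
model_objective <- function(par, X, y, w, lambda, fixed_sigmoid, eps = 1e-8) {
  p <- ncol(X)
  theta <- par[seq_len(p)]
  if (is.null(fixed_sigmoid)) {
    a <- par[[p + 1L]]
    R <- exp(par[[p + 2L]])
  } else {
    a <- fixed_sigmoid[["L"]]
    R <- fixed_sigmoid[["U"]] - fixed_sigmoid[["L"]]
  }
  phi <- as.vector(X %*% theta)
  sig <- stats::plogis(-phi)
  pred <- a + R * sig
  res <- y - pred
  pen <- lambda * (sum(sqrt(theta^2 + eps)) + sum(theta^2))
  sum(w * res^2) + pen
}

model_gradient <- function(par, X, y, w, lambda, fixed_sigmoid, eps = 1e-8) {
  p <- ncol(X)
  theta <- par[seq_len(p)]
  learn <- is.null(fixed_sigmoid)
  if (learn) {
    a <- par[[p + 1L]]
    R <- exp(par[[p + 2L]])
  } else {
    a <- fixed_sigmoid[["L"]]
    R <- fixed_sigmoid[["U"]] - fixed_sigmoid[["L"]]
  }
  phi <- as.vector(X %*% theta)
  sig <- stats::plogis(-phi)
  pred <- a + R * sig
  res <- y - pred
  # d pred / d phi = -R * sig * (1 - sig)
  common <- -2 * w * res
  dtheta <- as.vector(Matrix::crossprod(X, common * (-R * sig * (1 - sig)))) +
    lambda * (theta / sqrt(theta^2 + eps) + 2 * theta)
  if (!learn) return(dtheta)
  da <- sum(common)
  db <- sum(common * sig) * R
  c(dtheta, da, db)
}

#' Fit the global-epistasis energy model to growth rates
#'
#' Minimizes the error-weighted squared loss between observed relative growth
#' rates and the sigmoid of the additive energy trait,
#' `sum(w * (gr - g(X theta))^2) + lambda * (|theta|_1 + |theta|_2^2)` with
#' `w = 1/sigma^2` and `g(phi) = L + (U - L)/(1 + exp(phi))`, `L` and `U`
#' learnable (the trait scale is fixed to 1 and absorbed into the energy
#' units; calibration to kcal/mol restores physical units). Held-out accuracy
#' is evaluated by k-fold cross-validation; the per-term standard error is
#' the standard deviation of the term across the fold fits.
#'
#' @param growth Growth-rate tibble: `variant` (mutation strings), `gr`,
#'   `sigma`.
#' @param order 1 (additive only) or 2 (additive + pairwise couplings).
#' @param lambda L1/L2 regularization weight (default `1e-5`).
#' @param folds Cross-validation folds (default 10).
#' @param seed Seed controlling fold assignment and restart jitter.
#' @param terms Term universe from [model_terms()]; `NULL` derives it from
#'   the data.
#' @param fixed_sigmoid Named numeric `c(L=, U=)` to fix the sigmoid bounds
#'   instead of learning them (used for oracle checks); `NULL` learns them.
#' @param restarts Random restarts for the full-data fit.
#' @param maxit Optimizer iteration cap per start.
#' @param cv Set `FALSE` to skip cross-validation (no SEs, faster).
#' @return A `nuc_model`: tibble of terms with estimates and SEs, sigmoid
#'   bounds, fold-level and pooled held-out R-squared, convergence info.
#' @export
fit_energy_model <- function(growth, order = 1L, lambda = 1e-5, folds = 10L,
                             seed = 1L, terms = NULL, fixed_sigmoid = NULL,
                             restarts = 3L, maxit = 2000L, cv = TRUE) {
  stopifnot(all(c("variant", "gr", "sigma") %in% names(growth)),
            all(is.finite(growth$gr)), all(is.finite(growth$sigma)),
            all(growth$sigma > 0))
  withr::local_seed(seed)
  X <- encode_variants(growth$variant, terms = terms, order = order)
  gr <- growth$gr
  w <- 1 / growth$sigma^2
  p <- ncol(X)
  learn <- is.null(fixed_sigmoid)

  base_init <- c(rep(0, p),
                 if (learn) c(min(gr) - 0.05 * stats::sd(gr),
                              log(max(diff(range(gr)), 0.1))))
  run <- function(init, Xf = X, yf = gr, wf = w, iters = maxit) {
    stats::optim(init, model_objective, model_gradient,
                 X = Xf, y = yf, w = wf, lambda = lambda,
                 fixed_sigmoid = fixed_sigmoid,
                 method = "L-BFGS-B",
                 control = list(maxit = iters, factr = 4.5e7))
  }
  fits <- list(run(base_init))
  if (restarts > 1L) {
    for (k in seq_len(restarts - 1L)) {
      init <- base_init
      init[seq_len(p)] <- stats::rnorm(p, 0, 0.3)
      fits[[k + 1L]] <- run(init)
    }
  }
  best <- fits[[which.min(purrr::map_dbl(fits, "value"))]]

  sigmoid <- if (learn) {
    c(L = best$par[[p + 1L]],
      U = best$par[[p + 1L]] + exp(best$par[[p + 2L]]), s = 1)
  } else c(L = fixed_sigmoid[["L"]], U = fixed_sigmoid[["U"]], s = 1)

  term_names <- colnames(X)
  type <- c(rep("first_order", p))
  if (order >= 2L) type[grepl(":", term_names, fixed = TRUE)] <- "coupling"

  fold_terms <- NULL
  fold_r2 <- tibble::tibble(fold = integer(), r2 = numeric(), n = integer())
  r2_pooled <- NA_real_
  if (cv && nrow(growth) >= folds) {
    assign <- sample(rep_len(seq_len(folds), nrow(growth)))
    pred_all <- rep(NA_real_, nrow(growth))
    fold_terms <- matrix(NA_real_, nrow = folds, ncol = p,
                         dimnames = list(NULL, term_names))
    for (f in seq_len(folds)) {
      tr <- assign != f
      ft <- run(best$par, Xf = X[tr, , drop = FALSE], yf = gr[tr], wf = w[tr])
      fold_terms[f, ] <- ft$par[seq_len(p)]
      if (learn) {
        sf <- c(L = ft$par[[p + 1L]], U = ft$par[[p + 1L]] + exp(ft$par[[p + 2L]]),
                s = 1)
      } else sf <- sigmoid
      phi_te <- as.vector(X[!tr, , drop = FALSE] %*% ft$par[seq_len(p)])
      pred_all[!tr] <- sigmoid_gr(phi_te, sf)
      obs <- gr[!tr]
      fold_r2 <- dplyr::bind_rows(fold_r2, tibble::tibble(
        fold = f,
        r2 = stats::cor(obs, pred_all[!tr])^2,
        n = sum(!tr)
      ))
    }
    r2_pooled <- stats::cor(gr, pred_all)^2
  }

  terms_tbl <- tibble::tibble(
    term = term_names,
    type = type,
    estimate = best$par[seq_len(p)],
    se = if (is.null(fold_terms)) NA_real_ else
      apply(fold_terms, 2L, stats::sd)
  )

  structure(
    list(
      terms = terms_tbl,
      sigmoid = sigmoid,
      order = as.integer(order),
      lambda = lambda,
      folds = if (cv) as.integer(folds) else 0L,
      seed = as.integer(seed),
      r2_heldout = r2_pooled,
      fold_r2 = fold_r2,
      nobs = nrow(growth),
      units = "trait",
      convergence = best$convergence,
      loss = best$value,
      term_universe = list(first_order = term_names[type == "first_order"],
                           couplings = term_names[type == "coupling"])
    ),
    class = "nuc_model"
  )
}

#' @export
print.nuc_model <- function(x, ...) {
  cat("<nuc_model> order ", x$order, ": ",
      sum(x$terms$type == "first_order"), " first-order terms",
      if (x$order >= 2L) paste0(" + ", sum(x$terms$type == "coupling"),
                                " couplings"),
      "; units ", x$units, "\n", sep = "")
  if (!is.na(x$r2_heldout)) {
    cat("  held-out R^2 = ", signif(x$r2_heldout, 3), " (", x$folds,
        "-fold CV, n = ", x$nobs, ")\n", sep = "")
  }
  invisible(x)
}

#' Predict relative growth rates from a fitted energy model
#'
#' @param model A `nuc_model`.
#' @param variants Character vector of mutation strings or tibble with a
#'   `variant`/`mutations` column.
#' @return Predicted relative growth rates (same scale as the training data).
#' @export
predict_growth <- function(model, variants) {
  stopifnot(inherits(model, "nuc_model"))
  X <- encode_variants(variant_column(variants),
                       terms = model$term_universe, order = model$order)
  phi <- as.vector(X %*% model$terms$estimate)
  sigmoid_gr(phi, model$sigmoid)
}

#' Term-level significance by Z-test with Benjamini-Hochberg FDR
#'
#' Z is the term estimate over its across-fold standard error; p-values are
#' two-sided normal and adjusted across all testable terms by the
#' Benjamini-Hochberg step-up procedure. Terms are classified at FDR < `fdr`
#' as increasing or decreasing the activation energy, otherwise
#' indistinguishable from zero. Terms with zero or missing SE are flagged
#' and excluded from testing.
#'
#' @param model A `nuc_model` fitted with cross-validation.
#' @param fdr False-discovery-rate threshold (default 0.05).
#' @return Tibble: `term`, `type`, `estimate`, `se`, `z`, `p`, `q`, `class`.
#' @export
significance_terms <- function(model, fdr = 0.05) {
  stopifnot(inherits(model, "nuc_model"))
  out <- model$terms
  testable <- !is.na(out$se) & out$se > 0
  out$z <- ifelse(testable, out$estimate / out$se, NA_real_)
  out$p <- 2 * stats::pnorm(-abs(out$z))
  out$q <- NA_real_
  out$q[testable] <- stats::p.adjust(out$p[testable], method = "BH")
  out$class <- dplyr::case_when(
    !testable ~ "untestable",
    out$q < fdr & out$estimate > 0 ~ "increases_ddg_act",
    out$q < fdr & out$estimate < 0 ~ "decreases_ddg_act",
    TRUE ~ "indistinguishable_from_zero"
  )
  out
}

#' Extract the coupling table of an order-2 model
#'
#' @param model A `nuc_model` of order 2.
#' @return Tibble `mut1`, `mut2`, `coupling` (plus `se` when available).
#' @export
coupling_table <- function(model) {
  stopifnot(inherits(model, "nuc_model"), model$order >= 2L)
  cp <- model$terms[model$terms$type == "coupling", , drop = FALSE]
  parts <- stringr::str_split_fixed(cp$term, ":", 2)
  tibble::tibble(mut1 = parts[, 1], mut2 = parts[, 2],
                 coupling = cp$estimate, se = cp$se)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.nuc_model <- function(x, ...) significance_terms(x, ...)

#' @export
glance.nuc_model <- function(x, ...) {
  tibble::tibble(
    order = x$order, nobs = x$nobs, n_terms = nrow(x$terms),
    lambda = x$lambda, folds = x$folds, r2_heldout = x$r2_heldout,
    sigmoid_L = x$sigmoid[["L"]], sigmoid_U = x$sigmoid[["U"]],
    units = x$units, convergence = x$convergence
  )
}
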