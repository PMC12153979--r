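test_that("variant encoding produces the declared indicator structure", {
  terms <- model_terms(abeta_designs()[c("comb1", "comb2")], order = 2L)
  expect_length(terms$first_order, 44)
  expect_length(terms$couplings, 640)

  X <- encode_variants(c("", "I32M", "I32M:V40L"), terms = terms, order = 2L)
  expect_equal(ncol(X), 44 + 640)
  expect_equal(sum(X[1, ]), 0)              # WT is the zero vector
  expect_equal(sum(X[2, ]), 1)
  expect_equal(sum(X[3, ]), 3)              # two singles + one coupling
  expect_equal(unname(X[3, "I32M:V40L"]), 1)
  expect_error(encode_variants("A2C", terms = terms), "outside")
})

test_that("with lambda 0 and a fixed sigmoid the fit matches weighted least squares", {
  des <- tiny_design()
  # small effects keep the trait in the sigmoid's quasi-linear range
  land <- landscape(
    tibble::tibble(mutation = model_terms(des)$first_order,
                   ddg_act = withr::with_seed(8, stats::runif(57, -0.2, 0.2))),
    sigmoid = c(L = -2, U = 0, s = 1)
  )
  vars <- enumerate_variants(des, include_sequence = FALSE)$mutations
  growth <- tibble::tibble(
    variant = vars,
    gr = growth_rate_from_energy(land, vars),
    sigma = rep(c(0.5, 1, 2), length.out = length(vars))
  )
  fit <- fit_energy_model(growth, lambda = 0, cv = FALSE, restarts = 1,
                          fixed_sigmoid = c(L = -1, U = 1), seed = 1)
  # closed-form oracle: weighted normal equations on the inverted sigmoid
  X <- as.matrix(encode_variants(growth$variant,
                                 terms = list(first_order = fit$terms$term,
                                              couplings = character())))
  w <- 1 / growth$sigma^2
  z <- -stats::qlogis((growth$gr - (-1)) / 2)
  theta_wls <- solve(t(X) %*% (w * X), t(X) %*% (w * z))[, 1]
  expect_equal(fit$terms$estimate, unname(theta_wls), tolerance = 1e-3)
  expect_equal(
    fit$terms$estimate[match(land$first_order$mutation, fit$terms$term)],
    land$first_order$ddg_act, tolerance = 1e-3)
})

test_that("noiseless additive data are recovered almost exactly", {
  des <- tiny_design(c(31L, 32L, 34L, 35L))
  land <- sample_landscape(des, coupling_density = 0, seed = 17)
  vars <- enumerate_variants(des, include_sequence = FALSE)$mutations
  growth <- tibble::tibble(variant = vars,
                           gr = growth_rate_from_energy(land, vars),
                           sigma = 0.05)
  fit <- fit_energy_model(growth, cv = FALSE, restarts = 1, seed = 2)
  est <- fit$terms$estimate[match(land$first_order$mutation, fit$terms$term)]
  expect_gt(stats::cor(est, land$first_order$ddg_act), 0.99)
})

test_that("the artificial reference row is appended once with GR 0, sigma 100", {
  growth <- tibble::tibble(variant = c("I31M", "I32M"), gr = c(-0.5, -0.8),
                           sigma = 0.1)
  with_ref <- add_reference_variant(growth)
  expect_equal(nrow(with_ref), 3)
  ref_row <- with_ref[with_ref$variant == "", ]
  expect_equal(ref_row$gr, 0)
  expect_equal(ref_row$sigma, 100)
  expect_equal(1 / ref_row$sigma^2, 1e-4)   # negligible fitting weight
  expect_warning(again <- add_reference_variant(with_ref), "already present")
  expect_equal(nrow(again), 3)
})

test_that("predictions respect the decreasing sigmoid and additivity", {
  des <- tiny_design()
  land <- sample_landscape(des, coupling_density = 0, seed = 4)
  vars <- enumerate_variants(des, include_sequence = FALSE)$mutations
  growth <- tibble::tibble(variant = vars,
                           gr = growth_rate_from_energy(land, vars),
                           sigma = 0.05)
  fit <- fit_energy_model(growth, cv = FALSE, restarts = 1, seed = 3)
  # WT prediction is the sigmoid midpoint g(0)
  expect_equal(predict_growth(fit, ""),
               fit$sigmoid[["L"]] + (fit$sigmoid[["U"]] - fit$sigmoid[["L"]]) / 2)
  # order-1 traits add: prediction of a double from the sum of its singles
  th <- stats::setNames(fit$terms$estimate, fit$terms$term)
  expect_equal(predict_growth(fit, "I31M:I32M"),
               sigmoid_pred <- fit$sigmoid[["L"]] +
                 (fit$sigmoid[["U"]] - fit$sigmoid[["L"]]) *
                 stats::plogis(-(th[["I31M"]] + th[["I32M"]])))
  # raising any single term's trait lowers the predicted growth rate
  grs <- predict_growth(fit, c("I31V", "I31M"))
  expect_equal(order(grs), order(-th[c("I31V", "I31M")]))
})

test_that("term significance matches normal-theory and brute-force BH oracles", {
  model <- structure(list(terms = tibble::tibble(
    term = c("a", "b", "c", "d", "e"),
    type = "first_order",
    estimate = c(0, 1.96, -3, 0.5, 2),
    se = c(1, 1, 1, 1, 0)
  )), class = "nuc_model")
  sig <- significance_terms(model)
  expect_equal(sig$p[1], 1)
  expect_equal(sig$p[2], 0.05, tolerance = 1e-3)
  expect_equal(sig$class[5], "untestable")
  expect_equal(sig$class[3], "decreases_ddg_act")
  testable <- !is.na(sig$z)
  expect_equal(sig$q[testable], brute_bh(sig$p[testable]))

  # randomized p-vectors against the brute-force step-up
  for (seed in 1:3) {
    p <- withr::with_seed(seed, stats::runif(20)^2)
    expect_equal(stats::p.adjust(p, "BH"), brute_bh(p))
  }
  expect_equal(brute_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
})

test_that("fits are seed-reproducible and insensitive to row order", {
  des <- tiny_design()
  land <- sample_landscape(des, coupling_density = 0, seed = 6)
  vars <- enumerate_variants(des, include_sequence = FALSE)$mutations
  growth <- tibble::tibble(variant = vars,
                           gr = growth_rate_from_energy(land, vars),
                           sigma = 0.05)
  f1 <- fit_energy_model(growth, cv = FALSE, restarts = 1, seed = 11)
  f2 <- fit_energy_model(growth, cv = FALSE, restarts = 1, seed = 11)
  expect_equal(f1$terms, f2$terms)
  shuffled <- growth[withr::with_seed(1, sample(nrow(growth))), ]
  f3 <- fit_energy_model(shuffled, cv = FALSE, restarts = 1, seed = 11)
  expect_equal(f1$terms$estimate,
               f3$terms$estimate[match(f1$terms$term, f3$terms$term)],
               tolerance = 1e-3)
})

test_that("cross-validation reports held-out accuracy and per-term SEs", {
  des <- tiny_design(c(31L, 32L, 34L, 35L))
  land <- sample_landscape(des, coupling_density = 0, seed = 30)
  vars <- enumerate_variants(des, include_sequence = FALSE)$mutations
  counts <- simulate_selection(land, vars, depth = 5e5, replicates = 3,
                               n_wt_synonyms = 5, seed = 31)
  growth <- process_counts(counts, min_input_reads = 1)
  fit <- fit_energy_model(growth, folds = 5, restarts = 1, seed = 32)
  expect_equal(nrow(fit$fold_r2), 5)
  expect_true(all(fit$fold_r2$r2 > 0.8))
  expect_gt(fit$r2_heldout, 0.9)
  expect_true(all(is.finite(fit$terms$se) & fit$terms$se >= 0))
  gl <- glance(fit)
  expect_equal(gl$folds, 5L)
  expect_equal(gl$nobs, nrow(growth))
})
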