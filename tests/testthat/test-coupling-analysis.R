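test_that("interaction scores are mean absolute couplings per position pair", {
  cps <- tibble::tibble(
    mut1 = c("I31M", "I31V", "I31M", "I31V"),
    mut2 = c("I32M", "I32M", "I32V", "I32V"),
    coupling = c(1, -1, 2, -2)
  )
  sc <- interaction_scores(cps)
  expect_equal(nrow(sc), 1)
  expect_equal(sc$score, 1.5)
  expect_equal(sc$n_couplings, 4L)
  # sign flips leave the score unchanged; zeros give zero
  flipped <- dplyr::mutate(cps, coupling = -coupling)
  expect_equal(interaction_scores(flipped)$score, 1.5)
  zero <- dplyr::mutate(cps, coupling = 0)
  expect_equal(interaction_scores(zero)$score, 0)
  expect_error(interaction_scores(cps[0, ]), "no couplings")
})

test_that("equal-magnitude planted couplings give exactly that score", {
  cps <- tibble::tibble(
    mut1 = rep("L34F", 4), mut2 = rep("M35V", 4),
    coupling = c(0.8, -0.8, 0.8, -0.8)
  )
  expect_equal(interaction_scores(cps)$score, 0.8)
})

test_that("top pairs at the 90th percentile of 40 scores are the top 4", {
  withr::with_seed(2, {
    scores <- tibble::tibble(
      pos_i = rep(1:8, each = 5), pos_j = rep(11:15, times = 8),
      score = sample(seq(0.01, 0.4, length.out = 40)),
      n_couplings = 16L
    )
  })
  top <- top_pairs(scores, percentile = 90)
  expect_equal(nrow(top), 4)
  expect_equal(top$score, sort(scores$score, decreasing = TRUE)[1:4])
  expect_equal(nrow(top_pairs(scores, percentile = 0)), 40)
  # ties at the threshold are all kept
  tied <- tibble::tibble(pos_i = 1:5, pos_j = 6:10,
                         score = c(1, 1, 1, 0.5, 0.2))
  expect_equal(nrow(top_pairs(tied, percentile = 80)), 3)
})

test_that("rank correlation against distance matches a rank-based oracle", {
  for (seed in 1:3) {
    withr::with_seed(seed, {
      n <- 15
      scores <- tibble::tibble(
        pos_i = 1:n, pos_j = 21:(20 + n),
        score = stats::runif(n, 0, 2)
      )
      dists <- tibble::tibble(pos_i = 1:n, pos_j = 21:(20 + n),
                              scha_min = stats::runif(n, 3, 25))
    })
    res <- correlate_with_distance(scores, dists)
    # oracle: Pearson correlation of the ranks
    oracle <- stats::cor(rank(scores$score), rank(1 / dists$scha_min))
    expect_equal(res$rho, oracle, tolerance = 1e-12)
    expect_equal(res$n_pairs, n)
  }
})

test_that("distance correlation is signed, guarded, and drops unmatched pairs", {
  scores <- tibble::tibble(pos_i = 1:6, pos_j = 11:16,
                           score = c(3, 2.5, 2, 1.5, 1, 0.5))
  dists <- tibble::tibble(pos_i = 1:6, pos_j = 11:16,
                          scha_min = c(4, 5, 6, 7, 8, 9))
  perfect <- correlate_with_distance(scores, dists)
  expect_equal(perfect$rho, 1)
  reversed <- correlate_with_distance(
    dplyr::mutate(scores, score = rev(score)), dists)
  expect_equal(reversed$rho, -1)
  # constant scores: undefined, flagged rather than errored
  const <- correlate_with_distance(dplyr::mutate(scores, score = 1), dists)
  expect_true(is.na(const$rho))
  # pairs without distances are dropped and counted
  dropped <- correlate_with_distance(scores, dists[1:4, ])
  expect_equal(dropped$n_pairs, 4)
  expect_equal(dropped$n_dropped, 2)
  expect_error(correlate_with_distance(scores[1:2, ], dists), "at least 3")
})

test_that("per-position means of first-order terms match a group-by oracle", {
  terms <- tibble::tibble(
    term = c("I31M", "I31V", "I31F", "I32M", "L34F"),
    estimate = c(1, 2, 3, 5, -1)
  )
  summ <- position_summary(terms)
  expect_equal(summ$mean_ddg_act[summ$position == 31], 2)
  expect_equal(summ$mean_ddg_act[summ$position == 32], 5)
  expect_equal(summ$n_substitutions, c(3L, 1L, 1L))
  oracle <- tapply(terms$estimate, parse_mutations(terms$term)$position, mean)
  expect_equal(summ$mean_ddg_act, as.numeric(oracle))
})

test_that("couplings planted on structural contacts are detected at n = 40", {
  # the 11 combinatorial positions; four disjoint co-mutable pairs are placed
  # in contact (5 A), everything else far apart (> 15 A)
  positions <- c(19, 20, 24, 31, 32, 34, 35, 36, 39, 40, 41)
  contact_pairs <- list(c(31, 32), c(34, 35), c(36, 39), c(40, 41))
  islands <- list(c(0, 0), c(40, 0), c(0, 40), c(40, 40))
  coords <- list(`19` = c(80, 80), `20` = c(120, 0), `24` = c(0, 120))
  for (k in seq_along(contact_pairs)) {
    p <- contact_pairs[[k]]
    coords[[as.character(p[1])]] <- islands[[k]]
    coords[[as.character(p[2])]] <- islands[[k]] + c(5, 0)
  }
  spec <- purrr::map_dfr(positions, function(p) {
    xy <- coords[[as.character(p)]]
    tibble::tibble(chain = "A", resno = as.integer(p), resname = "LEU",
                   x = xy[1], y = xy[2], z = 0,
                   scx = xy[1], scy = xy[2] + 1.5, scz = 0)
  })
  st <- parse_structure(generate_fixture_structure(spec))
  dm <- distance_matrix(st, "monomer")

  terms <- model_terms(abeta_designs()[c("comb1", "comb2")], order = 2L)
  parts <- stringr::str_split_fixed(terms$couplings, ":", 2)
  cp <- tibble::tibble(mut1 = parts[, 1], mut2 = parts[, 2], coupling = 0)
  pos1 <- as.integer(stringr::str_extract(cp$mut1, "\\d+"))
  pos2 <- as.integer(stringr::str_extract(cp$mut2, "\\d+"))
  planted <- purrr::map_lgl(seq_len(nrow(cp)), function(i) {
    any(purrr::map_lgl(contact_pairs, function(p) {
      setequal(p, c(pos1[i], pos2[i]))
    }))
  })
  cp$coupling[planted] <- 1.5

  scores <- interaction_scores(cp)
  expect_equal(nrow(scores), 40)
  res <- correlate_with_distance(scores, dm)
  expect_gt(res$rho, 0)
  expect_lt(res$p_value, 0.05)
  top <- top_pairs(scores, percentile = 90)
  expect_equal(nrow(top), 4)
  expect_setequal(paste(top$pos_i, top$pos_j),
                  purrr::map_chr(contact_pairs, ~ paste(.x[1], .x[2])))
})
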