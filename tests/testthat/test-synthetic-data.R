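test_that("sampled landscapes are reproducible and honor coupling density", {
  des <- abeta_designs()[c("comb1", "comb2")]
  l1 <- sample_landscape(des, coupling_density = 0.1, seed = 42)
  l2 <- sample_landscape(des, coupling_density = 0.1, seed = 42)
  expect_equal(l1$first_order, l2$first_order)
  expect_equal(l1$couplings, l2$couplings)

  l0 <- sample_landscape(des, coupling_density = 0, seed = 42)
  expect_equal(nrow(l0$couplings), 0L)

  # 640 possible couplings at density 0.1: binomial expectation 64, sd 7.6
  n_on <- nrow(l1$couplings)
  expect_gt(n_on, 64 - 4 * 7.6)
  expect_lt(n_on, 64 + 4 * 7.6)
})

test_that("first-order effects have the expected sign composition", {
  land <- sample_landscape(abeta_designs()$shallow, seed = 9)
  frac_up <- mean(land$first_order$ddg_act > 0.2)
  frac_down <- mean(land$first_order$ddg_act < -0.2)
  expect_gt(frac_up, 0.5)   # most mutations slow nucleation
  expect_lt(frac_down, 0.3) # a minority accelerate it
})

test_that("growth rates follow the centered decreasing sigmoid", {
  land <- tiny_landscape()
  expect_equal(growth_rate_from_energy(land, ""), 0)
  # monotone decreasing in the energy trait
  gr <- growth_rate_from_energy(land, c("I31V", "L34F", "I31M", "I32M"))
  expect_true(all(diff(gr) < 0))
  # saturation at the sigmoid's lower bound for huge traits
  big <- landscape(tibble::tibble(mutation = "I31M", ddg_act = 50),
                   sigmoid = c(L = -2, U = 0, s = 1))
  g0 <- -2 + (0 - -2) / 2  # wild-type growth rate before centering
  expect_equal(growth_rate_from_energy(big, "I31M"), -2 - g0,
               tolerance = 1e-9)
  expect_error(growth_rate_from_energy(land, "A2C"), "not in landscape")
})

test_that("double-mutant traits are additive except for planted couplings", {
  land <- tiny_landscape()
  g <- function(v) growth_rate_from_energy(land, v)
  # invert the centered sigmoid to read back the energy trait
  phi <- function(v) {
    s <- land$sigmoid
    g0 <- s[["L"]] + (s[["U"]] - s[["L"]]) / 2
    -stats::qlogis((g(v) + g0 - s[["L"]]) / (s[["U"]] - s[["L"]]))
  }
  expect_equal(phi("I31V:L34F"), phi("I31V") + phi("L34F"), tolerance = 1e-9)
  # planted coupling shifts the double away from additivity by its value
  expect_equal(phi("I31M:I32M"), phi("I31M") + phi("I32M") + 1.5,
               tolerance = 1e-9)
})

test_that("selection simulation is seed-deterministic and conserves depth", {
  land <- tiny_landscape()
  vars <- c("", "I31M", "I31V", "I32M", "L34F", "I31M:I32M")
  c1 <- simulate_selection(land, vars, depth = 5000, replicates = 3,
                           n_wt_synonyms = 2, seed = 7)
  c2 <- simulate_selection(land, vars, depth = 5000, replicates = 3,
                           n_wt_synonyms = 2, seed = 7)
  expect_equal(as.data.frame(c1), as.data.frame(c2))
  for (r in 1:3) {
    expect_equal(sum(c1[[paste0("input_rep", r)]]), 5000)
    expect_equal(sum(c1[[paste0("output_rep", r)]]), 5000)
  }
  expect_error(simulate_selection(land, vars, depth = 0), "depth")
})

test_that("a flat landscape leaves output frequencies at input frequencies", {
  flat <- landscape(tibble::tibble(mutation = c("I31M", "I32M"),
                                   ddg_act = c(0, 0)))
  counts <- simulate_selection(flat, c("", "I31M", "I32M", "I31M:I32M"),
                               depth = 2e5, seed = 3)
  f_in <- counts$input_rep1 / sum(counts$input_rep1)
  f_out <- counts$output_rep1 / sum(counts$output_rep1)
  expect_equal(f_out, f_in, tolerance = 0.05)
})

test_that("empirical log-ratio growth rates converge to the truth at depth", {
  des <- tiny_design(c(31L, 32L, 34L, 35L))
  land <- sample_landscape(des, coupling_density = 0, seed = 5)
  vars <- enumerate_variants(des, include_sequence = FALSE)$mutations
  counts <- simulate_selection(land, vars, depth = 2e6, replicates = 2,
                               seed = 8)
  est <- process_counts(counts, min_input_reads = 1)
  truth <- growth_rate_from_energy(land, est$variant)
  expect_gt(stats::cor(truth, est$gr), 0.99)
})

test_that("surrogate stability tables reproduce construction guarantees", {
  land <- tiny_landscape()
  structs <- tibble::tibble(structure = c("S1", "S2"), n_chains = c(4, 3))
  tab <- generate_stability_table(land, structs, region = 1:42,
                                  correlation = 1, seed = 2)
  # correlation 1 with a global region: per-monomer stability equals ddg_act
  s1 <- tab[tab$structure == "S1", ]
  expect_equal(per_monomer_ddg(s1$assembly_ddg, s1$n_chains),
               land$first_order$ddg_act[match(s1$mutation,
                                              land$first_order$mutation)])
  expect_equal(tab, generate_stability_table(land, structs, region = 1:42,
                                             correlation = 1, seed = 2))
  # correlation 0: values decoupled from the activation terms
  t0a <- generate_stability_table(land, structs[1, ], region = 1:42,
                                  correlation = 0, seed = 3)
  expect_false(isTRUE(all.equal(
    per_monomer_ddg(t0a$assembly_ddg, t0a$n_chains),
    land$first_order$ddg_act
  )))
})

test_that("fixture structures encode stated geometry and reject bad specs", {
  st <- two_residue_structure(d = 5)
  expect_equal(schamin_distance(st, 1, 2), 5)
  # glycine is emitted with no side-chain atoms; its designated atom is CA
  spec <- tibble::tibble(chain = "A", resno = 1L, resname = "GLY",
                         x = 1, y = 2, z = 3)
  gly <- parse_structure(generate_fixture_structure(spec))
  sc <- gly$atoms[gly$atoms$side_chain, ]
  expect_equal(sc$atom, "CA")
  expect_equal(c(sc$x, sc$y, sc$z), c(1, 2, 3))
  expect_error(generate_fixture_structure(tibble::tibble(chain = "A")),
               "columns")
  expect_error(
    generate_fixture_structure(tibble::tibble(
      chain = "A", resno = 1L, resname = "ALA", x = NaN, y = 0, z = 0)),
    "non-finite")
})
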