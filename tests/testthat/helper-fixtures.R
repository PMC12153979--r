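# Shared fixtures built in code: tiny designs, landscapes and structures.

tiny_design <- function(positions = c(31L, 32L, 34L), max_order = 2L,
                        alphabet = NULL) {
  library_design("tiny", positions, alphabet = alphabet,
                 max_order = max_order)
}

# landscape with known, hand-set terms over the tiny design
tiny_landscape <- function(sigmoid = c(L = -2, U = 0, s = 1)) {
  landscape(
    first_order = tibble::tibble(
      mutation = c("I31M", "I31V", "I32M", "L34F"),
      ddg_act = c(1.0, -0.5, 2.0, 0.25)
    ),
    couplings = tibble::tibble(
      mut1 = "I31M", mut2 = "I32M", coupling = 1.5
    ),
    sigmoid = sigmoid
  )
}

# a count table with explicit numbers for hand-computed expectations
hand_counts <- function() {
  tibble::tibble(
    id = c("", "I31M"),
    variant = c("", "I31M"),
    is_wt_synonym = FALSE,
    input_rep1 = c(100, 100),
    output_rep1 = c(100, 400)
  )
}

# two-residue structure with single side-chain atoms a known distance apart
two_residue_structure <- function(d = 5) {
  spec <- tibble::tibble(
    chain = "A", resno = c(1L, 2L), resname = c("ALA", "LEU"),
    x = c(0, 10), y = 0, z = 0,
    scx = c(0, d), scy = 0, scz = 0
  )
  parse_structure(generate_fixture_structure(spec))
}

# random multi-atom structure spec for oracle comparisons
random_atom_spec <- function(n_res = 4, atoms_per_res = 3, seed = 1) {
  withr::with_seed(seed, {
    purrr::map_dfr(seq_len(n_res), function(r) {
      k <- sample(seq_len(atoms_per_res), 1) + 1L
      tibble::tibble(
        chain = "A", resno = r, resname = "LEU",
        atom = c("N", "CA", "C", "O", paste0("C", LETTERS[seq_len(k)], "B"))[
          seq_len(4 + k)],
        x = stats::runif(4 + k, 0, 20),
        y = stats::runif(4 + k, 0, 20),
        z = stats::runif(4 + k, 0, 20)
      )
    })
  })
}

# brute-force scHA_min oracle: double loop over side-chain atom pairs
brute_schamin <- function(atoms, i, j) {
  side <- function(r) {
    a <- atoms[atoms$resno == r, , drop = FALSE]
    sc <- a[!(a$atom %in% c("N", "CA", "C", "O", "OXT")) |
              (a$resname == "GLY" & a$atom == "CA"), , drop = FALSE]
    as.matrix(sc[, c("x", "y", "z")])
  }
  ai <- side(i); aj <- side(j)
  best <- Inf
  for (p in seq_len(nrow(ai))) {
    for (q in seq_len(nrow(aj))) {
      best <- min(best, sqrt(sum((ai[p, ] - aj[q, ])^2)))
    }
  }
  best
}

# brute-force Benjamini-Hochberg step-up
brute_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[ord[i]] <- min(vapply((i:m), function(j) p[ord[j]] * m / j,
                              numeric(1)), 1)
  }
  adj
}
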