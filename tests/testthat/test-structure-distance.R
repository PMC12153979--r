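test_that("fixture structures round-trip coordinates exactly", {
  spec <- random_atom_spec(n_res = 3, seed = 2)
  st <- parse_structure(generate_fixture_structure(spec))
  expect_equal(nrow(st$atoms), nrow(spec))
  # PDB fixed-width fields carry 3 decimals
  expect_equal(st$atoms$x, round(spec$x, 3))
  expect_equal(st$atoms$y, round(spec$y, 3))
  expect_equal(st$atoms$z, round(spec$z, 3))
})

test_that("side-chain classification follows the backbone/glycine rule", {
  spec <- tibble::tibble(
    chain = "A", resno = c(1L, 1L, 1L, 1L, 1L, 2L, 2L),
    resname = c(rep("LEU", 5), rep("GLY", 2)),
    atom = c("N", "CA", "C", "O", "CB", "N", "CA"),
    x = 1:7, y = 0, z = 0
  )
  st <- parse_structure(generate_fixture_structure(spec))
  expect_equal(st$atoms$atom[st$atoms$side_chain & st$atoms$resno == 1], "CB")
  expect_equal(st$atoms$atom[st$atoms$side_chain & st$atoms$resno == 2], "CA")
  # a residue with neither a side chain nor glycine's dispensation is flagged
  bare <- spec[spec$atom %in% c("N", "CA", "C", "O") & spec$resno == 1, ]
  flagged <- parse_structure(generate_fixture_structure(bare))
  expect_equal(flagged$missing_side_chains$resno, 1L)
})

test_that("requesting an absent chain lists the available ones", {
  st_txt <- generate_fixture_structure(tibble::tibble(
    chain = c("A", "B"), resno = 1L, resname = "ALA",
    x = c(0, 5), y = 0, z = 0
  ))
  expect_error(parse_structure(st_txt, chains = "Z"), "A, B")
})

test_that("scHA_min equals hand geometry and a brute-force oracle", {
  # single atoms at the origin and (3, 4, 0): the 3-4-5 triangle
  spec <- tibble::tibble(chain = "A", resno = c(1L, 2L),
                         resname = "ALA", x = c(0, 10), y = 0, z = 0,
                         scx = c(0, 3), scy = c(0, 4), scz = 0)
  st <- parse_structure(generate_fixture_structure(spec))
  expect_equal(schamin_distance(st, 1, 2), 5)
  # multi-atom residues against the exhaustive atom-pair loop
  for (seed in 1:4) {
    spec <- random_atom_spec(n_res = 4, atoms_per_res = 4, seed = seed)
    st <- parse_structure(generate_fixture_structure(spec))
    for (pair in list(c(1, 2), c(1, 4), c(2, 3))) {
      expect_equal(schamin_distance(st, pair[1], pair[2]),
                   brute_schamin(spec, pair[1], pair[2]),
                   tolerance = 1e-3)
    }
  }
})

test_that("distance matrices are symmetric with zero diagonal", {
  st <- parse_structure(generate_fixture_structure(random_atom_spec(5, seed = 9)))
  dm <- distance_matrix(st, "monomer")
  expect_equal(dm$matrix, t(dm$matrix))
  expect_equal(unname(diag(dm$matrix)), rep(0, 5))
  expect_true(all(dm$matrix >= 0))
  long <- tidy(dm)
  expect_equal(nrow(long), choose(5, 2))
})

test_that("distances are invariant under rigid-body transforms", {
  spec <- random_atom_spec(n_res = 5, seed = 3)
  base <- distance_matrix(
    parse_structure(generate_fixture_structure(spec)), "monomer")
  withr::with_seed(14, {
    rot <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
    shift <- stats::rnorm(3, 0, 20)
  })
  xyz <- as.matrix(spec[, c("x", "y", "z")]) %*% t(rot)
  moved <- spec
  moved$x <- xyz[, 1] + shift[1]
  moved$y <- xyz[, 2] + shift[2]
  moved$z <- xyz[, 3] + shift[3]
  rotated <- distance_matrix(
    parse_structure(generate_fixture_structure(moved)), "monomer")
  expect_equal(rotated$matrix, base$matrix, tolerance = 1e-2)
})

test_that("scHA_min never exceeds the single-atom CB-CB distance", {
  spec <- random_atom_spec(n_res = 4, atoms_per_res = 3, seed = 6)
  st <- parse_structure(generate_fixture_structure(spec))
  cb <- spec[spec$atom == "CAB", ]  # first side-chain atom of each residue
  for (i in 1:3) {
    d_cb <- sqrt(sum((cb[i, c("x", "y", "z")] - cb[i + 1, c("x", "y", "z")])^2))
    expect_lte(schamin_distance(st, i, i + 1), d_cb + 1e-3)
  }
})

test_that("dimer mode minimizes over both cross-chain assignments", {
  one <- tibble::tibble(chain = "A", resno = 1:3, resname = "ALA",
                        x = c(0, 6, 12), y = 0, z = 0)
  # exactly superposed chains: the extra cross-chain minimization can only
  # tie or undercut the within-chain distances
  sup <- dplyr::mutate(one, chain = "B")
  st_sup <- parse_structure(generate_fixture_structure(dplyr::bind_rows(one, sup)))
  dm_mono <- distance_matrix(st_sup, "monomer", chains = "A")
  dm_dimer <- distance_matrix(st_sup, "dimer", chains = c("A", "B"))
  expect_true(all(dm_dimer$matrix <= dm_mono$matrix + 1e-9))
  expect_equal(unname(diag(dm_dimer$matrix)), rep(0, 3))
  # facing filaments 3 A apart: both assignments are minimized over
  shifted <- dplyr::mutate(one, chain = "B", z = 3)
  st <- parse_structure(generate_fixture_structure(dplyr::bind_rows(one, shifted)))
  dd <- distance_matrix(st, "dimer", chains = c("A", "B"))
  expect_equal(dd$matrix, t(dd$matrix))
  expect_equal(unname(diag(dd$matrix)), rep(3, 3))
  expect_equal(unname(dd$matrix[1, 2]), sqrt(6^2 + 3^2))
  expect_error(distance_matrix(st, "dimer", chains = "A"), "2 chain")
  expect_error(distance_matrix(st, "monomer", chains = c("A", "B")),
               "1 chain")
})

test_that("contact calls are strict at the threshold and match a sweep", {
  m <- matrix(c(0, 7.9, 8.1, 7.9, 0, 8, 8.1, 8, 0), 3, 3,
              dimnames = list(1:3, 1:3))
  cm <- contact_map(m, threshold = 8)
  expect_true(cm[1, 2])    # 7.9 is a contact
  expect_false(cm[1, 3])   # 8.1 is not
  expect_false(cm[2, 3])   # exactly 8 is not (strict)
  st <- parse_structure(generate_fixture_structure(random_atom_spec(6, seed = 8)))
  dm <- distance_matrix(st, "monomer")
  for (thr in c(5, 8, 12)) {
    expect_equal(sum(contact_map(dm, thr)) / 2,
                 sum(dm$matrix[upper.tri(dm$matrix)] < thr))
  }
})
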