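# End-to-end orchestration: synthetic fixture bundles and a configurable
# multi-stage pipeline (counts -> growth rates -> energy model -> kcal/mol
# calibration -> stability ratios / couplings -> structure comparison) with
# a run manifest.

demo_designs <- function() {
  dts <- expand_degenerate_codon("DTS")$amino_acids
  list(
    double_demo = library_design("double_demo", c(31L, 32L, 34L, 35L, 36L),
                                 max_order = 2L),
    comb_demo = library_design("comb_demo", c(19L, 20L, 31L, 32L),
                               alphabet = dts, max_order = 4L)
  )
}

#' Generate a synthetic fixture bundle
#'
#' Writes everything the pipeline consumes to `dir`: a library-design YAML,
#' the ground-truth landscape (first-order terms and couplings), simulated
#' selection count tables per design, an in vitro nucleation-rate table, a
#' surrogate fibril-stability table over synthetic polymorphs, and fixture
#' structure files in PDB format. All randomness derives from `seed`.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @param scale `"demo"` (two reduced designs, <= 5,000 variants per library)
#'   or `"paper-shaped"` (the five full designs at reduced sequencing depth).
#' @param reads_per_variant Sequencing depth per pool, reads per variant.
#' @return Invisibly, a list of the written paths plus the ground-truth
#'   landscape.
#' @export
make_fixtures <- function(dir, seed = 1, scale = c("demo", "paper-shaped"),
                          reads_per_variant = 100) {
  scale <- match.arg(scale)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  designs <- if (scale == "demo") demo_designs() else abeta_designs()
  land <- sample_landscape(designs, coupling_density = 0.1, seed = seed)
  paths <- list()
  paths$designs <- write_design_yaml(designs, file.path(dir, "designs.yaml"))

  paths$landscape_first_order <- write_tsv_header(
    land$first_order, file.path(dir, "landscape_first_order.tsv"), seed = seed)
  paths$landscape_couplings <- write_tsv_header(
    land$couplings, file.path(dir, "landscape_couplings.tsv"), seed = seed)

  for (i in seq_along(designs)) {
    d <- designs[[i]]
    variants <- enumerate_variants(d, include_sequence = FALSE,
                                   cap = 5e5)$mutations
    counts <- simulate_selection(
      land, variants,
      depth = reads_per_variant * (length(variants) + 10L),
      replicates = 3, n_wt_synonyms = if (is_combinatorial(d)) 0L else 10L,
      seed = seed + i
    )
    p <- file.path(dir, paste0("counts_", d$name, ".tsv"))
    write_tsv_header(as.data.frame(counts), p, seed = seed + i,
                     extra = c(design = d$name))
    paths[[paste0("counts_", d$name)]] <- p
  }

  # kinetic rate table: variants with known trait, rates back-computed from
  # transition-state theory around an arbitrary wild-type rate constant
  fo <- land$first_order
  picks <- fo$mutation[order(-abs(fo$ddg_act))][seq_len(min(8L, nrow(fo)))]
  ddg <- fo$ddg_act[match(picks, fo$mutation)]
  k_wt <- 1e4
  rates <- tibble::tibble(
    variant = c("", picks),
    k_n = k_wt * exp(-c(0, ddg) / (GAS_CONSTANT_KCAL * land$temperature)),
    k2 = k_wt * exp(-c(0, ddg) / (GAS_CONSTANT_KCAL * land$temperature))
  )
  paths$rates <- write_tsv_header(rates, file.path(dir, "rates.tsv"),
                                  seed = seed)

  structures <- tibble::tibble(
    structure = c("SYN1", "SYN2", "SYN3"),
    n_chains = c(4, 4, 3),
    correlation = c(1, 0.5, 0)
  )
  stab <- generate_stability_table(land, structures, region = 29:42,
                                   seed = seed)
  paths$stability <- write_tsv_header(stab, file.path(dir, "stability.tsv"),
                                      seed = seed)

  paths$structure <- file.path(dir, "fixture_hairpin.pdb")
  generate_fixture_structure(hairpin_spec(), paths$structure)

  invisible(c(paths, list(landscape = land, designs = designs)))
}

# a 42-residue two-strand hairpin: residues i and 85 - i face each other
# across the strands ~5 A apart; used as a synthetic contact-rich fold
hairpin_spec <- function(gap = 5, spacing = 3.8) {
  aa3 <- c(A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE", G = "GLY",
           H = "HIS", I = "ILE", K = "LYS", L = "LEU", M = "MET", N = "ASN",
           P = "PRO", Q = "GLN", R = "ARG", S = "SER", T = "THR", V = "VAL",
           W = "TRP", Y = "TYR")
  wt <- strsplit(ab42_sequence(), "")[[1]]
  n <- length(wt)
  half <- n %/% 2
  purrr::map_dfr(seq_len(n), function(i) {
    if (i <= half) {
      x <- i * spacing; y <- 0; sy <- y + 1.5
    } else {
      x <- (n + 1 - i) * spacing; y <- gap + 3; sy <- y - 1.5
    }
    tibble::tibble(chain = "A", resno = i, resname = aa3[[wt[[i]]]],
                   x = x, y = y, z = 0, scx = x, scy = sy, scz = 0)
  })
}

`%or%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline from a configuration
#'
#' Executes the stages in dependency order: enrichment (counts to growth
#' rates), energy-model fitting per dataset, kinetic calibration to
#' kcal/mol, stability-ratio analysis, coupling aggregation and structural
#' comparison. Writes per-stage TSV artifacts and a run manifest to
#' `config$outdir` and returns the in-memory results.
#'
#' @param config A list (or path to a YAML file) with fields:
#'   `outdir`; `seed`; `datasets` (list of `name`, `counts` path,
#'   optional `reference` mutation string, `order`); optional `min_input_reads`,
#'   `lambda`, `folds`; optional `calibration` (list with `rates` path);
#'   optional `stability` path and `region`; optional `structures` (list of
#'   `path`, optional `chains`, `offset`, `mode`); optional
#'   `contact_threshold`.
#' @return List: `growth`, `models`, `calibration`, `ratios`, `polymorph_rank`,
#'   `interaction_scores`, `top_pairs`, `distance_correlations`, `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  for (field in c("outdir", "datasets")) {
    if (is.null(config[[field]])) {
      stop("pipeline config is missing required field `", field, "`")
    }
  }
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %or% 1L
  lambda <- config$lambda %or% 1e-5
  folds <- config$folds %or% 10L
  min_reads <- config$min_input_reads %or% 10

  used_files <- character(0)
  results <- list(growth = list(), models = list())

  for (ds in config$datasets) {
    stopifnot(!is.null(ds$name), !is.null(ds$counts))
    if (!file.exists(ds$counts)) {
      stop("stage enrich (", ds$name, "): counts file not found: ", ds$counts)
    }
    used_files <- c(used_files, ds$counts)
    counts <- read_tsv_header(ds$counts)
    growth <- process_counts(counts, reference = ds$reference %or% NULL,
                             min_input_reads = min_reads)
    write_tsv_header(growth, file.path(outdir, paste0("growth_", ds$name, ".tsv")),
                     seed = seed)
    results$growth[[ds$name]] <- growth

    fit_tbl <- growth
    if (!any(fit_tbl$variant == "")) {
      fit_tbl <- add_reference_variant(fit_tbl, "")
    }
    model <- fit_energy_model(fit_tbl, order = ds$order %or% 1L,
                              lambda = lambda, folds = folds, seed = seed)
    results$models[[ds$name]] <- model
    write_tsv_header(significance_terms(model),
                     file.path(outdir, paste0("terms_", ds$name, ".tsv")),
                     seed = seed)
  }

  orders <- purrr::map_int(results$models, "order")
  first_additive <- names(results$models)[orders == 1L][1]

  if (!is.null(config$calibration) && !is.na(first_additive)) {
    rp <- config$calibration$rates
    if (!file.exists(rp)) stop("stage calibrate: rates file not found: ", rp)
    used_files <- c(used_files, rp)
    rates <- read_tsv_header(rp)
    wt_row <- which(rates$variant == "")
    if (length(wt_row) == 0L) stop("stage calibrate: rates table lacks a wild-type row")
    rate_col <- if (isTRUE(config$calibration$rate_type == "primary")) "k_n" else "k2"
    model <- results$models[[first_additive]]
    known <- rates$variant %in% c("", model$term_universe$first_order)
    rates <- rates[known, , drop = FALSE]
    trait <- purrr::map_dbl(rates$variant, function(v) {
      if (v == "") 0 else
        model$terms$estimate[match(v, model$terms$term)]
    })
    cal_data <- tibble::tibble(
      trait = trait[rates$variant != ""],
      ddg_exp = ddg_from_rates(rates[[rate_col]][wt_row],
                               rates[[rate_col]][rates$variant != ""])
    )
    calibration <- fit_calibration(cal_data,
                                   rate_type = config$calibration$rate_type %or% "secondary")
    results$calibration <- calibration
    results$models <- purrr::map(results$models, apply_calibration, calibration)
  }

  if (!is.null(config$stability) && !is.na(first_additive)) {
    if (!file.exists(config$stability)) {
      stop("stage ratios: stability file not found: ", config$stability)
    }
    used_files <- c(used_files, config$stability)
    stab <- read_tsv_header(config$stability)
    terms <- results$models[[first_additive]]$terms
    terms <- terms[terms$type == "first_order", c("term", "estimate")]
    ratios <- compute_ratios(terms, stab)
    results$ratios <- ratios
    write_tsv_header(ratios, file.path(outdir, "ratios.tsv"), seed = seed)
    region <- if (!is.null(config$region)) {
      seq(config$region[[1]], config$region[[2]])
    } else NULL
    results$polymorph_rank <- rank_polymorphs(ratios, region = region)
    write_tsv_header(results$polymorph_rank,
                     file.path(outdir, "polymorph_rank.tsv"), seed = seed)
  }

  order2 <- names(results$models)[orders == 2L]
  if (length(order2) > 0L) {
    cps <- dplyr::bind_rows(purrr::map(results$models[order2], coupling_table))
    scores <- interaction_scores(cps)
    results$interaction_scores <- scores
    results$top_pairs <- top_pairs(scores, percentile = 90)
    write_tsv_header(scores, file.path(outdir, "interaction_scores.tsv"),
                     seed = seed)
  }

  if (!is.null(config$structures)) {
    cors <- list()
    for (st in config$structures) {
      if (!file.exists(st$path)) {
        stop("stage distances: structure file not found: ", st$path)
      }
      used_files <- c(used_files, st$path)
      struct <- parse_structure(st$path, chains = st$chains %or% NULL,
                                offset = st$offset %or% 0)
      dm <- distance_matrix(struct, mode = st$mode %or% "monomer")
      write_tsv_header(tidy(dm),
                       file.path(outdir, paste0("distances_", struct$id, ".tsv")),
                       seed = seed)
      if (!is.null(results$interaction_scores)) {
        cors[[struct$id]] <- correlate_with_distance(results$interaction_scores, dm)
      }
    }
    if (length(cors) > 0L) {
      results$distance_correlations <- dplyr::bind_rows(cors)
      write_tsv_header(results$distance_correlations,
                       file.path(outdir, "distance_correlations.tsv"),
                       seed = seed)
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("dmsenergy")),
    r_version = as.character(getRversion()),
    seed = seed,
    lambda = lambda,
    folds = folds,
    inputs = lapply(stats::setNames(nm = unique(used_files)), function(f) {
      rlang::hash(readLines(f, warn = FALSE))
    }),
    config_hash = rlang::hash(config)
  )
  yaml::write_yaml(manifest, file.path(outdir, "manifest.yaml"))
  results$manifest <- manifest
  invisible(results)
}
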