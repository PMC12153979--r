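Package: dmsenergy
Title: Energy Landscapes of Amyloid Nucleation from Deep Mutational Scanning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers quantitative energy landscapes of amyloid nucleation from
    deep-mutational-scanning selection experiments. Converts variant
    sequencing counts into relative growth rates with error estimates, fits
    global-epistasis energy models (additive changes in free energy of
    activation plus optional pairwise energetic couplings under a bounded
    sigmoid), calibrates model terms to kcal/mol with in vitro nucleation
    rate constants via transition-state theory, computes phi-like ratios of
    activation to fibril-stability free energy changes across fibril
    polymorphs, and compares energetic couplings with side-chain distances
    in fibril structures. Includes degenerate-codon library design tools and
    a synthetic-data generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    stringr,
    readr,
    ggplot2,
    generics,
    Matrix,
    Biostrings,
    bio3d,
    yaml,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
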