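# Plain-text interchange: tab-separated tables with '#'-prefixed headers
# carrying the seed and a content hash, and YAML library-design specs.

#' Write a tibble as TSV with a commented provenance header
#'
#' @param x Data frame.
#' @param path Output path.
#' @param seed Optional seed to record.
#' @param extra Named character vector of extra header fields.
#' @return `path`, invisibly.
#' @export
write_tsv_header <- function(x, path, seed = NULL, extra = NULL) {
  hdr <- c(
    paste0("# dmsenergy v", as.character(utils::packageVersion("dmsenergy"))),
    if (!is.null(seed)) paste0("# seed: ", seed),
    if (!is.null(extra)) paste0("# ", names(extra), ": ", extra),
    paste0("# hash: ", rlang::hash(x))
  )
  writeLines(hdr, path)
  readr::write_tsv(x, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read a TSV written by [write_tsv_header()]
#'
#' @param path Input path.
#' @return Tibble (header comments skipped).
#' @export
read_tsv_header <- function(path) {
  # na = "NA" keeps empty strings (the wild-type variant label) as ""
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE, na = "NA")
}

#' Write library designs to a YAML spec
#'
#' @param designs Named list of `library_design` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_design_yaml <- function(designs, path) {
  if (inherits(designs, "library_design")) designs <- list(designs)
  spec <- lapply(designs, function(d) {
    list(
      name = d$name,
      sequence = d$sequence,
      positions = as.integer(d$sites$position),
      alphabet = paste(d$sites$alphabet[[1]], collapse = ""),
      max_order = d$max_order
    )
  })
  yaml::write_yaml(spec, path)
  invisible(path)
}

#' Read library designs from a YAML spec
#'
#' @param path YAML file written by [write_design_yaml()] (or hand-written
#'   with fields `name`, `sequence`, `positions`, `alphabet`, `max_order`).
#' @return Named list of `library_design` objects.
#' @export
read_design_yaml <- function(path) {
  spec <- yaml::read_yaml(path)
  out <- lapply(spec, function(s) {
    library_design(
      name = s$name,
      positions = as.integer(s$positions),
      alphabet = if (is.null(s$alphabet) || s$alphabet == "") NULL else
        strsplit(s$alphabet, "")[[1]],
      max_order = s$max_order,
      sequence = s$sequence
    )
  })
  stats::setNames(out, purrr::map_chr(out, "name"))
}
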