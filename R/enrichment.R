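# From variant sequencing counts to relative growth rates with error
# estimates: input-read filtering, log-ratio enrichment scores relative to a
# reference, Poisson counting errors, error-weighted replicate merging and
# centering on wild-type synonyms.

input_cols <- function(counts) grep("^input_", names(counts), value = TRUE)
output_cols <- function(counts) grep("^output_", names(counts), value = TRUE)

#' Filter variants by minimum input reads
#'
#' A variant is retained only if its input count reaches `min_input_reads`
#' (inclusive) in every replicate; a filter log of removals is attached as
#' the `"filter_log"` attribute.
#'
#' @param counts Count table: `variant` column plus paired `input_rep*` /
#'   `output_rep*` columns.
#' @param min_input_reads Threshold in reads (default 10).
#' @return Filtered count table.
#' @export
filter_counts <- function(counts, min_input_reads = 10) {
  ic <- input_cols(counts)
  if (nrow(counts) == 0L || length(ic) == 0L) {
    stop("count table is empty or has no input_rep* columns")
  }
  keep <- Reduce(`&`, lapply(counts[ic], function(x) x >= min_input_reads))
  out <- counts[keep, , drop = FALSE]
  attr(out, "filter_log") <- tibble::tibble(
    variant = counts$variant[!keep],
    reason = sprintf("input reads below %g in at least one replicate",
                     min_input_reads)
  )
  out
}

#' Poisson counting error of a relative growth rate
#'
#' Counting-noise standard deviation of a log-ratio enrichment difference:
#' `sigma^2 = 1/(n_in + pc) + 1/(n_out + pc) + 1/(ref_in + pc) +
#' 1/(ref_out + pc)` with pseudocount `pc`.
#'
#' @param n_in,n_out Variant input/output counts (vectorized).
#' @param ref_in,ref_out Reference (wild-type) input/output counts.
#' @param pseudocount Added to every raw count (default 0.5).
#' @return Standard deviation vector.
#' @export
count_error <- function(n_in, n_out, ref_in, ref_out, pseudocount = 0.5) {
  sqrt(1 / (n_in + pseudocount) + 1 / (n_out + pseudocount) +
       1 / (ref_in + pseudocount) + 1 / (ref_out + pseudocount))
}

find_reference <- function(counts, reference) {
  if (is.null(reference)) reference <- ""
  idx <- which(counts$variant == reference &
                 !(counts[["is_wt_synonym"]] %||% rep(FALSE, nrow(counts))))
  if (length(idx) == 0L) {
    stop("reference variant '",
         if (reference == "") "(wild type)" else reference,
         "' not present in the count table; pass `reference =` explicitly")
  }
  idx[[1]]
}

#' Per-replicate enrichment scores and relative growth rates
#'
#' The enrichment score of a variant in a replicate is the natural log of
#' its output-pool frequency over its input-pool frequency (frequencies from
#' pseudocounted reads over raw pool depths); the relative growth rate is the
#' enrichment score minus the reference's. Errors are Poisson counting errors
#' from [count_error()].
#'
#' @param counts Count table (`variant`, `input_rep*`, `output_rep*`;
#'   optional `is_wt_synonym` logical).
#' @param reference Mutation string of the reference variant; `NULL` (default)
#'   uses the wild type (`""`). Combinatorial libraries without the wild type
#'   must designate a reference variant present in the data.
#' @param pseudocount Added to raw counts before taking logs.
#' @return Long tibble: `variant`, `is_wt_synonym`, `replicate`, `es`, `gr`,
#'   `sigma`.
#' @export
enrichment_scores <- function(counts, reference = NULL, pseudocount = 0.5) {
  ic <- input_cols(counts)
  oc <- output_cols(counts)
  stopifnot(length(ic) == length(oc), length(ic) >= 1L)
  ref <- find_reference(counts, reference)
  syn <- counts[["is_wt_synonym"]] %||% rep(FALSE, nrow(counts))
  id <- counts[["id"]] %||% counts$variant
  reps <- lapply(seq_along(ic), function(r) {
    n_in <- counts[[ic[[r]]]]
    n_out <- counts[[oc[[r]]]]
    depth_in <- sum(n_in)
    depth_out <- sum(n_out)
    es <- log((n_out + pseudocount) / depth_out) -
      log((n_in + pseudocount) / depth_in)
    tibble::tibble(
      id = id,
      variant = counts$variant,
      is_wt_synonym = syn,
      replicate = r,
      es = es,
      gr = es - es[[ref]],
      sigma = count_error(n_in, n_out, n_in[[ref]], n_out[[ref]], pseudocount)
    )
  })
  dplyr::bind_rows(reps)
}

#' Merge replicate growth rates and center on wild-type synonyms
#'
#' Replicates are combined by the error-weighted mean
#' (`sum(gr/sigma^2) / sum(1/sigma^2)`) with merged error
#' `(sum(1/sigma^2))^(-1/2)`. When wild-type synonym variants are present,
#' all merged growth rates are shifted so their error-weighted mean is zero.
#'
#' @param scores Long tibble from [enrichment_scores()].
#' @param center Center on wild-type synonyms when available.
#' @return Tibble: `variant`, `is_wt_synonym`, `gr`, `sigma`, `n_reps`.
#' @export
merge_replicates <- function(scores, center = TRUE) {
  stopifnot(all(c("variant", "gr", "sigma") %in% names(scores)))
  if (!"is_wt_synonym" %in% names(scores)) scores$is_wt_synonym <- FALSE
  if (!"id" %in% names(scores)) scores$id <- scores$variant
  scores <- scores[is.finite(scores$gr) & is.finite(scores$sigma), ,
                   drop = FALSE]
  grp <- factor(scores$id, levels = unique(scores$id))
  w <- 1 / scores$sigma^2
  num <- rowsum(scores$gr * w, grp)[, 1]
  den <- rowsum(w, grp)[, 1]
  first <- !duplicated(grp)
  merged <- tibble::tibble(
    id = scores$id[first],
    variant = scores$variant[first],
    is_wt_synonym = scores$is_wt_synonym[first],
    gr = unname(num / den),
    sigma = unname(den^(-1 / 2)),
    n_reps = as.integer(tabulate(grp))
  )
  if (center && any(merged$is_wt_synonym)) {
    syn <- merged[merged$is_wt_synonym, , drop = FALSE]
    shift <- sum(syn$gr / syn$sigma^2) / sum(1 / syn$sigma^2)
    merged$gr <- merged$gr - shift
  }
  merged
}

#' Scale merged growth rates to the unit interval
#'
#' Affine map sending the minimum to 0 and the maximum to 1. Visualization
#' only; all inference uses unscaled growth rates.
#'
#' @param gr Numeric vector with at least two distinct values.
#' @return Scaled vector.
#' @export
scale_unit_interval <- function(gr) {
  rng <- range(gr, finite = TRUE)
  if (diff(rng) == 0) stop("cannot scale a constant vector to [0, 1]")
  (gr - rng[[1]]) / diff(rng)
}

#' Counts-to-growth-rates convenience pipeline
#'
#' Applies [filter_counts()], [enrichment_scores()] and [merge_replicates()]
#' in sequence.
#'
#' @inheritParams enrichment_scores
#' @inheritParams filter_counts
#' @param center Passed to [merge_replicates()].
#' @return Merged growth-rate tibble.
#' @export
process_counts <- function(counts, reference = NULL, min_input_reads = 10,
                           pseudocount = 0.5, center = TRUE) {
  counts |>
    filter_counts(min_input_reads = min_input_reads) |>
    enrichment_scores(reference = reference, pseudocount = pseudocount) |>
    merge_replicates(center = center)
}
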