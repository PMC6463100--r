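#' Merge filtered callsets into ensemble variants with a confidence score
#'
#' Combines the post-filter callsets of all (aligner, caller)
#' combinations into one variant per distinct normalized key. The number
#' of combinations supporting a variant is its **confidence score** - with
#' the default 3 aligners x 2 callers, between 1 and 6. The score is a
#' prioritization aid, not an elimination criterion: singly-supported
#' variants can be real. Conflicting annotation values across combinations
#' are aggregated as the maximum QUAL and the median DP.
#'
#' @param calls A normalized call tibble covering all combinations
#'   (columns `chrom`, `pos`, `ref`, `alt`, `aligner`, `caller`, plus
#'   optional `qual`/`dp`). Each (aligner, caller) pair may contribute at
#'   most one call per key.
#' @param combos A combination table ([combo_table()]) declaring the run's
#'   (aligner, caller) pairs; calls from undeclared pairs are an error.
#' @return A tibble of class `merged_variants`, sorted by (chrom, pos,
#'   ref, alt), with columns `chrom`, `pos`, `ref`, `alt`, `type`,
#'   `confidence`, `combos` (comma-separated supporting ids), `qual_max`,
#'   `dp_median`. The result is invariant under permutation of the input
#'   rows.
#' @export
#' @examples
#' calls <- tidyr::expand_grid(
#'   tibble::tibble(chrom = "chr1", pos = 100L, ref = "A", alt = "G"),
#'   combo_table()
#' )
#' merge_callsets(calls)
merge_callsets <- function(calls, combos = combo_table()) {
  assert_calls(calls, c("chrom", "pos", "ref", "alt", "aligner", "caller"))
  calls <- as_tibble(calls)
  combo_ids <- paste(calls$aligner, calls$caller, sep = "_")
  undeclared <- setdiff(unique(combo_ids), combos$combo)
  if (nrow(calls) > 0 && length(undeclared) > 0) {
    abort(paste0("calls from undeclared combination(s): ",
                 paste(undeclared, collapse = ", ")))
  }
  dup <- dplyr::count(calls, .data$chrom, .data$pos, .data$ref, .data$alt,
                      .data$aligner, .data$caller)
  if (any(dup$n > 1)) {
    abort("a callset contains duplicate calls for the same variant key")
  }
  calls$combo <- combo_ids
  if (!"qual" %in% names(calls)) calls$qual <- NA_real_
  if (!"dp" %in% names(calls)) calls$dp <- NA_real_
  # Sort combos in declared order so output is permutation-invariant.
  merged <- calls |>
    dplyr::group_by(.data$chrom, .data$pos, .data$ref, .data$alt) |>
    dplyr::summarise(
      confidence = dplyr::n_distinct(.data$combo),
      combos = paste(combos$combo[combos$combo %in% .data$combo],
                     collapse = ","),
      qual_max = if (all(is.na(.data$qual))) NA_real_
                 else max(.data$qual, na.rm = TRUE),
      dp_median = if (all(is.na(.data$dp))) NA_real_
                  else median(.data$dp, na.rm = TRUE),
      .groups = "drop"
    ) |>
    classify_variants() |>
    arrange_genomic() |>
    dplyr::relocate("type", .after = "alt")
  class(merged) <- c("merged_variants", class(merged))
  merged
}

#' Confidence-score distribution
#'
#' Tabulates merged variants by confidence score, including zero-count
#' scores up to the configured maximum so the distribution always spans
#' the full 1..max range.
#'
#' @param merged A [merge_callsets()] result (or any tibble with a
#'   `confidence` column).
#' @param max_score Highest possible score; defaults to the number of
#'   combinations seen, floored at the default 6.
#' @return A tibble with columns `score` and `n`; `sum(n)` equals
#'   `nrow(merged)`.
#' @export
score_distribution <- function(merged, max_score = NULL) {
  assert_calls(merged, "confidence")
  max_score <- max_score %||%
    max(6L, if (nrow(merged) > 0) max(merged$confidence) else 0L)
  counts <- dplyr::count(as_tibble(merged), score = .data$confidence)
  dplyr::left_join(tibble(score = seq_len(max_score)), counts, by = "score") |>
    dplyr::mutate(n = tidyr::replace_na(.data$n, 0L))
}

#' @export
print.merged_variants <- function(x, ...) {
  cat(sprintf("Merged ensemble callset: %d variant(s)\n", nrow(x)))
  NextMethod()
}

#' Tidy a merged ensemble callset
#'
#' @param x A `merged_variants` object.
#' @param ... Unused.
#' @return The merged table as a plain tibble.
#' @export
tidy.merged_variants <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "merged_variants")
  out
}

#' One-row summary of a merged ensemble callset
#'
#' @param x A `merged_variants` object.
#' @param ... Unused.
#' @return A one-row tibble: variant count, mean/max confidence, and the
#'   count at full support.
#' @export
glance.merged_variants <- function(x, ...) {
  tibble(
    n_variants = nrow(x),
    mean_confidence = if (nrow(x) > 0) mean(x$confidence) else NA_real_,
    max_confidence = if (nrow(x) > 0) max(x$confidence) else NA_integer_,
    n_full_support = sum(x$confidence == max(6L, x$confidence))
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
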