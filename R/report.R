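#' Per-amplicon read coverage table
#'
#' Counts, for each amplicon and each aligner, the reads whose aligned
#' reference span overlaps the amplicon by at least one base. A read
#' overlapping several amplicons counts toward each; typical panels have
#' near-disjoint targets so double counting is marginal, and the table's
#' purpose is spotting dropped-out amplicons.
#'
#' @param reads A read tibble with `chrom`, `pos`, `cigar` and `aligner`
#'   columns.
#' @param regions A region tibble from [read_regions()].
#' @return A tibble with one row per region and one `n_<aligner>` column
#'   per aligner, in region file order.
#' @export
amplicon_coverage <- function(reads, regions) {
  assert_calls(reads, c("chrom", "pos", "cigar", "aligner"))
  assert_calls(regions, c("chrom", "start", "end"))
  reads <- as_tibble(reads)
  spans <- purrr::map2_int(reads$cigar, reads$pos,
                           ~ cigar_events(.x, .y)$end)
  aligners <- unique(reads$aligner)
  out <- as_tibble(regions)
  for (al in aligners) {
    sel <- reads$aligner == al
    out[[paste0("n_", al)]] <- purrr::pmap_int(
      list(out$chrom, out$start, out$end),
      function(chrom, start, end) {
        # BED [start, end) in 0-based = [start + 1, end] in 1-based.
        sum(sel & reads$chrom == chrom &
              reads$pos <= end & spans >= start + 1L)
      }
    )
  }
  out
}

#' Sensitivity and specificity from confusion counts
#'
#' Computes benchmark metrics from a confusion table against a truth set:
#' sensitivity `TP/(TP+FN)` and specificity `TN/(TN+FP)`, as percentages
#' rounded half-away-from-zero to two decimals. A zero denominator yields
#' `NA` for the affected metric, never 0 or 100.
#'
#' @param tp,tn,fp,fn Non-negative confusion counts.
#' @return A one-row tibble with `tp`, `tn`, `fp`, `fn`,
#'   `sensitivity_pct`, `specificity_pct`.
#' @export
#' @examples
#' confusion_metrics(tp = 25983, tn = 38974865, fp = 5863, fn = 2257)
confusion_metrics <- function(tp, tn, fp, fn) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(is.na(counts)) || any(counts < 0)) {
    abort("confusion counts must be non-negative numbers")
  }
  sens <- if (tp + fn > 0) round_half_up(100 * tp / (tp + fn)) else NA_real_
  spec <- if (tn + fp > 0) round_half_up(100 * tn / (tn + fp)) else NA_real_
  tibble(tp = tp, tn = tn, fp = fp, fn = fn,
         sensitivity_pct = sens, specificity_pct = spec)
}

#' Weighted mean confidence score of a distribution
#'
#' Averages a score distribution given as per-score percentages (or
#' counts): `sum(score * weight) / sum(weight)`, reported to two decimals
#' (half-away-from-zero).
#'
#' @param dist A data frame with columns `score` and `pct` (or a named
#'   numeric vector, names = scores).
#' @return Numeric scalar.
#' @export
#' @examples
#' mean_confidence(c(`1` = 0.31, `2` = 0.52, `3` = 1.95,
#'                   `4` = 4.61, `5` = 2.56, `6` = 90.04))
mean_confidence <- function(dist) {
  if (is.numeric(dist) && !is.null(names(dist))) {
    dist <- tibble(score = as.numeric(names(dist)), pct = unname(dist))
  }
  assert_calls(dist, c("score", "pct"))
  if (nrow(dist) == 0 || sum(dist$pct) <= 0) {
    abort("mean_confidence() needs a distribution with positive total weight")
  }
  if (any(dist$pct < 0)) abort("distribution weights must be non-negative")
  round_half_up(sum(dist$score * dist$pct) / sum(dist$pct))
}

#' Build the ranked final report
#'
#' Orders merged variants by descending confidence score, then genomic
#' position, optionally joining a user-supplied annotation table (gene
#' symbols, external database columns) on the variant key. Summary tables
#' (per-gene, per-score, per-type counts) each conserve the total variant
#' count.
#'
#' @param merged A [merge_callsets()] result.
#' @param annotations Optional tibble keyed by `chrom`, `pos`, `ref`,
#'   `alt` with extra columns (e.g. `gene`); rows whose key is absent from
#'   `merged` are ignored with a warning.
#' @param max_score Passed to [score_distribution()].
#' @return An object of class `variant_report`: a list with `report`
#'   (ranked rows), `per_gene`, `per_score`, `per_type` tibbles.
#' @export
build_report <- function(merged, annotations = NULL, max_score = NULL) {
  assert_calls(merged, c("chrom", "pos", "ref", "alt", "confidence"))
  report <- as_tibble(merged)
  class(report) <- setdiff(class(report), "merged_variants")
  if (!"type" %in% names(report)) report <- classify_variants(report)
  if (!is.null(annotations)) {
    assert_calls(annotations, c("chrom", "pos", "ref", "alt"))
    ann <- as_tibble(annotations)
    known <- variant_id(report$chrom, report$pos, report$ref, report$alt)
    ids <- variant_id(ann$chrom, ann$pos, ann$ref, ann$alt)
    orphan <- !ids %in% known
    if (any(orphan)) {
      warn(sprintf("%d annotation row(s) match no merged variant and were ignored",
                   sum(orphan)))
      ann <- ann[!orphan, ]
    }
    report <- dplyr::left_join(report, ann,
                               by = c("chrom", "pos", "ref", "alt"))
  }
  report <- dplyr::arrange(report, dplyr::desc(.data$confidence),
                           .data$chrom, .data$pos, .data$ref, .data$alt)
  per_gene <- if ("gene" %in% names(report)) {
    dplyr::count(report,
                 gene = tidyr::replace_na(.data$gene, "N/A"), name = "n")
  } else {
    tibble(gene = character(), n = integer())
  }
  structure(
    list(
      report = report,
      per_gene = per_gene,
      per_score = score_distribution(report, max_score),
      per_type = dplyr::count(report, .data$type, .drop = FALSE, name = "n")
    ),
    class = "variant_report"
  )
}

#' @export
print.variant_report <- function(x, ...) {
  cat(sprintf("Variant report: %d variant(s)\n", nrow(x$report)))
  print(utils::head(x$report, 10))
  invisible(x)
}

#' @rdname build_report
#' @param x A `variant_report`.
#' @param ... Unused.
#' @export
tidy.variant_report <- function(x, ...) x$report

#' @rdname build_report
#' @export
glance.variant_report <- function(x, ...) {
  tibble(
    n_variants = nrow(x$report),
    mean_confidence = if (nrow(x$report) > 0) mean(x$report$confidence)
                      else NA_real_,
    n_genes = sum(x$per_gene$gene != "N/A"),
    n_snp = sum(x$per_type$n[x$per_type$type == "SNP"]),
    n_indel = sum(x$per_type$n[x$per_type$type %in% c("INS", "DEL")])
  )
}
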