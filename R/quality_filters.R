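#' Filter configurations
#'
#' Hard-filter thresholds for the quality-expression stage. Defaults are
#' the panel-calibrated values used throughout: SNPs fail on
#' `MQ0 >= 4 && MQ0/DP > 0.1`, `DP < 5`, `QUAL < 50`, `QD < 0.7` or
#' `FS > 60` (`FS > 590` for bwa-aligned callsets, whose Fisher-strand
#' statistic runs systematically high on amplicon data), plus a SNP-cluster
#' rule (3 or more SNPs within 10 bp). Indels fail on
#' `QD < 2.5 || ReadPosRankSum < -20 || FS > 200`. SAMtools-style callsets
#' are instead depth-filtered to coverage within `[2, 4000]`. Any
#' sub-expression whose annotation is absent counts as failing
#' (missing-values-fail semantics), contributing a `MISSING_<FIELD>`
#' reason.
#'
#' @param min_dp,min_qual,min_qd,max_fs SNP thresholds (fail when below /
#'   above).
#' @param max_fs_bwa Aligner-specific FS threshold applied to bwa callsets.
#' @param mq0_count,mq0_ratio Both must hold for the MQ0 rule to fail a
#'   call: at least `mq0_count` mapping-quality-zero reads *and*
#'   `MQ0/DP > mq0_ratio`.
#' @param cluster_window,cluster_size A SNP is flagged when it belongs to a
#'   run of `cluster_size` SNPs spanning at most `cluster_window` bp.
#' @return A named list of thresholds.
#' @export
#' @examples
#' snp_filter_config(min_dp = 10)
snp_filter_config <- function(min_dp = 5L, min_qual = 50.0, min_qd = 0.7,
                              max_fs = 60.0, max_fs_bwa = 590.0,
                              mq0_count = 4L, mq0_ratio = 0.1,
                              cluster_window = 10L, cluster_size = 3L) {
  stopifnot(cluster_window >= 0, cluster_size >= 2,
            is.finite(c(min_dp, min_qual, min_qd, max_fs, max_fs_bwa,
                        mq0_count, mq0_ratio)))
  list(min_dp = min_dp, min_qual = min_qual, min_qd = min_qd,
       max_fs = max_fs, max_fs_bwa = max_fs_bwa,
       mq0_count = mq0_count, mq0_ratio = mq0_ratio,
       cluster_window = as.integer(cluster_window),
       cluster_size = as.integer(cluster_size))
}

#' @rdname snp_filter_config
#' @param min_read_pos_rank_sum Indel threshold on the read-position
#'   rank-sum statistic.
#' @export
indel_filter_config <- function(min_qd = 2.5, min_read_pos_rank_sum = -20.0,
                                max_fs = 200.0) {
  stopifnot(is.finite(c(min_qd, min_read_pos_rank_sum, max_fs)))
  list(min_qd = min_qd, min_read_pos_rank_sum = min_read_pos_rank_sum,
       max_fs = max_fs)
}

#' @rdname snp_filter_config
#' @param min_cov,max_cov Depth range for SAMtools-style callsets.
#' @param gap_window,adjacent_gap_window Gap-adjacency windows; at the
#'   default 0 no gap-adjacency test is applied.
#' @export
depth_filter_config <- function(min_cov = 2L, max_cov = 4000L,
                                gap_window = 0L, adjacent_gap_window = 0L) {
  stopifnot(min_cov >= 0, min_cov <= max_cov)
  list(min_cov = as.integer(min_cov), max_cov = as.integer(max_cov),
       gap_window = as.integer(gap_window),
       adjacent_gap_window = as.integer(adjacent_gap_window))
}

new_verdicts <- function(calls, reasons) {
  out <- as_tibble(calls)
  out$reasons <- reasons
  out$passed <- lengths(reasons) == 0
  out
}

#' Target-region filter
#'
#' Drops calls whose anchor position falls outside every targeted region.
#' Membership is tested on the normalized anchor position only: a call at
#' 1-based `pos` is on target when `pos - 1` lies in some 0-based
#' half-open `[start, end)` interval on the same chromosome.
#'
#' @param calls A call tibble (normalized).
#' @param regions A region tibble from [read_regions()].
#' @return The retained calls, input order preserved.
#' @export
#' @examples
#' calls <- tibble::tibble(chrom = "chr17", pos = 7578001L, ref = "A", alt = "G")
#' regions <- tibble::tibble(chrom = "chr17", start = 7578000L, end = 7578200L,
#'                           name = "AMP1")
#' filter_region(calls, regions)
filter_region <- function(calls, regions) {
  assert_calls(calls)
  assert_calls(regions, c("chrom", "start", "end"))
  if (nrow(calls) == 0 || nrow(regions) == 0) return(as_tibble(calls)[0, ])
  keep <- purrr::map2_lgl(calls$chrom, calls$pos, function(chrom, pos) {
    any(regions$chrom == chrom &
          regions$start <= pos - 1L &
          pos - 1L < regions$end)
  })
  as_tibble(calls)[keep, ]
}

#' Quality-expression verdicts for SNP calls
#'
#' Applies the SNP hard-filter expressions to each call. Every
#' sub-expression that matches contributes a reason (`MQ0_RATIO`,
#' `LOW_DP`, `LOW_QUAL`, `LOW_QD`, `HIGH_FS`); a sub-expression that
#' references an absent annotation matches too, contributing
#' `MISSING_<FIELD>`. The FS threshold is `max_fs_bwa` for calls from the
#' bwa aligner and `max_fs` otherwise.
#'
#' @param calls A call tibble whose rows are all SNP or MNP calls.
#' @param config A [snp_filter_config()].
#' @return The input with list-column `reasons` and logical `passed` added
#'   (`passed` is `TRUE` exactly when `reasons` is empty).
#' @export
evaluate_snp_filters <- function(calls, config = snp_filter_config()) {
  assert_calls(calls, c("chrom", "pos", "ref", "alt", "aligner"))
  types <- variant_type(calls$ref, calls$alt)
  if (!all(types %in% c("SNP", "MNP"))) {
    abort("evaluate_snp_filters() expects SNP/MNP calls only; route indels to evaluate_indel_filters()")
  }
  n <- nrow(calls)
  na_num <- function(nm) calls[[nm]] %||% rep(NA_real_, n)
  dp <- na_num("dp"); qual <- na_num("qual"); qd <- na_num("qd")
  fs <- na_num("fs"); mq0 <- na_num("mq0")
  fs_thr <- ifelse(calls$aligner == "bwa", config$max_fs_bwa, config$max_fs)
  reasons <- purrr::map(seq_len(n), function(i) {
    r <- character()
    # MQ0 rule references MQ0 and DP.
    if (is.na(mq0[i])) r <- c(r, "MISSING_MQ0")
    if (is.na(dp[i])) r <- c(r, "MISSING_DP")
    if (!is.na(mq0[i]) && !is.na(dp[i]) &&
        mq0[i] >= config$mq0_count && mq0[i] / dp[i] > config$mq0_ratio) {
      r <- c(r, "MQ0_RATIO")
    }
    if (!is.na(dp[i]) && dp[i] < config$min_dp) r <- c(r, "LOW_DP")
    if (is.na(qual[i])) r <- c(r, "MISSING_QUAL")
    else if (qual[i] < config$min_qual) r <- c(r, "LOW_QUAL")
    if (is.na(qd[i])) r <- c(r, "MISSING_QD")
    else if (qd[i] < config$min_qd) r <- c(r, "LOW_QD")
    if (is.na(fs[i])) r <- c(r, "MISSING_FS")
    else if (fs[i] > fs_thr[i]) r <- c(r, "HIGH_FS")
    unique(r)
  })
  new_verdicts(calls, reasons)
}

#' SNP-cluster verdicts
#'
#' Flags every SNP that belongs to a run of at least `cluster_size` SNPs
#' spanning at most `cluster_window` bp on the same chromosome (clustered
#' SNPs in amplicon data are usually alignment artifacts). Non-SNP rows
#' pass untouched.
#'
#' @inheritParams evaluate_snp_filters
#' @return The input with `reasons` (containing `"SNP_CLUSTER"` for
#'   flagged calls) and `passed` columns.
#' @export
flag_snp_clusters <- function(calls, config = snp_filter_config()) {
  assert_calls(calls)
  n <- nrow(calls)
  types <- variant_type(calls$ref, calls$alt)
  flagged <- rep(FALSE, n)
  snp_idx <- which(types == "SNP")
  for (chrom in unique(calls$chrom[snp_idx])) {
    idx <- snp_idx[calls$chrom[snp_idx] == chrom]
    idx <- idx[order(calls$pos[idx])]
    pos <- calls$pos[idx]
    k <- config$cluster_size
    if (length(pos) >= k) {
      for (i in seq_len(length(pos) - k + 1)) {
        if (pos[i + k - 1] - pos[i] <= config$cluster_window) {
          flagged[idx[i:(i + k - 1)]] <- TRUE
        }
      }
    }
  }
  reasons <- purrr::map(flagged, function(f) if (f) "SNP_CLUSTER" else character())
  new_verdicts(calls, reasons)
}

#' Quality-expression verdicts for indel calls
#'
#' An indel fails when any disjunct of
#' `QD < min_qd || ReadPosRankSum < min_read_pos_rank_sum || FS > max_fs`
#' matches (reason `INDEL_EXPR`); a disjunct whose annotation is absent
#' matches as well (reason `MISSING_<FIELD>`).
#'
#' @param calls A call tibble whose rows are all INS/DEL/COMPLEX calls.
#' @param config An [indel_filter_config()].
#' @return The input with `reasons` and `passed` columns.
#' @export
evaluate_indel_filters <- function(calls, config = indel_filter_config()) {
  assert_calls(calls)
  types <- variant_type(calls$ref, calls$alt)
  if (any(types %in% c("SNP", "MNP"))) {
    abort("evaluate_indel_filters() expects indel calls only; route SNPs to evaluate_snp_filters()")
  }
  n <- nrow(calls)
  na_num <- function(nm) calls[[nm]] %||% rep(NA_real_, n)
  qd <- na_num("qd"); rprs <- na_num("read_pos_rank_sum"); fs <- na_num("fs")
  reasons <- purrr::map(seq_len(n), function(i) {
    r <- character()
    if (is.na(qd[i])) r <- c(r, "MISSING_QD")
    else if (qd[i] < config$min_qd) r <- c(r, "INDEL_EXPR")
    if (is.na(rprs[i])) r <- c(r, "MISSING_READPOSRANKSUM")
    else if (rprs[i] < config$min_read_pos_rank_sum) r <- c(r, "INDEL_EXPR")
    if (is.na(fs[i])) r <- c(r, "MISSING_FS")
    else if (fs[i] > config$max_fs) r <- c(r, "INDEL_EXPR")
    unique(r)
  })
  new_verdicts(calls, reasons)
}

#' Depth-range verdicts for SAMtools-style callsets
#'
#' Fails calls whose depth lies outside `[min_cov, max_cov]` (reason
#' `DEPTH_RANGE`) or whose depth annotation is absent (`MISSING_DP`).
#' With the default zero gap windows no gap-adjacency test is applied.
#'
#' @param calls A call tibble.
#' @param config A [depth_filter_config()].
#' @return The input with `reasons` and `passed` columns.
#' @export
evaluate_depth_filter <- function(calls, config = depth_filter_config()) {
  assert_calls(calls)
  n <- nrow(calls)
  dp <- calls[["dp"]] %||% rep(NA_real_, n)
  reasons <- purrr::map(seq_len(n), function(i) {
    if (is.na(dp[i])) "MISSING_DP"
    else if (dp[i] < config$min_cov || dp[i] > config$max_cov) "DEPTH_RANGE"
    else character()
  })
  new_verdicts(calls, reasons)
}

#' Apply the quality-expression stage to labeled callsets
#'
#' Routes each call through the rule set of its caller's style: GATK-style
#' callsets get the SNP expressions plus the SNP-cluster rule for
#' SNPs/MNPs and the indel expressions for indels; SAMtools-style callsets
#' get the depth-range filter. Reasons from all applicable rules are
#' unioned per call.
#'
#' @param calls A call tibble covering any number of (aligner, caller)
#'   combinations.
#' @param snp_config,indel_config,depth_config Stage configurations.
#' @param style_map Named character vector mapping caller names to rule
#'   styles (`"gatk"` or `"samtools"`).
#' @return The input with `reasons` and `passed` columns.
#' @export
apply_quality_filters <- function(calls,
                                  snp_config = snp_filter_config(),
                                  indel_config = indel_filter_config(),
                                  depth_config = depth_filter_config(),
                                  style_map = c(gatk = "gatk",
                                                samtools = "samtools")) {
  assert_calls(calls, c("chrom", "pos", "ref", "alt", "aligner", "caller"))
  n <- nrow(calls)
  if (n == 0) return(new_verdicts(calls, list()))
  unknown <- setdiff(unique(calls$caller), names(style_map))
  if (length(unknown) > 0) {
    abort(paste0("no filter style declared for caller(s): ",
                 paste(unknown, collapse = ", ")))
  }
  style <- unname(style_map[calls$caller])
  types <- variant_type(calls$ref, calls$alt)
  reasons <- vector("list", n)
  for (i in seq_len(n)) reasons[[i]] <- character()

  gatk_snp <- which(style == "gatk" & types %in% c("SNP", "MNP"))
  if (length(gatk_snp) > 0) {
    v <- evaluate_snp_filters(calls[gatk_snp, ], snp_config)
    reasons[gatk_snp] <- purrr::map2(reasons[gatk_snp], v$reasons, union)
    # SNP clustering is evaluated within each callset, over its SNPs only.
    for (cs in unique(paste(calls$aligner[gatk_snp], calls$caller[gatk_snp]))) {
      idx <- gatk_snp[paste(calls$aligner[gatk_snp], calls$caller[gatk_snp]) == cs]
      vc <- flag_snp_clusters(calls[idx, ], snp_config)
      reasons[idx] <- purrr::map2(reasons[idx], vc$reasons, union)
    }
  }
  gatk_indel <- which(style == "gatk" & !types %in% c("SNP", "MNP"))
  if (length(gatk_indel) > 0) {
    v <- evaluate_indel_filters(calls[gatk_indel, ], indel_config)
    reasons[gatk_indel] <- purrr::map2(reasons[gatk_indel], v$reasons, union)
  }
  sam <- which(style == "samtools")
  if (length(sam) > 0) {
    v <- evaluate_depth_filter(calls[sam, ], depth_config)
    reasons[sam] <- purrr::map2(reasons[sam], v$reasons, union)
  }
  new_verdicts(calls, reasons)
}

#' Union-retention across aligner combinations
#'
#' Within each caller group, a variant is retained when at least one
#' aligner combination left it unlabeled: a key is removed only if every
#' aligner's filter labeled it. The rule is stated for the GATK group and
#' applied symmetrically to the SAMtools group.
#'
#' @param calls A call tibble with `reasons`/`passed` columns from
#'   [apply_quality_filters()].
#' @return A tibble of retained keys, one row per (caller, chrom, pos,
#'   ref, alt) that passed in at least one of that caller's callsets.
#' @export
retain_union <- function(calls) {
  assert_calls(calls, c("chrom", "pos", "ref", "alt", "caller", "passed"))
  empty <- tibble(caller = character(), chrom = character(), pos = integer(),
                  ref = character(), alt = character())
  if (nrow(calls) == 0) return(empty)
  keys <- dplyr::group_by(as_tibble(calls), .data$caller, .data$chrom,
                          .data$pos, .data$ref, .data$alt)
  keys <- dplyr::summarise(keys, retain = any(.data$passed), .groups = "drop")
  arrange_genomic(dplyr::select(dplyr::filter(keys, .data$retain), -"retain"))
}
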