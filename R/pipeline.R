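#' Assemble and validate a pipeline run configuration
#'
#' Declares the run's inputs and tool vocabulary and validates them before
#' any stage executes: every callset VCF must map to exactly one declared
#' (aligner, caller) combination, every alignment file to one declared
#' aligner, and all paths must exist. Validation failures abort with a
#' named error before anything is written.
#'
#' @param vcf A tibble with columns `path`, `aligner`, `caller`, one row
#'   per callset.
#' @param bed Path to the target-region BED file.
#' @param alignments Optional tibble with columns `path`, `aligner`, one
#'   row per aligner's SAM/BAM (required for the homopolymer stage and the
#'   coverage table; without it both are skipped).
#' @param reference Optional FASTA path (enables indel left-alignment and
#'   `mode = "homopolymer_run"` event matching).
#' @param annotation Optional TSV path of annotation columns keyed by
#'   `chrom`, `pos`, `ref`, `alt`.
#' @param out_dir Output directory.
#' @param aligners,callers Declared tool vocabularies.
#' @param snp_config,indel_config,depth_config,thresholds Stage
#'   configurations.
#' @param hp_mode Event matching mode for the homopolymer stage.
#' @return A validated config object of class `run_config`.
#' @export
run_config <- function(vcf, bed, alignments = NULL, reference = NULL,
                       annotation = NULL, out_dir = tempfile("varscreen_run_"),
                       aligners = default_aligners(),
                       callers = default_callers(),
                       snp_config = snp_filter_config(),
                       indel_config = indel_filter_config(),
                       depth_config = depth_filter_config(),
                       thresholds = hp_thresholds(),
                       hp_mode = c("exact", "homopolymer_run")) {
  hp_mode <- match.arg(hp_mode)
  assert_calls(vcf, c("path", "aligner", "caller"))
  combos <- combo_table(aligners, callers)
  ids <- paste(vcf$aligner, vcf$caller, sep = "_")
  undeclared <- setdiff(ids, combos$combo)
  if (length(undeclared) > 0) {
    abort(paste0("VCF declared for unknown combination(s): ",
                 paste(undeclared, collapse = ", ")))
  }
  if (anyDuplicated(ids)) {
    abort("more than one VCF declared for the same (aligner, caller) combination")
  }
  missing <- vcf$path[!file.exists(vcf$path)]
  if (!is.null(alignments)) {
    assert_calls(alignments, c("path", "aligner"))
    bad <- setdiff(alignments$aligner, aligners)
    if (length(bad) > 0) {
      abort(paste0("alignment file declared for unknown aligner(s): ",
                   paste(bad, collapse = ", ")))
    }
    if (anyDuplicated(alignments$aligner)) {
      abort("more than one alignment file declared for the same aligner")
    }
    missing <- c(missing, alignments$path[!file.exists(alignments$path)])
  }
  for (p in c(bed, reference, annotation)) {
    if (!is.null(p) && !file.exists(p)) missing <- c(missing, p)
  }
  if (length(missing) > 0) {
    abort(paste0("input file(s) not found: ", paste(missing, collapse = ", ")))
  }
  structure(
    list(vcf = as_tibble(vcf), bed = bed,
         alignments = if (is.null(alignments)) NULL else as_tibble(alignments),
         reference = reference, annotation = annotation, out_dir = out_dir,
         aligners = aligners, callers = callers, combos = combos,
         snp_config = snp_config, indel_config = indel_config,
         depth_config = depth_config, thresholds = thresholds,
         hp_mode = hp_mode),
    class = "run_config"
  )
}

#' Run the full filter-merge-report pipeline
#'
#' Executes the stages in order: region filter, quality-expression filters
#' with union retention per caller group, homopolymer indel filter,
#' ensemble merge with confidence scoring, and report generation. Every
#' stage's inputs and rejections are accounted for in a manifest; all
#' outputs are plain text and byte-stable, so a rerun on identical inputs
#' reproduces them exactly.
#'
#' Files written to `out_dir`: `filtered_<combo>.vcf` (stage-1 survivors
#' with FILTER labels), `merged.vcf` (ensemble calls with `CONF` /
#' `COMBOS` INFO tags), `report.tsv`, `summary_score.tsv`,
#' `summary_type.tsv`, `summary_gene.tsv`, `coverage.tsv` (when
#' alignments are supplied) and `manifest.json`.
#'
#' @param config A validated [run_config()].
#' @return An object of class `varscreen_run`: list with `merged`
#'   (a [merge_callsets()] result), `report` (a [build_report()] result),
#'   `coverage`, `site_stats`, `manifest`, `out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  regions <- read_regions(config$bed)
  reference <- if (!is.null(config$reference)) read_reference(config$reference)
  log_stage <- function(...) message(sprintf(...))

  calls <- purrr::pmap(config$vcf, function(path, aligner, caller) {
    read_vcf_calls(path, aligner, caller)
  })
  calls <- bind_rows(calls)
  calls <- normalize_variants(calls, reference)
  n_input <- nrow(calls)
  log_stage("input: %d calls across %d callsets", n_input, nrow(config$vcf))

  # Stage 1: target-region filter.
  on_target <- filter_region(calls, regions)
  log_stage("region filter: %d calls retained, %d off-target",
            nrow(on_target), n_input - nrow(on_target))

  # Stage 2: quality-expression filters + union retention per caller group.
  labeled <- apply_quality_filters(
    on_target, config$snp_config, config$indel_config, config$depth_config,
    style_map = setNames(config$callers, config$callers)
  )
  retained_keys <- retain_union(labeled)
  survivors <- dplyr::filter(labeled, .data$passed)
  # A passing call's key is by construction in the retained set; keep the
  # explicit semijoin so the rule reads as stated.
  survivors <- dplyr::semi_join(
    survivors, retained_keys,
    by = c("caller", "chrom", "pos", "ref", "alt")
  )
  log_stage("quality filters: %d calls pass (%d distinct keys retained)",
            nrow(survivors), nrow(retained_keys))

  # Stage 3: homopolymer indel filter (needs alignments).
  reads <- NULL
  site_stats <- NULL
  if (!is.null(config$alignments)) {
    reads <- bind_rows(purrr::pmap(config$alignments, read_alignments))
    hp <- filter_homopolymer(survivors, reads, config$thresholds,
                             reference = reference, mode = config$hp_mode)
    site_stats <- hp$site_stats
    n_hp <- length(unique(variant_id(
      hp$calls$chrom, hp$calls$pos, hp$calls$ref, hp$calls$alt
    )[hp$calls$hp_filtered]))
    survivors <- dplyr::filter(hp$calls, !.data$hp_filtered)
    log_stage("homopolymer filter: %d candidate site(s) rejected", n_hp)
  } else {
    log_stage("homopolymer filter: skipped (no alignments supplied)")
  }

  # Stage 4: ensemble merge + confidence score.
  merged <- merge_callsets(survivors, config$combos)
  log_stage("merge: %d variant(s), max confidence %s", nrow(merged),
            if (nrow(merged) > 0) max(merged$confidence) else "-")

  # Stage 5: report + summaries (+ coverage when alignments are present).
  annotations <- if (!is.null(config$annotation)) {
    ann <- utils::read.delim(config$annotation, sep = "\t",
                             stringsAsFactors = FALSE)
    ann$pos <- as.integer(ann$pos)
    as_tibble(ann)
  }
  report <- build_report(merged, annotations,
                         max_score = nrow(config$combos))
  coverage <- if (!is.null(reads)) amplicon_coverage(reads, regions)

  write_outputs(config, calls, labeled, survivors, merged, report, coverage)
  manifest <- build_manifest(config, n_input, on_target, labeled,
                             retained_keys, survivors, merged)
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  structure(
    list(merged = merged, report = report, coverage = coverage,
         site_stats = site_stats, manifest = manifest,
         out_dir = config$out_dir),
    class = "varscreen_run"
  )
}

write_outputs <- function(config, calls, labeled, survivors, merged, report,
                          coverage) {
  out <- config$out_dir
  # Per-combo filtered VCFs: stage-1 survivors with their filter labels.
  for (i in seq_len(nrow(config$vcf))) {
    al <- config$vcf$aligner[i]
    ca <- config$vcf$caller[i]
    sub <- dplyr::filter(labeled, .data$aligner == al, .data$caller == ca)
    sub$filter <- vapply(sub$reasons, function(r) {
      if (length(r) == 0) NA_character_ else paste(sort(r), collapse = ";")
    }, character(1))
    write_vcf_calls(arrange_genomic(sub),
                    file.path(out, sprintf("filtered_%s_%s.vcf", al, ca)))
  }
  mv <- as_tibble(merged)
  mv$conf <- mv$confidence
  mv$qual <- mv$qual_max
  mv$dp <- as.integer(round(mv$dp_median))
  write_vcf_calls(mv, file.path(out, "merged.vcf"))
  write_tsv_plain <- function(df, name) {
    df <- as.data.frame(df)
    list_cols <- vapply(df, is.list, logical(1))
    df[list_cols] <- lapply(df[list_cols],
                            vapply, paste, character(1), collapse = ";")
    utils::write.table(df, file.path(out, name), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  write_tsv_plain(report$report, "report.tsv")
  write_tsv_plain(report$per_score, "summary_score.tsv")
  write_tsv_plain(report$per_type, "summary_type.tsv")
  write_tsv_plain(report$per_gene, "summary_gene.tsv")
  if (!is.null(coverage)) write_tsv_plain(coverage, "coverage.tsv")
  invisible(out)
}

build_manifest <- function(config, n_input, on_target, labeled,
                           retained_keys, survivors, merged) {
  per_combo <- purrr::map(seq_len(nrow(config$vcf)), function(i) {
    al <- config$vcf$aligner[i]
    ca <- config$vcf$caller[i]
    lab <- dplyr::filter(labeled, .data$aligner == al, .data$caller == ca)
    surv <- dplyr::filter(survivors, .data$aligner == al, .data$caller == ca)
    list(
      combo = paste(al, ca, sep = "_"),
      n_after_region = nrow(lab),
      n_quality_labeled = sum(!lab$passed),
      n_final = nrow(surv)
    )
  })
  list(
    n_input_calls = n_input,
    n_off_target = n_input - nrow(on_target),
    n_retained_keys = nrow(retained_keys),
    n_merged_variants = nrow(merged),
    combos = per_combo
  )
}

#' @export
print.varscreen_run <- function(x, ...) {
  cat("varscreen pipeline run\n")
  cat(sprintf("  merged variants: %d\n", nrow(x$merged)))
  cat(sprintf("  outputs: %s\n", x$out_dir))
  invisible(x)
}
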