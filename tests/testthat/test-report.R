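test_that("amplicon coverage counts any 1-base overlap, per aligner", {
  regions <- tibble::tibble(chrom = "chr1", start = c(100L, 500L),
                            end = c(200L, 600L), name = c("A1", "A2"))
  reads <- tibble::tibble(
    read_id = c("inside", "last_base", "before", "spanning"),
    chrom = "chr1",
    pos = c(120L, 200L, 50L, 90L),
    cigar = c("50M", "30M", "40M", "150M"),
    mapq = 60L,
    aligner = c("bwa", "bwa", "bwa", "bowtie2")
  )
  cov <- amplicon_coverage(reads, regions)
  # last_base starts at 1-based 200 = 0-based 199, the region's final base.
  expect_equal(cov$n_bwa, c(2L, 0L))
  expect_equal(cov$n_bowtie2, c(1L, 0L))

  # Brute-force overlap check over every read x region pair.
  spans <- vapply(seq_len(nrow(reads)), function(i) {
    varscreen::cigar_events(reads$cigar[i], reads$pos[i])$end
  }, integer(1))
  for (r in seq_len(nrow(regions))) {
    for (al in c("bwa", "bowtie2")) {
      manual <- sum(vapply(seq_len(nrow(reads)), function(i) {
        if (reads$aligner[i] != al) return(FALSE)
        bases_read <- seq(reads$pos[i], spans[i])
        bases_amp <- seq(regions$start[r] + 1L, regions$end[r])
        length(intersect(bases_read, bases_amp)) >= 1
      }, logical(1)))
      expect_equal(cov[[paste0("n_", al)]][r], manual)
    }
  }
})

test_that("sensitivity and specificity are computed and rounded as printed", {
  m <- confusion_metrics(tp = 25983, tn = 38974865, fp = 5863, fn = 2257)
  expect_equal(m$sensitivity_pct, 92.01)
  expect_equal(m$specificity_pct, 99.98)
  # Scale invariance.
  m10 <- confusion_metrics(tp = 259830, tn = 389748650, fp = 58630,
                           fn = 22570)
  expect_equal(m10$sensitivity_pct, m$sensitivity_pct)
  expect_equal(m10$specificity_pct, m$specificity_pct)
  # Zero denominators yield NA, not 0 or 100.
  expect_true(is.na(confusion_metrics(0, 10, 1, 0)$sensitivity_pct))
  expect_true(is.na(confusion_metrics(5, 0, 0, 1)$specificity_pct))
  expect_error(confusion_metrics(-1, 1, 1, 1), "non-negative")
})

test_that("mean confidence reproduces the printed weighted means", {
  expect_equal(mean_confidence(c(`1` = 0.31, `2` = 0.52, `3` = 1.95,
                                 `4` = 4.61, `5` = 2.56, `6` = 90.04)), 5.79)
  expect_equal(mean_confidence(c(`1` = 30.60, `2` = 34.55, `3` = 15.94,
                                 `4` = 7.64, `5` = 4.57, `6` = 6.69)), 2.41)
  expect_equal(mean_confidence(c(`6` = 100)), 6.00)
  expect_error(mean_confidence(tibble::tibble(score = 1, pct = 0)), "weight")
})

test_that("the report ranks by confidence then genomic order and conserves counts", {
  merged <- dplyr::bind_rows(
    tibble::tibble(chrom = "chr2", pos = 5L, ref = "A", alt = "G",
                   confidence = 3L),
    tibble::tibble(chrom = "chr1", pos = 9L, ref = "C", alt = "T",
                   confidence = 3L),
    tibble::tibble(chrom = "chr1", pos = 1L, ref = "G", alt = "GA",
                   confidence = 6L),
    tibble::tibble(chrom = "chr1", pos = 3L, ref = "TA", alt = "T",
                   confidence = 1L)
  )
  rep <- build_report(merged)
  expect_equal(rep$report$confidence, c(6L, 3L, 3L, 1L))
  expect_equal(rep$report$chrom[2:3], c("chr1", "chr2"))  # ties in genomic order
  expect_equal(sum(rep$per_score$n), nrow(merged))
  expect_equal(sum(rep$per_type$n), nrow(merged))
  expect_equal(rep$per_type$n[rep$per_type$type == "SNP"], 2L)

  empty <- build_report(merged[0, ])
  expect_equal(nrow(empty$report), 0)
  expect_equal(sum(empty$per_score$n), 0L)
})

test_that("annotation join populates the per-gene summary and drops orphans", {
  merged <- dplyr::bind_rows(
    tibble::tibble(chrom = "chr3", pos = c(10L, 20L, 30L), ref = "A",
                   alt = "G", confidence = 2L),
    tibble::tibble(chrom = "chr4", pos = c(10L, 20L, 30L), ref = "C",
                   alt = "T", confidence = 4L)
  )
  ann <- tibble::tibble(
    chrom = c(rep("chr3", 3), rep("chr4", 3), "chr9"),
    pos = c(10L, 20L, 30L, 10L, 20L, 30L, 99L),
    ref = c(rep("A", 3), rep("C", 3), "G"),
    alt = c(rep("G", 3), rep("T", 3), "C"),
    gene = c(rep("PIK3CA", 3), rep("KDR", 3), "GHOST")
  )
  expect_warning(rep <- build_report(merged, ann), "ignored")
  expect_equal(sort(rep$per_gene$gene), c("KDR", "PIK3CA"))
  expect_equal(rep$per_gene$n, c(3L, 3L))
  expect_equal(sum(rep$per_gene$n), nrow(merged))
  g <- glance(rep)
  expect_equal(g$n_genes, 2L)
})

test_that("report generation is deterministic", {
  merged <- merge_callsets(dplyr::bind_rows(
    calls_all_combos(pos = 10L), calls_all_combos(pos = 20L, alt = "C")
  ))
  r1 <- build_report(merged)
  r2 <- build_report(merged)
  expect_identical(r1$report, r2$report)
  expect_identical(r1$per_score, r2$per_score)
})
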