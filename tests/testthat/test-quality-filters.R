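test_that("region filter keeps exactly the calls inside half-open intervals", {
  regions <- tibble::tibble(chrom = "chr17", start = 7578000L,
                            end = 7578200L, name = "AMP1")
  calls <- dplyr::bind_rows(
    make_call(chrom = "chr17", pos = 7578001L),   # 0-based 7578000: first base
    make_call(chrom = "chr17", pos = 7578200L),   # 0-based 7578199: last base
    make_call(chrom = "chr17", pos = 7578201L),   # 0-based 7578200: outside
    make_call(chrom = "chr16", pos = 7578001L)    # wrong chromosome
  )
  kept <- filter_region(calls, regions)
  expect_equal(kept$pos, c(7578001L, 7578200L))
  expect_equal(unique(kept$chrom), "chr17")
  # No regions: everything is off-target.
  expect_equal(nrow(filter_region(calls, regions[0, ])), 0)
})

test_that("SNP filter expressions match as printed, with bwa-specific FS", {
  cfg <- snp_filter_config()
  v <- evaluate_snp_filters(make_call(mq0 = 5L, dp = 40L), cfg)
  expect_false(v$passed)
  expect_true("MQ0_RATIO" %in% v$reasons[[1]])

  v <- evaluate_snp_filters(make_call(dp = 4L), cfg)
  expect_true("LOW_DP" %in% v$reasons[[1]])
  expect_true(evaluate_snp_filters(make_call(dp = 5L), cfg)$passed)

  v <- evaluate_snp_filters(make_call(qual = 49.9), cfg)
  expect_true("LOW_QUAL" %in% v$reasons[[1]])
  v <- evaluate_snp_filters(make_call(qd = 0.69), cfg)
  expect_true("LOW_QD" %in% v$reasons[[1]])

  # FS = 100 passes under the bwa override (> 590 needed) but fails others.
  expect_true(evaluate_snp_filters(make_call(fs = 100, aligner = "bwa"), cfg)$passed)
  v <- evaluate_snp_filters(make_call(fs = 100, aligner = "bowtie2"), cfg)
  expect_equal(v$reasons[[1]], "HIGH_FS")
  v <- evaluate_snp_filters(make_call(fs = 591, aligner = "bwa"), cfg)
  expect_equal(v$reasons[[1]], "HIGH_FS")

  # MQ0 rule needs both conjuncts.
  expect_true(evaluate_snp_filters(make_call(mq0 = 3L, dp = 10L), cfg)$passed)
  expect_true(evaluate_snp_filters(make_call(mq0 = 5L, dp = 100L), cfg)$passed)

  expect_error(evaluate_snp_filters(make_call(ref = "CA", alt = "C")),
               "indel")
})

test_that("absent annotations fail their sub-expressions", {
  v <- evaluate_snp_filters(make_call(qd = NA_real_))
  expect_false(v$passed)
  expect_equal(v$reasons[[1]], "MISSING_QD")
  v <- evaluate_snp_filters(make_call(dp = NA_integer_))
  expect_true("MISSING_DP" %in% v$reasons[[1]])
  v <- evaluate_indel_filters(make_call(ref = "CA", alt = "C",
                                        read_pos_rank_sum = NA_real_))
  expect_equal(v$reasons[[1]], "MISSING_READPOSRANKSUM")
})

test_that("SNP verdicts are order-independent and deterministic", {
  set.seed(1)
  calls <- dplyr::bind_rows(lapply(1:30, function(i) {
    make_call(pos = 100L + i,
              aligner = sample(default_aligners(), 1),
              dp = sample(c(NA, 1:100), 1), qual = runif(1, 0, 200),
              qd = runif(1, 0, 5), fs = runif(1, 0, 700),
              mq0 = sample(0:10, 1))
  }))
  v1 <- evaluate_snp_filters(calls)
  perm <- sample(nrow(calls))
  v2 <- evaluate_snp_filters(calls[perm, ])
  expect_equal(v2$passed, v1$passed[perm])
  expect_equal(v2$reasons, v1$reasons[perm])
})

test_that("relaxing thresholds never shrinks the passing set", {
  set.seed(2)
  calls <- dplyr::bind_rows(lapply(1:50, function(i) {
    make_call(pos = 100L + i, dp = sample(1:20, 1), qual = runif(1, 0, 100),
              qd = runif(1, 0, 2), fs = runif(1, 0, 100))
  }))
  strict <- evaluate_snp_filters(calls, snp_filter_config())
  relaxed <- evaluate_snp_filters(
    calls, snp_filter_config(min_dp = 2L, min_qual = 10, min_qd = 0.1,
                             max_fs = 90)
  )
  expect_true(all(relaxed$passed[strict$passed]))
})

test_that("SNP-cluster flagging matches the all-subsets oracle", {
  # Printed examples: span 9 within window 10 flags all three.
  calls <- dplyr::bind_rows(lapply(c(100L, 104L, 109L), function(p) {
    make_call(pos = p)
  }))
  v <- flag_snp_clusters(calls)
  expect_equal(v$reasons, list("SNP_CLUSTER", "SNP_CLUSTER", "SNP_CLUSTER"))

  calls2 <- dplyr::bind_rows(lapply(c(100L, 104L, 120L), function(p) {
    make_call(pos = p)
  }))
  expect_true(all(flag_snp_clusters(calls2)$passed))
  expect_true(all(flag_snp_clusters(calls2[1, ])$passed))

  set.seed(3)
  for (i in 1:25) {
    n <- sample(2:50, 1)
    pos <- sort(sample(1:200, n))
    calls <- dplyr::bind_rows(lapply(pos, function(p) make_call(pos = p)))
    got <- !flag_snp_clusters(calls)$passed
    expect_equal(got, bf_cluster(pos), info = paste("case", i))
  }
})

test_that("indel filter expression fails on any disjunct", {
  indel <- function(...) make_call(ref = "CA", alt = "C", ...)
  expect_false(evaluate_indel_filters(indel(qd = 2.4))$passed)
  expect_true(evaluate_indel_filters(
    indel(qd = 10, read_pos_rank_sum = -1, fs = 10))$passed)
  expect_false(evaluate_indel_filters(indel(read_pos_rank_sum = -20.5))$passed)
  expect_false(evaluate_indel_filters(indel(fs = 200.1))$passed)
  expect_error(evaluate_indel_filters(make_call()), "SNP")
})

test_that("depth filter boundaries are inclusive at 2 and 4000", {
  verdict <- function(dp) evaluate_depth_filter(make_call(dp = dp,
                                                          caller = "samtools"))
  expect_false(verdict(1L)$passed)
  expect_true(verdict(2L)$passed)
  expect_true(verdict(500L)$passed)
  expect_true(verdict(4000L)$passed)
  expect_false(verdict(4001L)$passed)
  expect_equal(verdict(NA_integer_)$reasons[[1]], "MISSING_DP")
  expect_equal(verdict(4001L)$reasons[[1]], "DEPTH_RANGE")
})

test_that("union retention keeps keys unlabeled in at least one callset", {
  key <- list(chrom = "chr1", pos = 100L, ref = "A", alt = "G")
  labeled <- function(aligner, passed) {
    out <- make_call(pos = key$pos, aligner = aligner, caller = "gatk")
    out$reasons <- list(if (passed) character() else "LOW_QUAL")
    out$passed <- passed
    out
  }
  # Labeled by bwa and bowtie2 but clean in nextgenmap: retained.
  calls <- dplyr::bind_rows(labeled("bwa", FALSE), labeled("bowtie2", FALSE),
                            labeled("nextgenmap", TRUE))
  retained <- retain_union(calls)
  expect_equal(nrow(retained), 1)
  expect_equal(retained$pos, 100L)
  # Labeled everywhere: removed.
  calls_all <- dplyr::bind_rows(labeled("bwa", FALSE), labeled("bowtie2", FALSE),
                                labeled("nextgenmap", FALSE))
  expect_equal(nrow(retain_union(calls_all)), 0)
  # Empty input: empty set.
  expect_equal(nrow(retain_union(calls_all[0, ])), 0)
  # The rule is applied per caller group.
  mixed <- dplyr::bind_rows(
    calls_all,
    dplyr::mutate(labeled("bwa", TRUE), caller = "samtools")
  )
  retained <- retain_union(mixed)
  expect_equal(retained$caller, "samtools")
})

test_that("apply_quality_filters routes by caller style", {
  calls <- dplyr::bind_rows(
    make_call(pos = 100L, caller = "gatk", qd = 0.5),          # LOW_QD
    make_call(pos = 200L, caller = "samtools", dp = 1L),        # DEPTH_RANGE
    make_call(pos = 300L, ref = "CA", alt = "C", caller = "gatk", qd = 2.0),
    make_call(pos = 400L, caller = "samtools", dp = 1000L)      # passes
  )
  v <- apply_quality_filters(calls)
  expect_equal(v$passed, c(FALSE, FALSE, FALSE, TRUE))
  expect_true("LOW_QD" %in% v$reasons[[1]])
  expect_equal(v$reasons[[2]], "DEPTH_RANGE")
  expect_true("INDEL_EXPR" %in% v$reasons[[3]])
  expect_error(apply_quality_filters(dplyr::mutate(calls, caller = "other")),
               "style")
})
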