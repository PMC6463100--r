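del_site <- function(pos = 100L) {
  list(chrom = "chr1", pos = pos, ref = "AT", alt = "A")
}

read_row <- function(id, pos, cigar, aligner = "bwa") {
  tibble::tibble(read_id = id, chrom = "chr1", pos = as.integer(pos),
                 cigar = cigar, mapq = 60L, aligner = aligner)
}

test_that("event extraction collects signed lengths from covering reads", {
  # 10 reads each with a 1-bp deletion anchored at the site.
  reads <- dplyr::bind_rows(lapply(1:10, function(i) {
    # (20 - i) matched bases put the deletion anchor at 100 for every read.
    read_row(paste0("r", i), 101L - (20L - i), sprintf("%dM1D%dM", 20L - i, 30L))
  }))
  d <- extract_event_lengths(reads, del_site())
  expect_equal(d$lengths[[1]], rep(-1L, 10))
  expect_equal(d$n_covering, 10L)

  # A read ending before the anchor contributes nothing, not even coverage.
  short <- read_row("s", 50L, "30M")  # spans 50..79 < 100
  d <- extract_event_lengths(dplyr::bind_rows(reads, short), del_site())
  expect_equal(d$n_covering, 10L)

  # Insertion event: 50M1I49M starting at 51 puts the insertion anchor at 100.
  ins <- read_row("i", 51L, "50M1I49M")
  d <- extract_event_lengths(ins, list(chrom = "chr1", pos = 100L,
                                       ref = "A", alt = "AT"))
  expect_equal(d$lengths[[1]], 1L)
  # Cross-check with the independent pileup walk.
  expect_equal(bf_site_lengths(ins, 100L)$lengths, 1L)

  # Covering reads without a matched event count only toward n_covering.
  plain <- read_row("p", 80L, "50M")
  d <- extract_event_lengths(dplyr::bind_rows(reads, plain), del_site())
  expect_equal(length(d$lengths[[1]]), 10)
  expect_equal(d$n_covering, 11L)
})

test_that("homopolymer-run matching requires a reference and widens the net", {
  expect_error(extract_event_lengths(read_row("r", 90L, "30M"), del_site(),
                                     mode = "homopolymer_run"),
               "reference")
  # T-run at positions 101..106; events shifted within the run still count.
  ref <- c(chr1 = paste0(strrep("A", 100), strrep("T", 6), strrep("G", 20)))
  site <- list(chrom = "chr1", pos = 100L, ref = "AT", alt = "A")
  shifted <- read_row("r", 81L, "22M1D30M")  # deletion anchored at 102
  expect_equal(extract_event_lengths(shifted, site)$n_events, 0L)
  d <- extract_event_lengths(shifted, site, reference = ref,
                             mode = "homopolymer_run")
  expect_equal(d$lengths[[1]], -1L)
})

test_that("var and frmode match their printed worked values", {
  expect_equal(compute_var(rep(-1, 10)), 0.0)
  expect_equal(compute_var(c(-1, -1, -1, -2)), 0.1875)
  expect_equal(compute_var(c(1, -1)), 1.0)
  expect_equal(compute_frmode(rep(-1, 10)), 1.0)
  expect_equal(compute_frmode(c(-1, -1, -1, -2)), 0.75)
  expect_equal(compute_frmode(c(-1, -1, -2, -2)), 0.5)
  expect_error(compute_var(integer()), "NO_EVENTS")
  expect_error(compute_frmode(integer()), "NO_EVENTS")
})

test_that("var/frmode satisfy their joint invariants on random distributions", {
  set.seed(11)
  for (i in 1:200) {
    lengths <- sample(c(-3:-1, 1:3), sample(1:30, 1), replace = TRUE)
    v <- compute_var(lengths)
    f <- compute_frmode(lengths)
    expect_gte(v, 0)
    expect_gt(f, 0)
    expect_lte(f, 1)
    all_equal <- length(unique(lengths)) == 1
    expect_equal(v == 0, all_equal)
    expect_equal(f == 1, all_equal)
    # Agreement with direct-summation oracles.
    expect_equal(v, bf_var(lengths))
    expect_equal(f, bf_frmode(lengths))
  }
})

test_that("extraction and statistics agree with the brute-force pileup walk", {
  set.seed(13)
  ref <- simulate_reference(length = 300, runs = 8L, seed = 5)
  run <- ref$runs[1, ]
  site_pos <- run$start - 1L
  site <- list(chrom = "chr1", pos = site_pos,
               ref = paste0(substr(ref$reference, site_pos, site_pos),
                            run$base),
               alt = substr(ref$reference, site_pos, site_pos))
  for (i in 1:40) {
    reads <- simulate_pileup(ref$reference, site_pos = site_pos,
                             indel_len = sample(c(-2L, -1L, 1L), 1),
                             n_reads = sample(5:100, 1),
                             slippage_prob = runif(1, 0, 0.6),
                             read_length = 80L, seed = 1000L + i)
    got <- extract_event_lengths(reads, site)
    want <- bf_site_lengths(reads, site_pos)
    expect_equal(sort(got$lengths[[1]]), sort(want$lengths))
    expect_equal(got$n_covering, want$n_covering)
    if (length(want$lengths) > 0) {
      expect_equal(compute_var(got$lengths[[1]]), bf_var(want$lengths))
      expect_equal(compute_frmode(got$lengths[[1]]), bf_frmode(want$lengths))
    }
  }
})

test_that("calibration takes max TP var and min TP frmode, ignoring FPs", {
  training <- tibble::tibble(
    label = c("TP", "TP", "TP", "FP", "FP"),
    var = c(0.0, 0.031, 0.055, 1.2, 3.0),
    frmode = c(1.0, 0.995, 0.9790, 0.4, 0.2)
  )
  th <- calibrate_thresholds(training)
  expect_equal(th$max_var, 0.055)
  expect_equal(th$min_frmode, 0.9790)

  single <- calibrate_thresholds(tibble::tibble(label = "TP", var = 0.02,
                                                frmode = 0.99))
  expect_equal(single$max_var, 0.02)
  expect_equal(single$min_frmode, 0.99)

  degenerate <- calibrate_thresholds(
    tibble::tibble(label = rep("TP", 3), var = 0, frmode = 1)
  )
  expect_equal(degenerate$max_var, 0.0)
  expect_equal(degenerate$min_frmode, 1.0)

  expect_error(calibrate_thresholds(tibble::tibble(label = "FP", var = 1,
                                                   frmode = 0.5)),
               "TP")
})

test_that("rejection needs var AND frmode violated for the same aligner", {
  th <- hp_thresholds()  # maxVar = 0.055, minFrmode = 0.9790
  one <- function(var, frmode, aligner = "bwa") {
    tibble::tibble(aligner = aligner, var = var, frmode = frmode)
  }
  expect_true(decide_homopolymer(one(0.06, 0.97), th)$filtered)
  expect_false(decide_homopolymer(one(0.06, 0.99), th)$filtered)
  expect_false(decide_homopolymer(one(0.01, 0.90), th)$filtered)

  # Any-aligner rule: one violating aligner suffices.
  three <- dplyr::bind_rows(one(0.001, 1.0, "bwa"), one(0.02, 0.999, "bowtie2"),
                            one(0.10, 0.90, "nextgenmap"))
  v <- decide_homopolymer(three, th)
  expect_true(v$filtered)
  expect_equal(v$violating_aligners, "nextgenmap")

  # Cross-threshold violations split across aligners do not reject.
  split <- dplyr::bind_rows(one(0.10, 0.999, "bwa"), one(0.001, 0.90, "bowtie2"))
  expect_false(decide_homopolymer(split, th)$filtered)

  # Boundary values sit exactly on the thresholds: strict inequalities retain.
  expect_false(decide_homopolymer(one(0.055, 0.9790), th)$filtered)

  # Aligners without events are skipped; all-NA input is an error.
  with_na <- dplyr::bind_rows(one(NA_real_, NA_real_, "bwa"),
                              one(0.10, 0.90, "bowtie2"))
  expect_true(decide_homopolymer(with_na, th)$filtered)
  expect_error(decide_homopolymer(one(NA_real_, NA_real_), th), "aligner")
  expect_error(decide_homopolymer(one(0.1, 0.9)[0, ], th), "aligner")
})

test_that("decide is monotone in the thresholds", {
  set.seed(17)
  for (i in 1:50) {
    stats <- tibble::tibble(aligner = "bwa", var = runif(1, 0, 0.2),
                            frmode = runif(1, 0.5, 1))
    base <- decide_homopolymer(stats, hp_thresholds(0.055, 0.9790))$filtered
    looser <- decide_homopolymer(stats, hp_thresholds(0.1, 0.9))$filtered
    expect_true(!base || base >= looser)
    if (!base) expect_false(looser)
  }
})

test_that("self-calibrated thresholds never reject a training TP", {
  set.seed(19)
  for (i in 1:30) {
    n_tp <- sample(1:30, 1)
    n_fp <- sample(0:50, 1)
    training <- tibble::tibble(
      label = c(rep("TP", n_tp), rep("FP", n_fp)),
      var = abs(stats::rnorm(n_tp + n_fp, 0.1, 0.2)),
      frmode = runif(n_tp + n_fp, 0.3, 1)
    )
    th <- calibrate_thresholds(training)
    tp <- training[training$label == "TP", ]
    rejected <- vapply(seq_len(nrow(tp)), function(j) {
      decide_homopolymer(tibble::tibble(aligner = "bwa", var = tp$var[j],
                                        frmode = tp$frmode[j]), th)$filtered
    }, logical(1))
    expect_false(any(rejected))
  }
})

test_that("filter_homopolymer labels rejected sites and reports statistics", {
  ref <- simulate_reference(length = 300, runs = 8L, seed = 23)
  run <- ref$runs[1, ]
  site_pos <- run$start - 1L
  anchor <- substr(ref$reference, site_pos, site_pos)
  calls <- dplyr::bind_rows(
    make_call(pos = site_pos, ref = paste0(anchor, run$base), alt = anchor),
    make_call(pos = 50L)  # a SNP, untouched by this stage
  )
  noisy <- simulate_pileup(ref$reference, site_pos = site_pos,
                           indel_len = -1L, n_reads = 60L,
                           slippage_prob = 0.5, seed = 29, aligner = "bwa")
  res <- filter_homopolymer(calls, noisy)
  expect_true(res$calls$hp_filtered[1])
  expect_false(res$calls$hp_filtered[2])
  expect_equal(res$site_stats$aligner, "bwa")
  expect_gt(res$site_stats$var, 0.055)

  clean <- simulate_pileup(ref$reference, site_pos = site_pos,
                           indel_len = -1L, n_reads = 60L,
                           slippage_prob = 0, seed = 29, aligner = "bwa")
  res <- filter_homopolymer(calls, clean)
  expect_false(any(res$calls$hp_filtered))
  expect_equal(res$site_stats$var, 0)
  expect_equal(res$site_stats$frmode, 1)
})
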