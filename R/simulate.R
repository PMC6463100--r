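# Deterministic generators emulating the statistical structure the filter
# cascade assumes: homopolymer slippage in reads, per-combination dropout in
# callsets, and labeled training indels for threshold calibration. All
# randomness is seeded locally so the caller's RNG state is untouched.

with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Simulate a reference snippet containing homopolymer runs
#'
#' Builds a random sequence in which homopolymer runs of the requested
#' lengths are embedded at known positions - the substrate for simulating
#' slippage-prone pileups.
#'
#' @param length Total sequence length (bp).
#' @param runs Integer vector of homopolymer run lengths to embed, spaced
#'   evenly through the sequence.
#' @param seed Integer seed; fixes all randomness.
#' @param chrom Contig name.
#' @return A list with `reference` (named character vector) and `runs`
#'   (tibble of `chrom`, `start`, `end`, `base` for each embedded run,
#'   1-based inclusive).
#' @export
#' @examples
#' simulate_reference(length = 200, runs = c(8, 6), seed = 1)$runs
simulate_reference <- function(length = 600L, runs = c(8L, 10L, 6L),
                               seed = 1L, chrom = "chr1") {
  stopifnot(length >= 50, all(runs >= 2))
  with_local_seed(seed, {
    seq <- sample(c("A", "C", "G", "T"), length, replace = TRUE)
    # Break accidental long runs so the embedded runs are the only ones.
    for (i in seq(2, length)) {
      if (seq[i] == seq[i - 1] && i > 2 && seq[i] == seq[i - 2]) {
        seq[i] <- sample(setdiff(c("A", "C", "G", "T"), seq[i - 1]), 1)
      }
    }
    anchors <- floor(seq_len(length(runs)) * length / (length(runs) + 1))
    run_rows <- purrr::map2(anchors, runs, function(at, rl) {
      base <- sample(c("A", "C", "G", "T"), 1)
      seq[at:(at + rl - 1)] <<- base
      # Guard bases so the run does not extend.
      if (at > 1 && seq[at - 1] == base) {
        seq[at - 1] <<- sample(setdiff(c("A", "C", "G", "T"), base), 1)
      }
      if (at + rl <= length && seq[at + rl] == base) {
        seq[at + rl] <<- sample(setdiff(c("A", "C", "G", "T"), base), 1)
      }
      tibble(chrom = chrom, start = at, end = at + rl - 1L, base = base)
    })
    list(
      reference = setNames(paste(seq, collapse = ""), chrom),
      runs = bind_rows(run_rows)
    )
  })
}

#' Simulate a pileup of reads over a candidate indel site
#'
#' Generates single-end reads covering a site, each showing the true indel
#' event (if any) with its length perturbed by +/-1 with probability
#' `slippage_prob` - the dominant flow-based sequencing error mode, where
#' a homopolymer run is read one base too long or too short. A perturbed
#' length is never 0 (that would silently erase the event); when a draw
#' would cancel the event, the magnitude is pushed one further instead.
#' With `slippage_prob = 0` every covering read shows exactly the true
#' length, so `var = 0` and `frmode = 1` by construction.
#'
#' @param reference Named character vector with one contig (or a list as
#'   returned by [simulate_reference()]).
#' @param site_pos 1-based anchor position of the true indel, or `NULL`
#'   for an event-free pileup.
#' @param indel_len Signed true event length (`+` insertion, `-`
#'   deletion); ignored when `site_pos` is `NULL`.
#' @param n_reads Number of reads.
#' @param slippage_prob Per-read probability the event length is
#'   perturbed.
#' @param read_length Read length in bases (query length).
#' @param seed Integer seed.
#' @param aligner Value for the `aligner` column.
#' @return A read tibble (`read_id`, `chrom`, `pos`, `cigar`, `mapq`,
#'   `seq`, `aligner`) suitable for [write_sam()] and
#'   [extract_event_lengths()].
#' @export
simulate_pileup <- function(reference, site_pos = NULL, indel_len = -1L,
                            n_reads = 50L, slippage_prob = 0,
                            read_length = 100L, seed = 1L,
                            aligner = "sim") {
  if (is.list(reference) && !is.null(reference$reference)) {
    reference <- reference$reference
  }
  stopifnot(is.character(reference), length(reference) == 1,
            !is.null(names(reference)),
            n_reads >= 1, slippage_prob >= 0, slippage_prob <= 1)
  chrom <- names(reference)
  seq <- strsplit(toupper(reference[[1]]), "")[[1]]
  ref_len <- length(seq)
  if (!is.null(site_pos)) {
    stopifnot(indel_len != 0)
    if (site_pos < 1 || site_pos + abs(indel_len) + 1 > ref_len) {
      abort("indel site lies outside the reference snippet")
    }
  }
  with_local_seed(seed, {
    rows <- purrr::map(seq_len(n_reads), function(i) {
      if (is.null(site_pos)) {
        start <- sample.int(max(1L, ref_len - read_length + 1L), 1)
        rl <- min(read_length, ref_len - start + 1L)
        return(tibble(
          read_id = sprintf("r%04d", i), chrom = chrom,
          pos = as.integer(start), cigar = sprintf("%dM", rl), mapq = 60L,
          seq = paste(seq[start:(start + rl - 1)], collapse = ""),
          aligner = aligner
        ))
      }
      len <- as.integer(indel_len)
      if (slippage_prob > 0 && runif(1) < slippage_prob) {
        delta <- sample(c(-1L, 1L), 1)
        len2 <- len + delta
        if (len2 == 0L) len2 <- len - delta
        len <- len2
      }
      # Choose how many matched bases precede the anchor so the event sits
      # strictly inside the read.
      pad <- max(abs(len), 1L) + 2L
      a_max <- read_length - pad - 1L
      a <- sample(seq.int(2L, max(2L, a_max)), 1)
      start <- site_pos - a + 1L
      if (start < 1L) {
        a <- a + start - 1L
        start <- 1L
      }
      if (len < 0) {
        d <- -len
        b <- read_length - a
        b <- min(b, ref_len - (site_pos + d))
        cigar <- sprintf("%dM%dD%dM", a, d, b)
        bases <- c(seq[start:site_pos],
                   seq[(site_pos + d + 1):(site_pos + d + b)])
      } else {
        ins <- min(len, read_length - a - 1L)
        b <- read_length - a - ins
        b <- min(b, ref_len - site_pos)
        cigar <- sprintf("%dM%dI%dM", a, ins, b)
        bases <- c(seq[start:site_pos],
                   rep(seq[min(site_pos + 1L, ref_len)], ins),
                   seq[(site_pos + 1L):(site_pos + b)])
      }
      tibble(
        read_id = sprintf("r%04d", i), chrom = chrom,
        pos = as.integer(start), cigar = cigar, mapq = 60L,
        seq = paste(bases, collapse = ""), aligner = aligner
      )
    })
    bind_rows(rows)
  })
}

#' Simulate callsets for a set of true variants
#'
#' Each true variant enters each (aligner, caller) combination's callset
#' independently with probability `1 - dropout_prob`, carrying healthy
#' annotation values drawn uniformly from the configured ranges. With
#' `dropout_prob = 0` every merged variant reaches the maximum confidence
#' score.
#'
#' @param true_variants A tibble with `chrom`, `pos`, `ref`, `alt`.
#' @param combos A [combo_table()]; must be non-empty.
#' @param dropout_prob Scalar, or named vector keyed by combo id, of
#'   per-combination dropout probabilities.
#' @param seed Integer seed.
#' @param ranges Named list of `c(min, max)` annotation ranges for `dp`,
#'   `qual`, `qd`, `fs`, `read_pos_rank_sum` (`mq0` is fixed at 0).
#' @return A call tibble covering all combinations.
#' @export
simulate_callsets <- function(true_variants, combos = combo_table(),
                              dropout_prob = 0, seed = 1L,
                              ranges = list(dp = c(200, 1500),
                                            qual = c(100, 4000),
                                            qd = c(5, 25),
                                            fs = c(0, 30),
                                            read_pos_rank_sum = c(-3, 3))) {
  assert_calls(true_variants)
  if (nrow(combos) == 0) abort("simulate_callsets() needs at least one combination")
  if (is.null(names(dropout_prob))) {
    dropout <- setNames(rep(dropout_prob[1], nrow(combos)), combos$combo)
  } else {
    missing <- setdiff(combos$combo, names(dropout_prob))
    if (length(missing) > 0) {
      abort(paste0("dropout_prob missing combos: ", paste(missing, collapse = ", ")))
    }
    dropout <- dropout_prob[combos$combo]
  }
  stopifnot(all(dropout >= 0), all(dropout <= 1))
  with_local_seed(seed, {
    rows <- purrr::map(seq_len(nrow(combos)), function(ci) {
      keep <- runif(nrow(true_variants)) >= dropout[[combos$combo[ci]]]
      kept <- as_tibble(true_variants)[keep, c("chrom", "pos", "ref", "alt")]
      if (nrow(kept) == 0) return(NULL)
      n <- nrow(kept)
      dplyr::mutate(
        kept,
        aligner = combos$aligner[ci],
        caller = combos$caller[ci],
        qual = round(runif(n, ranges$qual[1], ranges$qual[2]), 2),
        dp = as.integer(round(runif(n, ranges$dp[1], ranges$dp[2]))),
        qd = round(runif(n, ranges$qd[1], ranges$qd[2]), 2),
        fs = round(runif(n, ranges$fs[1], ranges$fs[2]), 2),
        mq0 = 0L,
        read_pos_rank_sum = round(runif(n, ranges$read_pos_rank_sum[1],
                                        ranges$read_pos_rank_sum[2]), 3),
        filter = NA_character_
      )
    })
    out <- bind_rows(purrr::compact(rows))
    if (nrow(out) == 0) {
      out <- tibble(chrom = character(), pos = integer(), ref = character(),
                    alt = character(), aligner = character(),
                    caller = character(), qual = double(), dp = integer(),
                    qd = double(), fs = double(), mq0 = integer(),
                    read_pos_rank_sum = double(), filter = character())
    }
    out
  })
}

#' Simulate a labeled training-indel table
#'
#' Emulates a Sanger-labeled training cohort for threshold calibration:
#' TP entries are drawn from low-dispersion pileups (slippage at most
#' `tp_noise`), FP entries from high-dispersion pileups (slippage around
#' `fp_noise`). The default cohort shape is 18 TP and 90 FP entries.
#'
#' @param n_tp,n_fp Entry counts (`n_tp >= 1`).
#' @param tp_noise,fp_noise Slippage probabilities for the two classes.
#' @param n_reads Reads per simulated pileup.
#' @param seed Integer seed.
#' @return A tibble with `chrom`, `pos`, `ref`, `alt`, `label`, `var`,
#'   `frmode`, one row per training indel.
#' @export
simulate_training_set <- function(n_tp = 18L, n_fp = 90L,
                                  tp_noise = 0.02, fp_noise = 0.35,
                                  n_reads = 40L, seed = 1L) {
  stopifnot(n_tp >= 1, n_fp >= 0)
  with_local_seed(seed, {
    entry_seeds <- sample.int(.Machine$integer.max, n_tp + n_fp)
    labels <- c(rep("TP", n_tp), rep("FP", n_fp))
    rows <- purrr::map(seq_along(labels), function(i) {
      noise <- if (labels[i] == "TP") tp_noise else fp_noise
      rs <- simulate_reference(length = 200L, runs = 7L,
                               seed = entry_seeds[i],
                               chrom = sprintf("trn%03d", i))
      run <- rs$runs[1, ]
      site_pos <- run$start - 1L  # anchor just before the run
      len <- sample(c(-1L, 1L), 1)
      reads <- simulate_pileup(rs$reference, site_pos = site_pos,
                               indel_len = len, n_reads = n_reads,
                               slippage_prob = noise, read_length = 80L,
                               seed = entry_seeds[i])
      lengths <- extract_event_lengths(
        reads,
        site = list(chrom = run$chrom, pos = site_pos,
                    ref = if (len < 0) {
                      paste0(substr_base(rs$reference, site_pos),
                             strrep(run$base, -len))
                    } else substr_base(rs$reference, site_pos),
                    alt = if (len < 0) substr_base(rs$reference, site_pos)
                          else paste0(substr_base(rs$reference, site_pos),
                                      strrep(run$base, len))),
        reference = rs$reference, mode = "homopolymer_run"
      )$lengths[[1]]
      tibble(
        chrom = run$chrom, pos = site_pos,
        ref = if (len < 0) paste0(substr_base(rs$reference, site_pos),
                                  strrep(run$base, -len))
              else substr_base(rs$reference, site_pos),
        alt = if (len < 0) substr_base(rs$reference, site_pos)
              else paste0(substr_base(rs$reference, site_pos),
                          strrep(run$base, len)),
        label = labels[i],
        var = compute_var(lengths),
        frmode = compute_frmode(lengths)
      )
    })
    bind_rows(rows)
  })
}

substr_base <- function(reference, pos) {
  substr(reference[[1]], pos, pos)
}

#' Simulate a complete toy run directory
#'
#' Emits every input the pipeline consumes, in standard on-disk formats:
#' a reference FASTA with a homopolymer run, a BED of amplicons, one SAM
#' per aligner, one VCF per (aligner, caller) combination, and a labeled
#' training TSV - so the full command-line path is exercisable without any
#' external data. True variants are a set of SNPs plus one deletion inside
#' the homopolymer run.
#'
#' @param dir Output directory (created if needed).
#' @param n_snps Number of true SNPs.
#' @param dropout_prob Per-combination callset dropout.
#' @param slippage_prob Read-level slippage noise at the true indel site.
#' @param n_reads Reads per aligner.
#' @param seed Integer seed.
#' @param combos A [combo_table()].
#' @return A list describing the run: `dir`, `reference_path`, `bed_path`,
#'   `vcf` (tibble path/aligner/caller), `sam` (tibble path/aligner),
#'   `training_path`, `truth` (tibble of true variants), `reference`.
#' @export
simulate_run <- function(dir, n_snps = 4L, dropout_prob = 0,
                         slippage_prob = 0, n_reads = 60L, seed = 1L,
                         combos = combo_table()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  with_local_seed(seed, {
    sub_seeds <- sample.int(.Machine$integer.max, 8 + 2 * nrow(combos))
    rs <- simulate_reference(length = 600L, runs = c(8L, 6L),
                             seed = sub_seeds[1], chrom = "chr1")
    ref_len <- nchar(rs$reference[[1]])
    regions <- tibble(
      chrom = "chr1",
      start = c(39L, 299L),
      end = c(300L, 560L),
      name = c("AMP1", "AMP2")
    )
    run <- rs$runs[1, ]
    indel_pos <- run$start - 1L
    # True SNPs at fixed offsets inside the amplicons, away from the runs.
    snp_pos <- sort(sample(setdiff(seq(60L, 540L, by = 1L),
                                   seq(run$start - 5L, run$end + 5L)),
                           n_snps))
    seqchars <- strsplit(rs$reference[[1]], "")[[1]]
    snps <- tibble(
      chrom = "chr1", pos = snp_pos,
      ref = seqchars[snp_pos],
      alt = vapply(seqchars[snp_pos],
                   function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                   character(1))
    )
    indel <- tibble(
      chrom = "chr1", pos = indel_pos,
      ref = paste0(seqchars[indel_pos], run$base),
      alt = seqchars[indel_pos]
    )
    truth <- arrange_genomic(bind_rows(snps, indel))
    truth <- normalize_variants(truth, rs$reference)

    reference_path <- file.path(dir, "reference.fa")
    write_reference(rs$reference, reference_path)
    bed_path <- file.path(dir, "amplicons.bed")
    write_regions(regions, bed_path)

    sam <- purrr::map(seq_along(unique(combos$aligner)), function(i) {
      al <- unique(combos$aligner)[i]
      reads <- simulate_pileup(rs$reference, site_pos = indel_pos,
                               indel_len = -1L, n_reads = n_reads,
                               slippage_prob = slippage_prob,
                               read_length = 100L,
                               seed = sub_seeds[8 + i], aligner = al)
      # Event-free background reads tiling the rest of the panel.
      bg <- simulate_pileup(rs$reference, site_pos = NULL,
                            n_reads = n_reads, read_length = 100L,
                            seed = sub_seeds[8 + nrow(combos) + i],
                            aligner = al)
      bg$read_id <- paste0("b", bg$read_id)
      reads <- bind_rows(reads, bg)
      path <- file.path(dir, paste0("reads_", al, ".sam"))
      write_sam(reads, path, contigs = setNames(ref_len, "chr1"))
      tibble(path = path, aligner = al)
    })
    sam <- bind_rows(sam)

    calls <- simulate_callsets(truth, combos = combos,
                               dropout_prob = dropout_prob,
                               seed = sub_seeds[2])
    vcf <- purrr::map(seq_len(nrow(combos)), function(ci) {
      sub <- dplyr::filter(calls, .data$aligner == combos$aligner[ci],
                           .data$caller == combos$caller[ci])
      path <- file.path(dir, paste0("calls_", combos$combo[ci], ".vcf"))
      write_vcf_calls(arrange_genomic(sub), path,
                      contigs = setNames(ref_len, "chr1"))
      tibble(path = path, aligner = combos$aligner[ci],
             caller = combos$caller[ci])
    })
    vcf <- bind_rows(vcf)

    training <- simulate_training_set(seed = sub_seeds[4])
    training_path <- file.path(dir, "training_indels.tsv")
    utils::write.table(training, training_path, sep = "\t", row.names = FALSE,
                       quote = FALSE)

    list(dir = dir, reference_path = reference_path, bed_path = bed_path,
         vcf = vcf, sam = sam, training_path = training_path,
         truth = truth, reference = rs$reference, regions = regions)
  })
}
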