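# Fixture builders and independent brute-force oracles. The oracles share no
# code with the implementation paths they check.

make_call <- function(chrom = "chr1", pos = 100L, ref = "A", alt = "G",
                      aligner = "bwa", caller = "gatk",
                      qual = 1000, dp = 500L, qd = 10, fs = 5, mq0 = 0L,
                      read_pos_rank_sum = 0, filter = NA_character_) {
  tibble::tibble(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
                 aligner = aligner, caller = caller, qual = qual,
                 dp = dp, qd = qd, fs = fs, mq0 = mq0,
                 read_pos_rank_sum = read_pos_rank_sum, filter = filter)
}

# Healthy call replicated across every combination of the default 3x2 grid.
calls_all_combos <- function(chrom = "chr1", pos = 100L, ref = "A", alt = "G") {
  combos <- combo_table()
  dplyr::bind_rows(lapply(seq_len(nrow(combos)), function(i) {
    make_call(chrom, pos, ref, alt,
              aligner = combos$aligner[i], caller = combos$caller[i])
  }))
}

# Brute-force SNP-cluster oracle: a position is flagged iff some subset of
# cluster_size positions containing it spans <= window bp. Enumerates all
# subsets via combn, unlike the sliding-window implementation.
bf_cluster <- function(positions, window = 10L, size = 3L) {
  flagged <- rep(FALSE, length(positions))
  if (length(positions) >= size) {
    for (grp in utils::combn(seq_along(positions), size, simplify = FALSE)) {
      if (diff(range(positions[grp])) <= window) flagged[grp] <- TRUE
    }
  }
  flagged
}

# Independent CIGAR pileup walk: returns signed lengths of events whose
# anchor (preceding reference base) equals site_pos, plus covering-read
# count. Parses the CIGAR with a different mechanism (gsub splitting).
bf_site_lengths <- function(reads, site_pos) {
  lengths <- integer()
  n_cov <- 0L
  for (i in seq_len(nrow(reads))) {
    toks <- strsplit(gsub("([MIDS])", "\\1 ", reads$cigar[i]), " ")[[1]]
    ref_at <- reads$pos[i]
    events <- list()
    for (tok in toks) {
      op <- substr(tok, nchar(tok), nchar(tok))
      len <- as.integer(substr(tok, 1, nchar(tok) - 1))
      if (op == "M") {
        ref_at <- ref_at + len
      } else if (op == "D") {
        events[[length(events) + 1]] <- c(ref_at - 1L, -len)
        ref_at <- ref_at + len
      } else if (op == "I") {
        events[[length(events) + 1]] <- c(ref_at - 1L, len)
      }
    }
    span_end <- ref_at - 1L
    if (reads$pos[i] <= site_pos && site_pos <= span_end) {
      n_cov <- n_cov + 1L
      for (ev in events) {
        if (ev[1] == site_pos) lengths <- c(lengths, ev[2])
      }
    }
  }
  list(lengths = lengths, n_covering = n_cov)
}

# Direct-summation variance and mode-frequency oracles.
bf_var <- function(x) {
  m <- sum(x) / length(x)
  sum((x - m)^2) / length(x)
}
bf_frmode <- function(x) {
  counts <- vapply(unique(x), function(u) sum(x == u), integer(1))
  max(counts) / length(x)
}

# Exhaustive minimal-representation oracle for allele trimming (no
# left-alignment): tries every legal amount of suffix then prefix trimming
# and returns the shortest representation keeping an indel anchor.
bf_trim <- function(pos, ref, alt) {
  best <- NULL
  r <- strsplit(ref, "")[[1]]
  a <- strsplit(alt, "")[[1]]
  max_suf <- 0
  while (max_suf < min(length(r), length(a)) - 1 &&
         r[length(r) - max_suf] == a[length(a) - max_suf]) {
    max_suf <- max_suf + 1
  }
  for (suf in max_suf) {
    r2 <- r[seq_len(length(r) - suf)]
    a2 <- a[seq_len(length(a) - suf)]
    pre <- 0
    while (pre < min(length(r2), length(a2)) - 1 && r2[pre + 1] == a2[pre + 1]) {
      pre <- pre + 1
    }
    best <- list(pos = pos + pre,
                 ref = paste(r2[(pre + 1):length(r2)], collapse = ""),
                 alt = paste(a2[(pre + 1):length(a2)], collapse = ""))
  }
  best
}

# All equivalent placements of deleting `del_len` bases from a homopolymer
# run, as raw VCF-style keys (anchor base + deleted bases).
run_deletion_placements <- function(seq, run_start, run_end, del_len = 1L) {
  lapply(run_start:(run_end - del_len + 1L), function(s) {
    chars <- strsplit(seq, "")[[1]]
    tibble::tibble(
      chrom = "chr1", pos = s - 1L,
      ref = paste(chars[(s - 1L):(s + del_len - 1L)], collapse = ""),
      alt = chars[s - 1L]
    )
  })
}
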