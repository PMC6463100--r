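#' Parse CIGAR strings into indel events
#'
#' Walks a CIGAR string from a read's 1-based leftmost aligned position and
#' returns the insertion/deletion events it encodes. Each event is anchored
#' at the reference base immediately preceding it (the VCF anchor
#' convention), with signed length: `+len` for insertions, `-len` for
#' deletions. `M` and `D` consume reference; `I` and `S` do not.
#'
#' @param cigar A CIGAR string over operations M, I, D, S.
#' @param pos 1-based leftmost aligned reference position.
#' @return A list with `end` (last aligned reference position) and
#'   `events`, a tibble with columns `anchor` and `length`.
#' @export
#' @examples
#' cigar_events("50M1I49M", 1000L)
cigar_events <- function(cigar, pos) {
  ops <- stringr::str_match_all(cigar, "(\\d+)([MIDSHNP=X])")[[1]]
  if (nrow(ops) == 0 || paste0(ops[, 2], ops[, 3], collapse = "") != cigar) {
    abort(paste0("unparsable CIGAR: ", cigar))
  }
  lens <- as.integer(ops[, 2])
  chars <- ops[, 3]
  if (any(!chars %in% c("M", "I", "D", "S", "=", "X"))) {
    abort(paste0("unsupported CIGAR operation in: ", cigar))
  }
  r <- as.integer(pos)
  anchors <- integer()
  lengths <- integer()
  for (i in seq_along(chars)) {
    op <- chars[i]
    len <- lens[i]
    if (op %in% c("M", "=", "X")) {
      r <- r + len
    } else if (op == "I") {
      anchors <- c(anchors, r - 1L)
      lengths <- c(lengths, len)
    } else if (op == "D") {
      anchors <- c(anchors, r - 1L)
      lengths <- c(lengths, -len)
      r <- r + len
    }
    # S consumes neither reference nor event.
  }
  list(end = r - 1L, events = tibble(anchor = anchors, length = lengths))
}

#' Per-site indel event-length distribution
#'
#' Collects, from every read covering a candidate indel site, the signed
#' length of the indel event the read shows there. A read covers the site
#' when its aligned reference span includes the anchor position. In
#' `mode = "exact"` an event is matched to the site when its anchor equals
#' the site's normalized position; in `mode = "homopolymer_run"` (which
#' requires `reference`) any event anchored inside the homopolymer run
#' containing the site counts, since flow-based sequencers place slipped
#' events anywhere in the run. A covering read with no matched event
#' contributes nothing to `lengths` but still counts in `n_covering`.
#'
#' @param reads A read tibble ([read_alignments()]); if it carries an
#'   `aligner` column the distribution is computed per aligner.
#' @param site A one-row data frame (or list) with `chrom`, `pos`, `ref`,
#'   `alt` of a normalized INS or DEL.
#' @param reference Optional named character vector of chromosome
#'   sequences (required for `mode = "homopolymer_run"`).
#' @param mode Event-to-site matching mode.
#' @return A tibble with one row per aligner: `aligner`, `lengths`
#'   (list-column of signed integer event lengths), `n_events`,
#'   `n_covering`.
#' @export
extract_event_lengths <- function(reads, site, reference = NULL,
                                  mode = c("exact", "homopolymer_run")) {
  mode <- match.arg(mode)
  assert_calls(reads, c("chrom", "pos", "cigar"))
  site <- as.list(site)
  stopifnot(!is.null(site$chrom), !is.null(site$pos))
  type <- as.character(variant_type(site$ref, site$alt))
  if (!type %in% c("INS", "DEL")) {
    abort("extract_event_lengths() expects a normalized INS or DEL site")
  }
  ref_seqs <- as_reference(reference)
  if (mode == "homopolymer_run" && is.null(ref_seqs)) {
    abort("mode = \"homopolymer_run\" requires a reference sequence")
  }
  run <- NULL
  if (mode == "homopolymer_run") {
    run <- homopolymer_run(ref_seqs, site$chrom, as.integer(site$pos), type)
  }
  aligner <- if ("aligner" %in% names(reads)) reads$aligner
             else rep("all", nrow(reads))
  groups <- unique(aligner)
  rows <- purrr::map(groups, function(al) {
    sub <- as_tibble(reads)[aligner == al & reads$chrom == site$chrom, ]
    lengths <- integer()
    n_cov <- 0L
    for (i in seq_len(nrow(sub))) {
      ce <- cigar_events(sub$cigar[i], sub$pos[i])
      if (sub$pos[i] > site$pos || ce$end < site$pos) next  # does not cover
      n_cov <- n_cov + 1L
      ev <- ce$events
      if (nrow(ev) == 0) next
      if (mode == "exact") {
        hit <- ev$anchor == site$pos
      } else {
        # Anchor of an event inside the run lies in [run_start - 1, run_end].
        hit <- ev$anchor >= run$start - 1L & ev$anchor <= run$end
      }
      lengths <- c(lengths, ev$length[hit])
    }
    n_ev <- length(lengths)
    tibble(aligner = al, lengths = list(lengths),
           n_events = n_ev, n_covering = n_cov)
  })
  bind_rows(rows)
}

# Maximal run of identical reference bases containing the first base the
# event touches (pos + 1 for a deletion; the base adjacent to the anchor
# for an insertion).
homopolymer_run <- function(ref_seqs, chrom, pos, type) {
  if (!chrom %in% names(ref_seqs)) {
    abort(paste0("reference has no sequence for ", chrom))
  }
  seq <- strsplit(ref_seqs[[chrom]], "")[[1]]
  focus <- min(pos + 1L, length(seq))
  base <- seq[focus]
  start <- focus
  while (start > 1 && seq[start - 1] == base) start <- start - 1L
  end <- focus
  while (end < length(seq) && seq[end + 1] == base) end <- end + 1L
  list(start = start, end = end, base = base)
}

#' Variance of indel event lengths at a site
#'
#' The population variance (divide by *n*) of the signed event lengths, in
#' bp squared. High values indicate reads disagreeing about the event -
#' the signature of homopolymer slippage errors; 0 means every read shows
#' the identical event.
#'
#' @param lengths Signed integer event lengths (insertions positive,
#'   deletions negative), one per indel-bearing read.
#' @return Non-negative numeric scalar.
#' @export
#' @examples
#' compute_var(c(-1, -1, -1, -2))  # 0.1875
compute_var <- function(lengths) {
  if (length(lengths) == 0) abort("NO_EVENTS: empty length distribution")
  if (any(lengths == 0)) abort("event lengths must be non-zero")
  mean((lengths - mean(lengths))^2)
}

#' Frequency of the modal indel event length at a site
#'
#' The fraction of indel-bearing reads carrying the most common event
#' length, in (0, 1]. Robust to single outlier reads that inflate the
#' variance; 1 means perfect agreement. Under a mode tie the tied modes
#' share the same count, so the value is well defined.
#'
#' @inheritParams compute_var
#' @return Numeric scalar in (0, 1].
#' @export
#' @examples
#' compute_frmode(c(-1, -1, -1, -2))  # 0.75
compute_frmode <- function(lengths) {
  if (length(lengths) == 0) abort("NO_EVENTS: empty length distribution")
  if (any(lengths == 0)) abort("event lengths must be non-zero")
  max(table(lengths)) / length(lengths)
}

#' Per-aligner var/frmode statistics for one candidate site
#'
#' Convenience wrapper: extracts the event-length distribution per aligner
#' and summarises it. Aligners whose reads show no event at the site get
#' `NA` statistics (and are skipped by [decide_homopolymer()]).
#'
#' @inheritParams extract_event_lengths
#' @return A tibble with columns `aligner`, `var`, `frmode`, `n_events`,
#'   `n_covering`.
#' @export
indel_site_stats <- function(reads, site, reference = NULL,
                             mode = c("exact", "homopolymer_run")) {
  d <- extract_event_lengths(reads, site, reference, mode)
  dplyr::mutate(
    d,
    var = purrr::map_dbl(.data$lengths,
                         ~ if (length(.x) == 0) NA_real_ else compute_var(.x)),
    frmode = purrr::map_dbl(.data$lengths,
                            ~ if (length(.x) == 0) NA_real_ else compute_frmode(.x)),
    lengths = NULL
  )
}

#' Homopolymer filter thresholds
#'
#' Constructs a thresholds object. The defaults are the values calibrated
#' on 108 Sanger-labeled training indels from homopolymer regions (18 true
#' positives, 90 false positives): `max_var` is the largest `var` observed
#' among the true positives and `min_frmode` the smallest `frmode`, so by
#' construction no true positive violates both.
#'
#' @param max_var Maximum tolerated event-length variance (bp^2).
#' @param min_frmode Minimum tolerated modal-length frequency.
#' @param training Optional training tibble the thresholds were calibrated
#'   from (stored for [generics::tidy()] / [ggplot2::autoplot()]).
#' @return An object of class `hp_thresholds`.
#' @export
#' @examples
#' hp_thresholds()
hp_thresholds <- function(max_var = 0.055, min_frmode = 0.9790,
                          training = NULL) {
  stopifnot(max_var >= 0, min_frmode > 0, min_frmode <= 1)
  structure(
    list(max_var = max_var, min_frmode = min_frmode, training = training),
    class = "hp_thresholds"
  )
}

#' @export
print.hp_thresholds <- function(x, ...) {
  cat("Homopolymer indel filter thresholds\n")
  cat(sprintf("  max_var:    %g bp^2\n", x$max_var))
  cat(sprintf("  min_frmode: %g\n", x$min_frmode))
  if (!is.null(x$training)) {
    cat(sprintf("  calibrated from %d training indels (%d TP, %d FP)\n",
                nrow(x$training), sum(x$training$label == "TP"),
                sum(x$training$label == "FP")))
  }
  invisible(x)
}

#' Tidy a thresholds object into its training table
#'
#' One row per training indel with a `rejected` column: whether the
#' calibrated thresholds would filter it (strict `var > max_var` and
#' `frmode < min_frmode`). By construction no TP entry is rejected by
#' thresholds calibrated on the same table.
#'
#' @param x An [hp_thresholds()] object with a training table attached.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.hp_thresholds <- function(x, ...) {
  if (is.null(x$training)) {
    abort("no training table attached to these thresholds")
  }
  dplyr::mutate(
    as_tibble(x$training),
    rejected = .data$var > x$max_var & .data$frmode < x$min_frmode
  )
}

#' One-row summary of calibrated thresholds
#'
#' Reports the thresholds together with the filtering they achieve on the
#' attached training table: TP retention (always 100% for self-calibrated
#' thresholds) and the share of FP entries rejected.
#'
#' @param x An [hp_thresholds()] object.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.hp_thresholds <- function(x, ...) {
  out <- tibble(max_var = x$max_var, min_frmode = x$min_frmode,
                n_tp = NA_integer_, n_fp = NA_integer_,
                tp_retained_pct = NA_real_, fp_removed_pct = NA_real_)
  if (!is.null(x$training)) {
    td <- tidy(x)
    tp <- td[td$label == "TP", ]
    fp <- td[td$label == "FP", ]
    out$n_tp <- nrow(tp)
    out$n_fp <- nrow(fp)
    out$tp_retained_pct <- if (nrow(tp) > 0) {
      round_half_up(100 * mean(!tp$rejected))
    } else NA_real_
    out$fp_removed_pct <- if (nrow(fp) > 0) {
      round_half_up(100 * mean(fp$rejected))
    } else NA_real_
  }
  out
}

#' Calibrate homopolymer thresholds from labeled training indels
#'
#' Given indel calls labeled `TP`/`FP` by an orthogonal method (Sanger
#' sequencing in the original calibration), sets `max_var` to the maximum
#' `var` among TP entries and `min_frmode` to the minimum `frmode` among
#' TP entries. FP entries play no part in the formula - they only quantify
#' the filtering the calibrated thresholds achieve (see
#' [glance.hp_thresholds()]). The resulting thresholds are guaranteed to
#' retain every training TP.
#'
#' @param training A tibble with columns `label` (`"TP"`/`"FP"`), `var`
#'   and `frmode`, one row per training indel.
#' @return An [hp_thresholds()] object with the training table attached.
#' @export
#' @examples
#' tr <- tibble::tibble(label = c("TP", "TP", "FP"),
#'                      var = c(0.0, 0.03, 0.8),
#'                      frmode = c(1.0, 0.99, 0.55))
#' calibrate_thresholds(tr)
calibrate_thresholds <- function(training) {
  assert_calls(training, c("label", "var", "frmode"))
  if (!all(training$label %in% c("TP", "FP"))) {
    abort("training labels must be \"TP\" or \"FP\"")
  }
  tp <- training[training$label == "TP", ]
  if (nrow(tp) == 0) abort("calibration requires at least one TP training indel")
  if (any(is.na(tp$var)) || any(is.na(tp$frmode))) {
    abort("TP training entries must have var and frmode values")
  }
  hp_thresholds(max_var = max(tp$var), min_frmode = min(tp$frmode),
                training = as_tibble(training))
}

#' Decide whether a candidate indel is a homopolymer artifact
#'
#' A site is filtered out when, for at least one aligner,
#' `var > max_var` **and** `frmode < min_frmode` - both strict, both for
#' the same aligner. This any-aligner rule is deliberately conservative:
#' an artifact visible in only one aligner's pileup is still an artifact.
#' Aligners with no events at the site (`NA` statistics) are skipped.
#'
#' @param stats A tibble with columns `aligner`, `var`, `frmode`, e.g.
#'   from [indel_site_stats()].
#' @param thresholds An [hp_thresholds()] object.
#' @return A one-row tibble with `filtered` (logical) and
#'   `violating_aligners` (comma-separated names, `""` when retained).
#' @export
#' @examples
#' decide_homopolymer(
#'   tibble::tibble(aligner = "bwa", var = 0.06, frmode = 0.97)
#' )
decide_homopolymer <- function(stats, thresholds = hp_thresholds()) {
  assert_calls(stats, c("aligner", "var", "frmode"))
  stopifnot(inherits(thresholds, "hp_thresholds"))
  usable <- dplyr::filter(as_tibble(stats),
                          !is.na(.data$var), !is.na(.data$frmode))
  if (nrow(stats) == 0 || nrow(usable) == 0) {
    abort("decide_homopolymer() needs statistics from at least one aligner")
  }
  viol <- usable$var > thresholds$max_var & usable$frmode < thresholds$min_frmode
  tibble(
    filtered = any(viol),
    violating_aligners = paste(usable$aligner[viol], collapse = ",")
  )
}

#' Apply the homopolymer filter to candidate indel calls
#'
#' For every distinct indel key among `calls`, computes per-aligner
#' var/frmode from the supplied alignments and applies
#' [decide_homopolymer()]. SNP/MNP calls pass through untouched. Calls at
#' rejected sites receive the `HP_INDEL` label; per-aligner statistics are
#' returned alongside for reporting (`VAR_<aligner>` / `FRMODE_<aligner>`
#' style annotation).
#'
#' @param calls A normalized call tibble (any mixture of types).
#' @param reads A read tibble covering all aligners, with an `aligner`
#'   column.
#' @param thresholds An [hp_thresholds()] object.
#' @inheritParams extract_event_lengths
#' @return A list with `calls` (input plus logical `hp_filtered` and
#'   character `hp_violating` columns) and `site_stats` (per site x
#'   aligner var/frmode table).
#' @export
filter_homopolymer <- function(calls, reads, thresholds = hp_thresholds(),
                               reference = NULL,
                               mode = c("exact", "homopolymer_run")) {
  mode <- match.arg(mode)
  assert_calls(calls)
  out <- as_tibble(calls)
  types <- variant_type(out$ref, out$alt)
  out$hp_filtered <- FALSE
  out$hp_violating <- ""
  sites <- dplyr::distinct(out[types %in% c("INS", "DEL"), ],
                           .data$chrom, .data$pos, .data$ref, .data$alt)
  all_stats <- list()
  for (i in seq_len(nrow(sites))) {
    site <- sites[i, ]
    stats <- indel_site_stats(reads, site, reference, mode)
    stats <- dplyr::mutate(stats, chrom = site$chrom, pos = site$pos,
                           ref = site$ref, alt = site$alt, .before = 1)
    all_stats[[i]] <- stats
    usable <- stats[!is.na(stats$var) & !is.na(stats$frmode), ]
    if (nrow(usable) == 0) next  # no events anywhere: nothing to judge
    verdict <- decide_homopolymer(usable, thresholds)
    hit <- out$chrom == site$chrom & out$pos == site$pos &
      out$ref == site$ref & out$alt == site$alt
    out$hp_filtered[hit] <- verdict$filtered
    out$hp_violating[hit] <- verdict$violating_aligners
  }
  list(
    calls = out,
    site_stats = if (length(all_stats) > 0) bind_rows(all_stats) else
      tibble(chrom = character(), pos = integer(), ref = character(),
             alt = character(), aligner = character(), n_events = integer(),
             n_covering = integer(), var = double(), frmode = double())
  )
}
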