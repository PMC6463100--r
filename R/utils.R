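# Internal helpers shared across stages.

# Round half away from zero on the percent scale; base round() is
# round-half-even, which would print 92.005 as 92.00.
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Canonical "chrom:pos:ref:alt" id used for joins and set operations.
variant_id <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

assert_calls <- function(calls, cols = c("chrom", "pos", "ref", "alt")) {
  if (!is.data.frame(calls)) {
    abort("`calls` must be a data frame of variant calls.")
  }
  missing <- setdiff(cols, names(calls))
  if (length(missing) > 0) {
    abort(paste0("`calls` is missing required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  invisible(calls)
}

check_allele <- function(x, what) {
  bad <- is.na(x) | !grepl("^[ACGTN]+$", x)
  if (any(bad)) {
    abort(paste0("invalid ", what, " allele(s): ",
                 paste(unique(x[bad]), collapse = ", "),
                 " (alleles must be non-empty, uppercase over {A,C,G,T,N})"))
  }
  invisible(x)
}

# Natural ordering for chrom/pos used everywhere output order matters.
arrange_genomic <- function(df) {
  dplyr::arrange(df, .data$chrom, .data$pos, .data$ref, .data$alt)
}
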