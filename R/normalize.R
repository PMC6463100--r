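#' Normalize variant representations
#'
#' Callers represent the same indel in different ways (padding bases,
#' right-shifted placement inside repeats). Merging callsets on exact
#' (chrom, pos, ref, alt) identity therefore requires every call to be in a
#' canonical form first: shared trailing bases are trimmed, then shared
#' leading bases are trimmed while keeping at least one anchor base for
#' indels, and - when reference sequence is supplied - indels are shifted
#' to their leftmost equivalent position. The operation is idempotent.
#'
#' @param calls A data frame with at least `chrom`, `pos` (1-based anchor
#'   position), `ref`, `alt`. Other columns pass through untouched.
#' @param reference Optional named character vector (or
#'   [Biostrings::DNAStringSet]) of chromosome sequences starting at
#'   position 1, used to left-align indels. Without it, trimming alone is
#'   performed.
#' @return The input tibble with `pos`, `ref`, `alt` replaced by their
#'   normalized values.
#' @export
#' @examples
#' calls <- tibble::tibble(chrom = "chr1", pos = 100L, ref = "AC", alt = "GC")
#' normalize_variants(calls)
normalize_variants <- function(calls, reference = NULL) {
  assert_calls(calls)
  if (nrow(calls) == 0) return(as_tibble(calls))
  check_allele(calls$ref, "ref")
  check_allele(calls$alt, "alt")
  if (any(calls$pos < 1)) abort("variant positions must be >= 1")
  if (any(calls$ref == calls$alt)) {
    abort("ref and alt alleles are identical: not a variant")
  }
  ref_seqs <- as_reference(reference)
  norm <- purrr::pmap(
    list(calls$chrom, calls$pos, calls$ref, calls$alt),
    function(chrom, pos, ref, alt) {
      normalize_one(chrom, pos, ref, alt, ref_seqs)
    }
  )
  out <- as_tibble(calls)
  out$pos <- vapply(norm, `[[`, integer(1), "pos")
  out$ref <- vapply(norm, `[[`, character(1), "ref")
  out$alt <- vapply(norm, `[[`, character(1), "alt")
  out
}

# Accepts NULL, named character vector, or DNAStringSet.
as_reference <- function(reference) {
  if (is.null(reference)) return(NULL)
  if (methods::is(reference, "DNAStringSet")) {
    return(setNames(as.character(reference), names(reference)))
  }
  if (is.character(reference) && !is.null(names(reference))) {
    return(toupper(reference))
  }
  abort("`reference` must be a named character vector or DNAStringSet")
}

normalize_one <- function(chrom, pos, ref, alt, ref_seqs = NULL) {
  r <- strsplit(ref, "")[[1]]
  a <- strsplit(alt, "")[[1]]
  seq <- NULL
  if (!is.null(ref_seqs) && chrom %in% names(ref_seqs)) {
    seq <- strsplit(ref_seqs[[chrom]], "")[[1]]
  }
  # Trim shared trailing bases; with reference context, prepending the
  # preceding reference base whenever an allele would empty walks the event
  # to its leftmost equivalent placement before trimming continues.
  while (r[length(r)] == a[length(a)]) {
    if (length(r) == 1 || length(a) == 1) {
      if (is.null(seq) || pos <= 1) break
      prev <- seq[pos - 1]
      r <- c(prev, r)
      a <- c(prev, a)
      pos <- pos - 1L
    }
    r <- r[-length(r)]
    a <- a[-length(a)]
  }
  # Trim shared leading bases, keeping >= 1 anchor base for indels.
  while (length(r) > 1 && length(a) > 1 && r[1] == a[1]) {
    r <- r[-1]
    a <- a[-1]
    pos <- pos + 1L
  }
  ref2 <- paste(r, collapse = "")
  alt2 <- paste(a, collapse = "")
  if (ref2 == alt2) {
    abort(sprintf("%s:%d %s>%s reduces to no change: not a variant",
                  chrom, pos, ref, alt))
  }
  list(pos = as.integer(pos), ref = ref2, alt = alt2)
}

#' Classify variants by allele shape
#'
#' A normalized variant is a `SNP` when both alleles are single bases,
#' an `INS`/`DEL` when one allele extends the other with a shared anchor
#' prefix, an `MNP` when both alleles have equal length > 1, and
#' `COMPLEX` otherwise.
#'
#' @param calls A data frame with `ref` and `alt` columns (normalized).
#' @return The input with a `type` factor column added (levels SNP, INS,
#'   DEL, MNP, COMPLEX).
#' @export
#' @examples
#' tibble::tibble(chrom = "chr1", pos = 1L,
#'                ref = c("A", "C", "CA"), alt = c("G", "CT", "C")) |>
#'   classify_variants()
classify_variants <- function(calls) {
  assert_calls(calls, c("ref", "alt"))
  out <- as_tibble(calls)
  out$type <- variant_type(out$ref, out$alt)
  out
}

#' @rdname classify_variants
#' @param ref,alt Allele character vectors (for the vector interface).
#' @export
variant_type <- function(ref, alt) {
  nr <- nchar(ref)
  na <- nchar(alt)
  type <- dplyr::case_when(
    nr == 1 & na == 1 ~ "SNP",
    na > nr & startsWith(alt, ref) ~ "INS",
    nr > na & startsWith(ref, alt) ~ "DEL",
    nr == na ~ "MNP",
    TRUE ~ "COMPLEX"
  )
  factor(type, levels = c("SNP", "INS", "DEL", "MNP", "COMPLEX"))
}
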