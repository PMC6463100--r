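#' Read a BED file of target regions
#'
#' Amplicon panels ship a BED file listing the targeted regions. BED is
#' 0-based half-open; those semantics are preserved in the returned table
#' (conversion to 1-based happens only where a comparison against VCF
#' coordinates is made).
#'
#' @param path Path to a BED file with >= 3 tab-separated columns
#'   (chrom, start, end, and optionally a region name).
#' @return A tibble with columns `chrom` (character), `start`, `end`
#'   (0-based half-open integers) and `name` (character, `NA` when the
#'   file has no fourth column), one row per data line in file order.
#' @export
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines("chr17\t7578000\t7578200\tAMP1", bed)
#' read_regions(bed)
read_regions <- function(path) {
  if (!file.exists(path)) abort(paste0("BED file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  # Drop headers/comments and blank lines but keep line numbers for errors.
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  rows <- purrr::map2(lines[keep], which(keep), function(line, lineno) {
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) {
      abort(sprintf("%s line %d: expected >= 3 tab-separated columns", path, lineno))
    }
    start <- suppressWarnings(as.integer(f[2]))
    end <- suppressWarnings(as.integer(f[3]))
    if (is.na(start) || is.na(end)) {
      abort(sprintf("%s line %d: non-integer coordinates '%s'/'%s'",
                    path, lineno, f[2], f[3]))
    }
    if (start < 0 || start >= end) {
      abort(sprintf("%s line %d: invalid interval [%d, %d)", path, lineno, start, end))
    }
    if (!nzchar(f[1])) {
      abort(sprintf("%s line %d: empty chromosome name", path, lineno))
    }
    tibble(chrom = f[1], start = start, end = end,
           name = if (length(f) >= 4) f[4] else NA_character_)
  })
  if (length(rows) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  name = character()))
  }
  bind_rows(rows)
}

#' Write target regions to a BED file
#'
#' @param regions A tibble as returned by [read_regions()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regions <- function(regions, path) {
  assert_calls(regions, c("chrom", "start", "end"))
  name <- if ("name" %in% names(regions)) regions$name else
    rep(NA_character_, nrow(regions))
  lines <- ifelse(
    is.na(name),
    sprintf("%s\t%d\t%d", regions$chrom, regions$start, regions$end),
    sprintf("%s\t%d\t%d\t%s", regions$chrom, regions$start, regions$end, name)
  )
  writeLines(lines, path)
  invisible(path)
}

# INFO fields carried through VCF I/O, in canonical order.
info_fields <- function() {
  c(dp = "DP", qd = "QD", fs = "FS", mq0 = "MQ0",
    read_pos_rank_sum = "ReadPosRankSum")
}

#' Read a VCF callset
#'
#' Reads one caller's VCF into the flat call table the filter stages
#' operate on. Multi-allelic records are split into one row per alternate
#' allele before any downstream normalization, so per-combination support
#' counting is well defined. Missing annotations are `NA`, never sentinel
#' numbers; the quality-expression filters treat them as failing.
#'
#' @param path Path to a VCF 4.x file (plain or gzipped).
#' @param aligner,caller Names of the (aligner, caller) combination that
#'   produced this callset.
#' @return A tibble with columns `chrom`, `pos`, `ref`, `alt`, `aligner`,
#'   `caller`, `qual`, `dp`, `qd`, `fs`, `mq0`, `read_pos_rank_sum` and
#'   `filter` (character; `NA` for unlabeled/PASS records).
#' @export
read_vcf_calls <- function(path, aligner, caller) {
  if (!file.exists(path)) abort(paste0("VCF file not found: ", path))
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  empty <- tibble(
    chrom = character(), pos = integer(), ref = character(), alt = character(),
    aligner = character(), caller = character(), qual = double(),
    dp = integer(), qd = double(), fs = double(), mq0 = integer(),
    read_pos_rank_sum = double(), filter = character()
  )
  if (nrow(fix) == 0) return(empty)
  info <- vcfR::extract_info_tidy(
    vcf,
    info_fields = unname(info_fields()),
    info_types = c(DP = "i", QD = "n", FS = "n", MQ0 = "i",
                   ReadPosRankSum = "n")
  )
  out <- tibble(
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = toupper(fix$REF),
    alt = toupper(fix$ALT),
    aligner = aligner,
    caller = caller,
    qual = suppressWarnings(as.numeric(fix$QUAL)),
    dp = pick_info(info, "DP", nrow(fix), integer(1)),
    qd = pick_info(info, "QD", nrow(fix), double(1)),
    fs = pick_info(info, "FS", nrow(fix), double(1)),
    mq0 = pick_info(info, "MQ0", nrow(fix), integer(1)),
    read_pos_rank_sum = pick_info(info, "ReadPosRankSum", nrow(fix), double(1)),
    filter = ifelse(is.na(fix$FILTER) | fix$FILTER %in% c(".", "PASS"),
                    NA_character_, fix$FILTER)
  )
  # Split multi-allelic records: one row per alternate allele.
  out <- tidyr::separate_rows(out, "alt", sep = ",")
  dplyr::filter(out, .data$alt != "*")
}

pick_info <- function(info, field, n, proto) {
  int <- is.integer(proto)
  if (!field %in% names(info)) {
    return(if (int) rep(NA_integer_, n) else rep(NA_real_, n))
  }
  v <- info[[field]]
  if (int) as.integer(v) else as.numeric(v)
}

#' Write a call table to a VCF file
#'
#' Emits a minimal VCF 4.2 file with the annotations the filter stages
#' consume (`DP`, `QD`, `FS`, `MQ0`, `ReadPosRankSum` as INFO; `QUAL`;
#' filter labels in `FILTER`). Output is plain text and byte-stable for
#' identical input, so pipeline runs are reproducible and diffable.
#'
#' @param calls A call tibble (see [read_vcf_calls()]); an optional
#'   `filter` column supplies FILTER labels and optional `conf` / `combos`
#'   columns are written as `CONF` / `COMBOS` INFO tags.
#' @param path Output path (plain `.vcf`).
#' @param contigs Optional named integer vector of contig lengths for the
#'   header.
#' @return `path`, invisibly.
#' @export
write_vcf_calls <- function(calls, path, contigs = NULL) {
  assert_calls(calls)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=varscreen",
    if (!is.null(contigs)) {
      sprintf("##contig=<ID=%s,length=%d>", names(contigs), as.integer(contigs))
    },
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Quality by depth\">",
    "##INFO=<ID=FS,Number=1,Type=Float,Description=\"Fisher strand bias (phred)\">",
    "##INFO=<ID=MQ0,Number=1,Type=Integer,Description=\"Mapping quality zero read count\">",
    "##INFO=<ID=ReadPosRankSum,Number=1,Type=Float,Description=\"Read position rank-sum\">",
    "##INFO=<ID=CONF,Number=1,Type=Integer,Description=\"Confidence score: number of supporting aligner-caller combinations\">",
    "##INFO=<ID=COMBOS,Number=.,Type=String,Description=\"Supporting aligner_caller combinations\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  fmt_num <- function(x) {
    ifelse(is.na(x), NA_character_,
           sub("\\.?0+$", "", sprintf("%.4f", x)))
  }
  n <- nrow(calls)
  col <- function(nm, default = rep(NA, n)) {
    if (nm %in% names(calls)) calls[[nm]] else default
  }
  dp <- col("dp"); qd <- col("qd"); fs <- col("fs"); mq0 <- col("mq0")
  rprs <- col("read_pos_rank_sum")
  conf <- col("conf", NULL); combos <- col("combos", NULL)
  info_parts <- list(
    DP = if (!all(is.na(dp))) ifelse(is.na(dp), NA, sprintf("DP=%d", as.integer(dp))),
    QD = if (!all(is.na(qd))) ifelse(is.na(qd), NA, paste0("QD=", fmt_num(qd))),
    FS = if (!all(is.na(fs))) ifelse(is.na(fs), NA, paste0("FS=", fmt_num(fs))),
    MQ0 = if (!all(is.na(mq0))) ifelse(is.na(mq0), NA, sprintf("MQ0=%d", as.integer(mq0))),
    RPRS = if (!all(is.na(rprs))) {
      ifelse(is.na(rprs), NA, paste0("ReadPosRankSum=", fmt_num(rprs)))
    },
    CONF = if (!is.null(conf)) sprintf("CONF=%d", as.integer(conf)),
    COMBOS = if (!is.null(combos)) paste0("COMBOS=", combos)
  )
  info_parts <- Filter(Negate(is.null), info_parts)
  info <- if (length(info_parts) == 0 || n == 0) {
    rep(".", n)
  } else {
    apply(do.call(cbind, info_parts), 1, function(row) {
      row <- row[!is.na(row)]
      if (length(row) == 0) "." else paste(row, collapse = ";")
    })
  }
  qual <- col("qual")
  filt <- col("filter", rep(NA_character_, n))
  body <- sprintf(
    "%s\t%d\t.\t%s\t%s\t%s\t%s\t%s",
    calls$chrom, calls$pos, calls$ref, calls$alt,
    ifelse(is.na(qual), ".", fmt_num(qual)),
    ifelse(is.na(filt), "PASS", filt),
    info
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read aligned reads from a SAM or BAM file
#'
#' Extracts the minimal per-read fields the homopolymer filter and the
#' coverage table need: id, chromosome, 1-based leftmost position, CIGAR
#' and mapping quality. SAM input is converted through [Rsamtools::asBam()]
#' before scanning; unmapped reads are dropped.
#'
#' @param path Path to a SAM or BAM file (SAM must carry `@SQ` header lines).
#' @param aligner Name of the aligner that produced the file.
#' @return A tibble with columns `read_id`, `chrom`, `pos`, `cigar`,
#'   `mapq`, `aligner`.
#' @export
read_alignments <- function(path, aligner) {
  if (!file.exists(path)) abort(paste0("alignment file not found: ", path))
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, destination = dest,
                            overwrite = TRUE, indexDestination = FALSE)
  }
  res <- Rsamtools::scanBam(
    bam,
    param = Rsamtools::ScanBamParam(
      what = c("qname", "rname", "pos", "cigar", "mapq"),
      flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)
    )
  )[[1]]
  tibble(
    read_id = res$qname,
    chrom = as.character(res$rname),
    pos = as.integer(res$pos),
    cigar = res$cigar,
    mapq = as.integer(res$mapq),
    aligner = aligner
  )
}

#' Write reads as a SAM file
#'
#' Companion writer for the read simulator: emits a valid single-end SAM
#' with `@SQ` lines so the file round-trips through standard tooling.
#'
#' @param reads A tibble with `read_id`, `chrom`, `pos`, `cigar`, `mapq`
#'   and `seq` columns.
#' @param path Output path (`.sam`).
#' @param contigs Named integer vector of contig lengths.
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, path, contigs) {
  assert_calls(reads, c("read_id", "chrom", "pos", "cigar", "mapq"))
  header <- c(
    "@HD\tVN:1.6\tSO:unsorted",
    sprintf("@SQ\tSN:%s\tLN:%d", names(contigs), as.integer(contigs))
  )
  seq <- if ("seq" %in% names(reads)) reads$seq else rep("*", nrow(reads))
  body <- sprintf(
    "%s\t0\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*",
    reads$read_id, reads$chrom, reads$pos, reads$mapq, reads$cigar, seq
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read / write reference sequences
#'
#' Thin FASTA wrappers returning plain named character vectors, the
#' reference representation used throughout the package.
#'
#' @param path FASTA path.
#' @return `read_reference()`: a named character vector of uppercase
#'   sequences. `write_reference()`: `path`, invisibly.
#' @export
read_reference <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(seqs))
  # FASTA headers may carry descriptions; keep the first word as the name.
  names(out) <- sub("\\s.*$", "", names(out))
  out
}

#' @rdname read_reference
#' @param reference Named character vector of sequences.
#' @export
write_reference <- function(reference, path) {
  stopifnot(is.character(reference), !is.null(names(reference)))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(reference), path
  )
  invisible(path)
}
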