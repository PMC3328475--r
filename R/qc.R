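#' Read a FASTQ file into a read table
#'
#' @param path FASTQ path (4-line records).
#' @param offset Quality encoding offset: 33 (Phred+33, default) or 64 for
#'   the legacy Illumina dialect.
#' @return A data.frame with columns `read_id`, `sequence`, `quality`
#'   (quality re-encoded to Phred+33 when `offset = 64`).
#' @export
read_fastq <- function(path, offset = 33L) {
  if (!file.exists(path)) stop("cannot read FASTQ file: ", path, call. = FALSE)
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  qual <- as.character(S4Vectors::mcols(x)$qualities)
  if (offset == 64L) {
    qual <- vapply(qual, function(q) {
      intToUtf8(utf8ToInt(q) - 31L)
    }, character(1), USE.NAMES = FALSE)
  } else if (offset != 33L) {
    stop("offset must be 33 or 64", call. = FALSE)
  }
  data.frame(read_id = sub("\\s.*$", "", names(x)),
             sequence = unname(as.character(x)), quality = unname(qual),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write a read table as FASTQ (Phred+33)
#'
#' @param reads A data.frame with `read_id`, `sequence`, `quality`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  check_reads(reads)
  x <- Biostrings::DNAStringSet(reads$sequence)
  names(x) <- reads$read_id
  Biostrings::writeXStringSet(
    x, path, format = "fastq",
    qualities = Biostrings::BStringSet(reads$quality))
  invisible(path)
}

check_reads <- function(reads) {
  stopifnot(is.data.frame(reads),
            all(c("read_id", "sequence", "quality") %in% names(reads)))
  if (nrow(reads) && !all(nchar(reads$sequence) == nchar(reads$quality)))
    stop("sequence and quality lengths differ", call. = FALSE)
  invisible(reads)
}

phred_means <- function(quality) {
  if (length(quality) == 0L) return(numeric())
  ql <- methods::as(Biostrings::PhredQuality(quality), "IntegerList")
  BiocGenerics::mean(ql)
}

#' Restriction-tag read filter
#'
#' Keeps exactly the reads whose sequence begins with the enzyme's residual
#' tag (e.g. `CT` for AluI): reads from properly ligated restriction
#' fragments carry it, so reads without it are library artefacts. Matching
#' is exact and case-insensitive; an `N` in the tag positions fails.
#'
#' @param reads A read data.frame (see [read_fastq()]).
#' @param enz The library [enzyme()]; its residual tag must be non-empty
#'   and unambiguous.
#' @return A list with `reads` (kept rows) and `counts`
#'   (`total`, `pass`, `fail`).
#' @export
tag_filter <- function(reads, enz) {
  check_reads(reads)
  stopifnot(inherits(enz, "enzyme"))
  tag <- residual_tag(enz)
  if (!nzchar(tag))
    stop("tag filter undefined for this enzyme: empty residual tag",
         call. = FALSE)
  if (grepl("[^ACGT]", tag))
    stop("tag filter undefined for this enzyme: degenerate residual tag",
         call. = FALSE)
  keep <- startsWith(toupper(reads$sequence), tag)
  list(reads = reads[keep, , drop = FALSE],
       counts = c(total = nrow(reads), pass = sum(keep),
                  fail = sum(!keep)))
}

#' Mean-base-quality read filter
#'
#' Keeps reads whose arithmetic mean Phred score over all positions is at
#' least `min_mean_q` (inclusive).
#'
#' @param reads A read data.frame.
#' @param min_mean_q Minimum mean Phred score (default 25).
#' @return A list with `reads` and `counts` (`total`, `pass`, `fail`).
#' @export
quality_filter <- function(reads, min_mean_q = 25) {
  check_reads(reads)
  keep <- if (nrow(reads) == 0L) logical() else
    phred_means(reads$quality) >= min_mean_q
  list(reads = reads[keep, , drop = FALSE],
       counts = c(total = nrow(reads), pass = sum(keep),
                  fail = sum(!keep)))
}

#' Two-stage read cleaning with full accounting
#'
#' Applies the residual-tag filter, then the mean-quality filter, and
#' reports counts at each stage in the style of a library-summary table.
#'
#' @param reads A read data.frame.
#' @param enz The library [enzyme()].
#' @param min_mean_q Minimum mean Phred score (default 25).
#' @param library_name Label used in the report (default `"library"`).
#' @return A list with `reads` (surviving reads) and `report`, a one-row
#'   data.frame: `library`, `total`, `tag_present`, `tag_present_pct`,
#'   `pass_qc`, `pass_qc_pct`.
#' @export
run_qc <- function(reads, enz, min_mean_q = 25, library_name = "library") {
  tf <- tag_filter(reads, enz)
  qf <- quality_filter(tf$reads, min_mean_q)
  total <- nrow(reads)
  report <- data.frame(
    library = library_name,
    total = total,
    tag_present = unname(tf$counts["pass"]),
    tag_present_pct = 100 * unname(tf$counts["pass"]) / max(1L, total),
    pass_qc = unname(qf$counts["pass"]),
    pass_qc_pct = 100 * unname(qf$counts["pass"]) / max(1L, total),
    stringsAsFactors = FALSE)
  list(reads = qf$reads, report = report)
}

#' Write a QC report TSV
#'
#' @param report A data.frame of one or more [run_qc()] report rows.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
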