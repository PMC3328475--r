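#' In silico restriction digestion of a sequence
#'
#' Cuts a DNA sequence at every occurrence of the enzyme's recognition site,
#' at `match_start + cut_offset`. Digestion is complete: every site is cut,
#' including sites arising from overlapping occurrences. Sites are matched
#' on the forward strand; all shipped enzymes have palindromic sites, for
#' which forward-strand search equals double-strand recognition (a warning
#' is raised for non-palindromic sites). `N` in the sequence never matches.
#'
#' @param sequence A DNA string (character scalar or
#'   [Biostrings::DNAString]) over `A,C,G,T,N`.
#' @param enz An [enzyme()].
#' @param chrom Optional sequence name recorded in the output.
#' @param with_sequence Keep fragment sequences in the output (set `FALSE`
#'   for genome-scale enzyme surveys where only lengths matter).
#' @return A data.frame of fragments in genomic order with columns `chrom`,
#'   `start` (0-based inclusive), `end` (0-based exclusive), `length` and,
#'   unless suppressed, `sequence`. Fragments tile the input without gap or
#'   overlap; an empty input yields zero rows.
#' @examples
#' digest("AGCTAGCT", enzyme("AluI", "AGCT", 2))$sequence  # "AG" "CTAG" "CT"
#' @export
digest <- function(sequence, enz, chrom = NA_character_,
                   with_sequence = TRUE) {
  stopifnot(inherits(enz, "enzyme"))
  if (!site_is_palindromic(enz))
    warning("recognition site of ", enz$name,
            " is not palindromic; forward-strand search only", call. = FALSE)
  subj <- if (is(sequence, "DNAString")) sequence else {
    s <- toupper(as.character(sequence))
    if (!nzchar(s)) {
      return(empty_fragments(with_sequence))
    }
    if (!grepl("^[ACGTN]+$", s))
      stop("sequence must be over A,C,G,T,N", call. = FALSE)
    Biostrings::DNAString(s)
  }
  n <- length(subj)
  if (n == 0L) return(empty_fragments(with_sequence))
  cuts <- site_cut_positions(subj, enz)
  bounds <- c(0L, cuts, n)
  starts <- bounds[-length(bounds)]
  ends <- bounds[-1L]
  out <- data.frame(
    chrom = rep(chrom, length(starts)),
    start = starts, end = ends, length = ends - starts,
    stringsAsFactors = FALSE
  )
  if (with_sequence)
    out$sequence <- as.character(Biostrings::Views(subj, starts + 1L, ends))
  out
}

empty_fragments <- function(with_sequence = TRUE) {
  out <- data.frame(chrom = character(), start = integer(), end = integer(),
                    length = integer(), stringsAsFactors = FALSE)
  if (with_sequence) out$sequence <- character()
  out
}

# 0-based cut positions strictly inside (0, length(subj)), sorted, unique.
site_cut_positions <- function(subj, enz) {
  fixed <- if (site_is_degenerate(enz)) "subject" else TRUE
  m <- Biostrings::matchPattern(
    Biostrings::DNAString(enz$recognition_site), subj, fixed = fixed)
  cuts <- BiocGenerics::start(m) - 1L + enz$cut_offset
  cuts <- cuts[cuts > 0L & cuts < length(subj)]
  sort(unique(cuts))
}

#' Digest every sequence of a genome
#'
#' @param genome A named [Biostrings::DNAStringSet] or path to a FASTA file.
#' @inheritParams digest
#' @return A fragment data.frame as in [digest()], row-bound over sequences.
#' @export
digest_genome <- function(genome, enz, with_sequence = FALSE) {
  genome <- as_genome(genome)
  frs <- lapply(seq_along(genome), function(i)
    digest(genome[[i]], enz, chrom = names(genome)[i],
           with_sequence = with_sequence))
  do.call(rbind, frs)
}

as_genome <- function(genome) {
  if (is.character(genome) && length(genome) == 1L) {
    if (!file.exists(genome))
      stop("cannot read FASTA file: ", genome, call. = FALSE)
    genome <- Biostrings::readDNAStringSet(genome)
  }
  if (!is(genome, "DNAStringSet"))
    stop("genome must be a DNAStringSet or a FASTA path", call. = FALSE)
  if (length(genome) == 0L) stop("genome contains no sequences", call. = FALSE)
  if (is.null(names(genome))) names(genome) <- paste0("seq", seq_along(genome))
  # FASTA headers may carry a description after the first word
  names(genome) <- sub("\\s.*$", "", names(genome))
  genome
}

#' Size-select fragments
#'
#' Retains fragments whose length lies in `[min_len, max_len]` (inclusive),
#' the in silico analogue of excising a gel band.
#'
#' @param fragments A fragment data.frame from [digest()]/[digest_genome()].
#' @param min_len,max_len Inclusive bounds of the selection window (bp).
#' @return The selected rows, in the original order.
#' @export
size_select <- function(fragments, min_len = 450L, max_len = 550L) {
  stopifnot(is.data.frame(fragments), min_len <= max_len)
  fragments[fragments$length >= min_len & fragments$length <= max_len, ,
            drop = FALSE]
}

#' Survey enzymes for reduced-representation library design
#'
#' Digests a genome with each candidate enzyme, applies the size-selection
#' window, and reports per enzyme the fragment count, a fragment-size
#' histogram, the number of selected fragments, and the *representation
#' fraction* -- selected-fragment bases over total genome bases, i.e. the
#' genome share a library built from this digest would interrogate. When a
#' repeat mask is supplied, the fraction of selected-fragment bases falling
#' in masked intervals is reported as well, so enzymes can be ranked jointly
#' on representation and repetitive content.
#'
#' @param genome A named [Biostrings::DNAStringSet] or FASTA path.
#' @param enzymes A list of [enzyme()] objects (default: the four shipped
#'   blunt cutters, see [blunt_enzymes()]).
#' @param min_len,max_len Size-selection window (bp), inclusive.
#' @param bin_width Histogram bin width (bp).
#' @param mask Optional repeat mask: a [GenomicRanges::GRanges] or a BED
#'   path (0-based half-open).
#' @return A list with `summary`, a data.frame (one row per enzyme, sorted
#'   by `representation_fraction` descending) and `histograms`, a named list
#'   of `(bin_start, bin_end, count)` tables.
#' @export
rank_enzymes <- function(genome, enzymes = blunt_enzymes(),
                         min_len = 450L, max_len = 550L, bin_width = 50L,
                         mask = NULL) {
  stopifnot(length(enzymes) >= 1L)
  genome <- as_genome(genome)
  total_bp <- sum(as.numeric(Biostrings::width(genome)))
  mask_gr <- load_mask(mask)
  hists <- list()
  rows <- lapply(enzymes, function(enz) {
    fr <- digest_genome(genome, enz, with_sequence = FALSE)
    sel <- size_select(fr, min_len, max_len)
    hists[[enz$name]] <<- size_histogram(fr$length, bin_width)
    masked <- NA_real_
    if (!is.null(mask_gr) && nrow(sel) > 0L) {
      gr <- GenomicRanges::GRanges(sel$chrom,
                                   IRanges::IRanges(sel$start + 1L, sel$end))
      ov <- GenomicRanges::intersect(gr, mask_gr, ignore.strand = TRUE)
      masked <- sum(as.numeric(BiocGenerics::width(ov))) /
        sum(as.numeric(sel$length))
    }
    data.frame(
      enzyme = enz$name,
      n_fragments = nrow(fr),
      n_selected = nrow(sel),
      representation_fraction = sum(as.numeric(sel$length)) / total_bp,
      masked_fraction = masked,
      stringsAsFactors = FALSE
    )
  })
  summary <- do.call(rbind, rows)
  summary <- summary[order(-summary$representation_fraction, summary$enzyme), ]
  rownames(summary) <- NULL
  list(summary = summary, histograms = hists,
       window = c(min_len = min_len, max_len = max_len))
}

size_histogram <- function(lengths, bin_width = 50L) {
  if (length(lengths) == 0L)
    return(data.frame(bin_start = integer(), bin_end = integer(),
                      count = integer()))
  bin <- (lengths %/% bin_width) * bin_width
  tab <- table(bin)
  data.frame(bin_start = as.integer(names(tab)),
             bin_end = as.integer(names(tab)) + bin_width,
             count = as.integer(tab))
}

load_mask <- function(mask) {
  if (is.null(mask)) return(NULL)
  if (is(mask, "GRanges")) return(mask)
  if (is.character(mask) && length(mask) == 1L) {
    if (!file.exists(mask)) stop("cannot read mask file: ", mask, call. = FALSE)
    bed <- utils::read.table(mask, sep = "\t", stringsAsFactors = FALSE)
    return(GenomicRanges::GRanges(bed[[1L]],
                                  IRanges::IRanges(bed[[2L]] + 1L, bed[[3L]])))
  }
  stop("mask must be a GRanges or a BED file path", call. = FALSE)
}

#' Write an enzyme survey to TSV
#'
#' @param report A list from [rank_enzymes()].
#' @param path Output TSV path for the summary; histograms are written next
#'   to it as `<path>.<enzyme>.hist.tsv`.
#' @return `path`, invisibly.
#' @export
write_digest_report <- function(report, path) {
  utils::write.table(report$summary, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  for (nm in names(report$histograms))
    utils::write.table(report$histograms[[nm]],
                       paste0(path, ".", nm, ".hist.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
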