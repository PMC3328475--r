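#' Build an exact-match placement index over a reference
#'
#' Prepares a reference for exact full-length read placement at a fixed
#' read length: both strands are searchable and reverse-strand hits are
#' reported in forward-strand coordinates.
#'
#' When a table of known biallelic variants is supplied, the index
#' additionally holds the alternative parental haplotype (the reference
#' with the second allele substituted at every variant), and a read matches
#' a genomic position when it matches either haplotype sequence there.
#' Exact matching against this two-haplotype panel plays the role of the
#' mismatch allowance of a conventional short-read aligner: reads carrying
#' a parental allele place correctly, while reads carrying base-call errors
#' still fail to match anywhere and are dropped.
#'
#' @param reference A named [Biostrings::DNAStringSet] or FASTA path.
#' @param read_length Length shared by all reads to be placed.
#' @param variants Optional data.frame of known biallelic sites with
#'   columns `chrom`, `pos` (0-based), `parent1`, `parent2`; `parent1` must
#'   be the reference base.
#' @return An object of class `"exact_index"`.
#' @export
build_index <- function(reference, read_length, variants = NULL) {
  genome <- as_genome(reference)
  read_length <- as.integer(read_length)
  stopifnot(read_length >= 1L)
  if (all(Biostrings::width(genome) < read_length))
    stop("every reference sequence is shorter than read_length",
         call. = FALSE)
  panel <- list(genome)
  if (!is.null(variants) && nrow(variants) > 0L) {
    stopifnot(all(c("chrom", "pos", "parent1", "parent2") %in%
                    names(variants)))
    alt <- genome
    for (ch in unique(variants$chrom)) {
      v <- variants[variants$chrom == ch, ]
      if (!ch %in% names(alt))
        stop("variant on unknown chromosome: ", ch, call. = FALSE)
      ref_at <- as.character(Biostrings::extractAt(
        alt[[ch]], IRanges::IRanges(v$pos + 1L, width = 1L)))
      if (!all(ref_at == v$parent1))
        stop("variant parent1 alleles disagree with the reference",
             call. = FALSE)
      alt[[ch]] <- Biostrings::replaceLetterAt(
        alt[[ch]], v$pos + 1L, paste(v$parent2, collapse = ""))
    }
    panel <- c(panel, list(alt))
  }
  structure(list(
    panel = panel,
    rc_panel = lapply(panel, Biostrings::reverseComplement),
    read_length = read_length,
    chrom_names = names(genome),
    chrom_lengths = stats::setNames(Biostrings::width(genome),
                                    names(genome))
  ), class = "exact_index")
}

#' @export
print.exact_index <- function(x, ...) {
  cat(sprintf(
    "<exact_index> %d sequences, %.0f bp, read length %d, %d haplotype(s)\n",
    length(x$panel[[1]]), sum(as.numeric(x$chrom_lengths)),
    x$read_length, length(x$panel)))
  invisible(x)
}

#' Place reads by exact full-length match
#'
#' Each read is looked up on both strands of every indexed haplotype;
#' `hit_count` is its number of distinct matching genomic positions (a
#' position matched on several haplotypes, or by a palindromic read on both
#' strands, counts once). Reads with exactly one hit are kept; multi-hit
#' reads are discarded and counted, and reads exceeding `repeat_threshold`
#' hits are additionally tallied as repetitive elements. Reads containing
#' non-ACGT letters, or matching nowhere, are unmapped. Placement is
#' conservative: a read carrying any base-call error simply fails to match.
#'
#' @param reads A read data.frame (`read_id`, `sequence`, `quality`; a
#'   `bulk` column, if present, is carried through).
#' @param index A [build_index()] result.
#' @param repeat_threshold Hit count above which a read is flagged as a
#'   repetitive contaminant (default 100).
#' @return A list with `placements` (data.frame `read_id`, `chrom`, `pos`
#'   0-based, `strand`, `hit_count` = 1, sorted by position) and `report`:
#'   counts of input, mapped, unique, multi-hit discarded, repeat-flagged
#'   and unmapped reads, with fractions.
#' @export
place_reads <- function(reads, index, repeat_threshold = 100L) {
  check_reads(reads)
  stopifnot(inherits(index, "exact_index"))
  rl <- index$read_length
  n <- nrow(reads)
  if (n > 0L && !all(nchar(reads$sequence) == rl))
    stop("read length differs from index read_length", call. = FALSE)
  empty <- data.frame(read_id = character(), chrom = character(),
                      pos = integer(), strand = character(),
                      hit_count = integer(), stringsAsFactors = FALSE)
  if (n == 0L)
    return(list(placements = empty, report = mapping_report(0L, 0L, 0L, 0L)))

  clean <- grepl("^[ACGT]+$", reads$sequence)
  seqs <- Biostrings::DNAStringSet(reads$sequence[clean])
  hits <- list()
  if (length(seqs)) {
    pd <- Biostrings::PDict(seqs)
    for (h in seq_along(index$panel)) {
      for (j in seq_along(index$chrom_names)) {
        chrom <- index$chrom_names[j]
        clen <- index$chrom_lengths[[j]]
        mf <- Biostrings::matchPDict(pd, index$panel[[h]][[j]])
        sf <- Biostrings::startIndex(mf)
        lens <- lengths(sf)
        if (sum(lens))
          hits[[length(hits) + 1L]] <- data.table::data.table(
            idx = rep(seq_along(sf), lens), chrom = chrom,
            pos = unlist(sf) - 1L, strand = "+")
        mr <- Biostrings::matchPDict(pd, index$rc_panel[[h]][[j]])
        sr <- Biostrings::startIndex(mr)
        lens <- lengths(sr)
        if (sum(lens))
          hits[[length(hits) + 1L]] <- data.table::data.table(
            idx = rep(seq_along(sr), lens), chrom = chrom,
            pos = clen - (unlist(sr) - 1L) - rl, strand = "-")
      }
    }
  }
  hit_count <- integer(length(seqs))
  place <- empty
  if (length(hits)) {
    ht <- data.table::rbindlist(hits)
    # one hit per genomic position: a palindromic read matching both
    # strands at one position, or a position shared by several panel
    # haplotypes, counts once ("+" preferred for the kept placement)
    data.table::setorder(ht, idx, chrom, pos, strand)
    ht <- unique(ht, by = c("idx", "chrom", "pos"))
    cnt <- ht[, list(n_hits = .N), by = "idx"]
    hit_count[cnt$idx] <- cnt$n_hits
    upos <- ht[ht$idx %in% cnt$idx[cnt$n_hits == 1L], ]
    if (nrow(upos)) {
      clean_ids <- reads$read_id[clean]
      place <- data.frame(read_id = clean_ids[upos$idx], chrom = upos$chrom,
                          pos = upos$pos, strand = upos$strand,
                          hit_count = 1L, stringsAsFactors = FALSE)
      if ("bulk" %in% names(reads))
        place$bulk <- reads$bulk[clean][upos$idx]
      place <- place[order(place$chrom, place$pos, place$read_id), ]
      rownames(place) <- NULL
    }
  }

  report <- mapping_report(
    input = n,
    unique = sum(hit_count == 1L),
    multi = sum(hit_count > 1L),
    repeat_flagged = sum(hit_count > repeat_threshold))
  list(placements = place, report = report)
}

mapping_report <- function(input, unique, multi, repeat_flagged) {
  mapped <- unique + multi
  data.frame(
    input = input, mapped = mapped,
    mapped_fraction = if (input > 0L) mapped / input else NA_real_,
    unique = unique,
    unique_fraction = if (input > 0L) unique / input else NA_real_,
    multi_discarded = multi, repeat_flagged = repeat_flagged,
    unmapped = input - mapped)
}

#' Write placements as TSV
#'
#' @param placements Placement data.frame from [place_reads()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_placements <- function(placements, path) {
  utils::write.table(placements, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Import placements from a SAM file
#'
#' Lets any external aligner stand in for the internal exact-match engine.
#' The internal rules map onto SAM fields as: a record is kept as a unique
#' placement when it is mapped (flag bit 0x4 unset), primary (bits 0x100
#' and 0x800 unset) and has `MAPQ > 0` (multi-placed reads receive MAPQ 0
#' from common aligners); all other records are discarded. Strand comes
#' from flag bit 0x10; positions are converted to 0-based. SEQ/QUAL are
#' restored to as-sequenced orientation, so the result feeds [pileup()]
#' exactly like internal placements.
#'
#' @param path SAM file path (with `@SQ` header lines).
#' @return A list with `placements`, `reads` and `report` as in
#'   [place_reads()].
#' @export
read_sam_placements <- function(path) {
  if (!file.exists(path)) stop("cannot read SAM file: ", path, call. = FALSE)
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  res <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "seq", "qual")))[[1]]
  flag <- res$flag
  mapped <- bitwAnd(flag, 0x4L) == 0L
  primary <- bitwAnd(flag, 0x100L) == 0L & bitwAnd(flag, 0x800L) == 0L
  keep <- mapped & primary & !is.na(res$mapq) & res$mapq > 0L
  minus <- bitwAnd(flag, 0x10L) != 0L
  seqs <- as.character(res$seq)
  quals <- as.character(res$qual)
  flip <- keep & minus
  if (any(flip)) {
    seqs[flip] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(seqs[flip])))
    quals[flip] <- vapply(quals[flip], function(q)
      intToUtf8(rev(utf8ToInt(q))), character(1), USE.NAMES = FALSE)
  }
  placements <- data.frame(
    read_id = res$qname[keep], chrom = as.character(res$rname[keep]),
    pos = res$pos[keep] - 1L, strand = ifelse(minus[keep], "-", "+"),
    hit_count = 1L, stringsAsFactors = FALSE)
  reads <- data.frame(read_id = res$qname[keep], sequence = seqs[keep],
                      quality = quals[keep], stringsAsFactors = FALSE)
  report <- mapping_report(
    input = length(flag),
    unique = sum(keep),
    multi = sum(mapped & !keep),
    repeat_flagged = 0L)
  list(placements = placements, reads = reads, report = report)
}
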