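#' Detect tight clusters of associated SNPs
#'
#' Slides a window of `window_bp` along each chromosome, anchored at every
#' associated SNP; any window holding at least `min_count` SNPs seeds a
#' cluster, overlapping qualifying windows on a chromosome are merged, and
#' each merged cluster is reported as the minimal span of its member SNPs.
#' A chromosome region markedly enriched for bulk-differentiated SNPs is
#' the signature of a QTL in its vicinity.
#'
#' @param snps A data.frame of associated SNPs with `chrom` and `pos`
#'   (0-based), e.g. the `associated` table of [score_and_threshold()].
#' @param window_bp Window width in bp (default 400000).
#' @param min_count Minimum SNPs per window (default 5; must be >= 2).
#' @return A data.frame of clusters sorted by `snp_count` descending:
#'   `chrom`, `start`, `end` (0-based half-open minimal member span),
#'   `snp_count`, `fraction_of_all_associated`, and `members` (1-based row
#'   indices into the sorted input, comma-separated).
#' @export
scan_clusters <- function(snps, window_bp = 400000L, min_count = 5L) {
  stopifnot(is.data.frame(snps),
            all(c("chrom", "pos") %in% names(snps)))
  if (window_bp <= 0L) stop("window_bp must be positive", call. = FALSE)
  if (min_count < 2L) stop("min_count must be at least 2", call. = FALSE)
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), snp_count = integer(),
                      fraction_of_all_associated = numeric(),
                      members = character(), stringsAsFactors = FALSE)
  n_total <- nrow(snps)
  if (n_total == 0L) return(empty)
  snps <- snps[order(snps$chrom, snps$pos), , drop = FALSE]

  out <- list()
  for (ch in unique(snps$chrom)) {
    idx <- which(snps$chrom == ch)
    pos <- snps$pos[idx]
    # SNPs inside [pos_i, pos_i + window)
    cnt <- findInterval(pos + window_bp - 0.5, pos) -
      seq_along(pos) + 1L
    q <- which(cnt >= min_count)
    if (length(q) == 0L) next
    wins <- IRanges::reduce(IRanges::IRanges(start = pos[q] + 1L,
                                             width = window_bp))
    for (k in seq_along(wins)) {
      inw <- which(pos + 1L >= BiocGenerics::start(wins)[k] &
                     pos + 1L <= BiocGenerics::end(wins)[k])
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch,
        start = min(pos[inw]),
        end = max(pos[inw]) + 1L,
        snp_count = length(inw),
        fraction_of_all_associated = length(inw) / n_total,
        members = paste(idx[inw], collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(-res$snp_count, res$chrom, res$start), ]
  rownames(res) <- NULL
  res
}

#' Genome-wide distribution of associated SNPs
#'
#' @param snps Associated-SNP data.frame with `chrom` and `pos`.
#' @param chrom_lengths Named vector of chromosome lengths (bp); every SNP
#'   chromosome must appear in it.
#' @return A data.frame `(chrom, length_bp, n_snps, fraction)`, one row per
#'   chromosome in `chrom_lengths`; fractions sum to 1 over chromosomes
#'   carrying at least one SNP (and are 0 elsewhere).
#' @export
summarize_distribution <- function(snps, chrom_lengths) {
  stopifnot(is.data.frame(snps), all(c("chrom", "pos") %in% names(snps)),
            !is.null(names(chrom_lengths)))
  unknown <- setdiff(unique(snps$chrom), names(chrom_lengths))
  if (length(unknown))
    stop("SNPs on unknown chromosomes: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  n <- nrow(snps)
  counts <- table(factor(snps$chrom, levels = names(chrom_lengths)))
  data.frame(chrom = names(chrom_lengths),
             length_bp = as.integer(chrom_lengths),
             n_snps = as.integer(counts),
             fraction = if (n > 0L) as.integer(counts) / n else 0,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write clusters as BED and TSV
#'
#' BED is 0-based half-open with the SNP count as score.
#'
#' @param clusters A [scan_clusters()] data.frame.
#' @param bed_path,tsv_path Output paths (either may be `NULL`).
#' @return Invisibly, the paths written.
#' @export
write_clusters <- function(clusters, bed_path = NULL, tsv_path = NULL) {
  if (!is.null(bed_path)) {
    bed <- data.frame(clusters$chrom, clusters$start, clusters$end,
                      sprintf("cluster%d", seq_len(nrow(clusters))),
                      clusters$snp_count)
    utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(tsv_path))
    utils::write.table(clusters, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(c(bed = bed_path, tsv = tsv_path))
}
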