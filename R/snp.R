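#' Per-bulk allele pileup over placed reads
#'
#' Tallies the reference-oriented read base at every covered reference
#' position, separately per bulk. Reads placed on the minus strand are
#' reverse-complemented before tallying so all counts are in reference
#' orientation. Positions with zero coverage are omitted; non-ACGT read
#' bases are ignored.
#'
#' @param placements Placement data.frame (`read_id`, `chrom`, `pos`,
#'   `strand`), e.g. from [place_reads()]; a `bulk` column assigns each
#'   placement to a bulk, alternatively supply `bulk` as a vector.
#' @param reads Read data.frame holding the placed reads' sequences.
#' @param reference The reference genome ([Biostrings::DNAStringSet] or
#'   FASTA path) used for bounds checking.
#' @param bulk Optional per-placement bulk labels overriding a `bulk`
#'   column.
#' @return A data.frame with `chrom`, `pos` (0-based) and one count column
#'   per bulk and allele, named `<bulk>_<base>` (e.g. `RK_A` ... `SK_T`),
#'   sorted by position.
#' @export
pileup <- function(placements, reads, reference, bulk = NULL) {
  stopifnot(is.data.frame(placements),
            all(c("read_id", "chrom", "pos", "strand") %in% names(placements)))
  check_reads(reads)
  genome <- as_genome(reference)
  if (is.null(bulk)) {
    if (!"bulk" %in% names(placements))
      stop("no bulk labels: supply a bulk column or the bulk argument",
           call. = FALSE)
    bulk <- placements$bulk
  }
  stopifnot(length(bulk) == nrow(placements))
  if (nrow(placements) == 0L)
    return(data.frame(chrom = character(), pos = integer()))

  ri <- match(placements$read_id, reads$read_id)
  if (anyNA(ri)) stop("placements refer to unknown read_ids", call. = FALSE)
  seqs <- reads$sequence[ri]
  minus <- placements$strand == "-"
  if (any(minus))
    seqs[minus] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(seqs[minus])))

  clen <- stats::setNames(Biostrings::width(genome), names(genome))
  if (anyNA(clen[placements$chrom]))
    stop("placements refer to unknown chromosomes", call. = FALSE)
  L <- nchar(seqs)
  if (any(placements$pos < 0L) ||
      any(placements$pos + L > clen[placements$chrom]))
    stop("placement extends beyond the reference end", call. = FALSE)

  dt <- data.table::data.table(
    chrom = rep(placements$chrom, L),
    pos = rep(placements$pos, L) + sequence(L) - 1L,
    bulk = rep(bulk, L),
    allele = unlist(strsplit(seqs, "", fixed = TRUE)))
  dt <- dt[allele %in% DNA_BASES]
  cnt <- dt[, .N, by = c("chrom", "pos", "bulk", "allele")]
  wide <- data.table::dcast(cnt, chrom + pos ~ bulk + allele,
                            value.var = "N", fill = 0L, sep = "_")
  # guarantee all four allele columns per bulk
  bulks <- sort(unique(bulk))
  for (b in bulks) for (a in DNA_BASES) {
    col <- paste(b, a, sep = "_")
    if (!col %in% names(wide)) wide[[col]] <- 0L
  }
  cols <- c("chrom", "pos",
            as.vector(t(outer(bulks, DNA_BASES, paste, sep = "_"))))
  wide <- wide[order(chrom, pos), cols, with = FALSE]
  as.data.frame(wide)
}

#' Call candidate "simple SNPs" between two bulks
#'
#' A pileup position is a candidate biallelic site when (i) both bulks have
#' depth at least `min_depth_per_bulk`; (ii) the two most frequent alleles
#' jointly account for at least `1 - max_minor_fraction` of all reads across
#' both bulks (remaining bases are treated as sequencing noise and dropped
#' from the 2x2 table); and (iii) the two major alleles differ in relative
#' frequency between the bulks, so the table is non-degenerate. `allele_1`
#' is the allele more frequent in the first bulk (ties broken
#' alphabetically).
#'
#' @param pu A [pileup()] data.frame over exactly two bulks.
#' @param min_depth_per_bulk Minimum read depth per bulk (default 4).
#' @param max_minor_fraction Maximum tolerated fraction of reads carrying
#'   neither major allele (default 0.1).
#' @return A data.frame with `chrom`, `pos`, `allele_1`, `allele_2` and the
#'   2x2 counts `<bulk1>_n1`, `<bulk1>_n2`, `<bulk2>_n1`, `<bulk2>_n2`;
#'   bulk names are attached as attribute `"bulks"`.
#' @export
call_simple_snps <- function(pu, min_depth_per_bulk = 4L,
                             max_minor_fraction = 0.1) {
  stopifnot(is.data.frame(pu))
  count_cols <- grep("_[ACGT]$", names(pu), value = TRUE)
  bulks <- sort(unique(sub("_[ACGT]$", "", count_cols)))
  if (length(bulks) != 2L)
    stop("pileup must cover exactly two bulks", call. = FALSE)
  b1 <- bulks[1L]; b2 <- bulks[2L]
  empty <- data.frame(chrom = character(), pos = integer(),
                      allele_1 = character(), allele_2 = character(),
                      n1_b1 = integer(), n2_b1 = integer(),
                      n1_b2 = integer(), n2_b2 = integer())
  names(empty)[5:8] <- c(paste0(b1, c("_n1", "_n2")),
                         paste0(b2, c("_n1", "_n2")))
  if (nrow(pu) == 0L) return(structure(empty, bulks = bulks))

  m1 <- as.matrix(pu[, paste(b1, DNA_BASES, sep = "_")])
  m2 <- as.matrix(pu[, paste(b2, DNA_BASES, sep = "_")])
  d1 <- rowSums(m1); d2 <- rowSums(m2)
  tot <- m1 + m2
  # two most frequent alleles overall, ties to the alphabetically first
  rk <- t(apply(tot, 1L, function(x) order(-x, seq_along(x))[1:2]))
  j1 <- rk[, 1L]; j2 <- rk[, 2L]
  n <- nrow(pu)
  top2 <- tot[cbind(seq_len(n), j1)] + tot[cbind(seq_len(n), j2)]
  ok_depth <- d1 >= min_depth_per_bulk & d2 >= min_depth_per_bulk
  ok_purity <- (d1 + d2) > 0 & top2 >= (1 - max_minor_fraction) * (d1 + d2)

  a1_b1 <- m1[cbind(seq_len(n), j1)]; a2_b1 <- m1[cbind(seq_len(n), j2)]
  a1_b2 <- m2[cbind(seq_len(n), j1)]; a2_b2 <- m2[cbind(seq_len(n), j2)]
  f1 <- a1_b1 / pmax(1L, a1_b1 + a2_b1)
  f2 <- a1_b2 / pmax(1L, a1_b2 + a2_b2)
  ok_diff <- f1 != f2

  keep <- which(ok_depth & ok_purity & ok_diff)
  if (length(keep) == 0L) return(structure(empty, bulks = bulks))

  # orient so allele_1 is the first bulk's major allele
  swap <- a1_b1[keep] < a2_b1[keep] |
    (a1_b1[keep] == a2_b1[keep] & j1[keep] > j2[keep])
  A1 <- ifelse(swap, j2[keep], j1[keep])
  A2 <- ifelse(swap, j1[keep], j2[keep])
  out <- data.frame(
    chrom = pu$chrom[keep], pos = pu$pos[keep],
    allele_1 = DNA_BASES[A1], allele_2 = DNA_BASES[A2],
    n1_b1 = m1[cbind(keep, A1)], n2_b1 = m1[cbind(keep, A2)],
    n1_b2 = m2[cbind(keep, A1)], n2_b2 = m2[cbind(keep, A2)],
    stringsAsFactors = FALSE)
  names(out)[5:8] <- names(empty)[5:8]
  structure(out, bulks = bulks)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact hypergeometric test of allele-count homogeneity between two bulks.
#' The two-sided p-value follows the minimum-likelihood rule: the sum of
#' the probabilities of all tables with the observed margins whose
#' hypergeometric probability does not exceed that of the observed table
#' (with relative tolerance 1e-7 on the comparison, so exact ties are
#' included despite floating-point rounding). A table with a zero row or
#' column margin carries no information and returns p = 1.
#'
#' @param a,b,c,d Cell counts (vectors are accepted and recycled): rows are
#'   bulks, columns alleles, i.e. the table is `[[a, b], [c, d]]`.
#'   Alternatively `a` may be a single 2x2 matrix with `b, c, d` missing.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`
#'   (one-sided tails of the first cell).
#' @param log10 Return `-log10(p)` instead of `p` (computed in log space,
#'   accurate for very small p).
#' @return Numeric vector of p-values in `(0, 1]` (or `-log10 p`).
#' @examples
#' fisher_exact_2x2(10, 0, 0, 10)           # 2 / choose(20, 10)
#' fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2))  # 1
#' @export
fisher_exact_2x2 <- function(a, b = NULL, c = NULL, d = NULL,
                             alternative = c("two.sided", "greater", "less"),
                             log10 = FALSE) {
  alternative <- match.arg(alternative)
  if (is.matrix(a)) {
    stopifnot(all(dim(a) == 2L), is.null(b))
    b <- a[1L, 2L]; c <- a[2L, 1L]; d <- a[2L, 2L]; a <- a[1L, 1L]
  }
  n <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(a, n); b <- rep_len(b, n)
  c <- rep_len(c, n); d <- rep_len(d, n)
  if (any(a < 0 | b < 0 | c < 0 | d < 0) ||
      anyNA(a + b + c + d))
    stop("cell counts must be finite and non-negative", call. = FALSE)
  lp <- vapply(seq_len(n), function(i)
    fisher_log_p(a[i], b[i], c[i], d[i], alternative), numeric(1))
  if (log10) -lp / log(10) else pmin(1, exp(lp))
}

# natural-log p for one table
fisher_log_p <- function(a, b, c, d, alternative) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) return(0)  # p = 1
  klo <- max(0, r1 - c2); khi <- min(r1, c1)
  k <- klo:khi
  lpk <- stats::dhyper(k, c1, c2, r1, log = TRUE)
  lobs <- lpk[k == a]
  sel <- switch(alternative,
                two.sided = lpk <= lobs + log1p(1e-7),
                greater = k >= a,
                less = k <= a)
  # log-sum-exp over the selected tables
  mx <- max(lpk[sel])
  min(0, mx + log(sum(exp(lpk[sel] - mx))))
}

#' Score candidate SNPs and apply the association threshold
#'
#' Computes the two-sided Fisher exact p-value of every candidate's 2x2
#' bulk-by-allele table and retains sites with `-log10(p)` strictly greater
#' than the threshold -- the *associated SNPs*.
#'
#' @param candidates A [call_simple_snps()] data.frame.
#' @param threshold_neg_log10_p Selection threshold on `-log10(p)`
#'   (default 16; strict inequality).
#' @param alternative Passed to [fisher_exact_2x2()].
#' @return A list with `associated` (retained sites, sorted by
#'   chromosome and position) and `scored` (all candidates with `p_value`
#'   and `neg_log10_p`, for threshold-ladder reporting).
#' @export
score_and_threshold <- function(candidates, threshold_neg_log10_p = 16,
                                alternative = "two.sided") {
  stopifnot(is.data.frame(candidates), threshold_neg_log10_p >= 0)
  scored <- candidates
  if (nrow(scored)) {
    cc <- as.matrix(scored[, 5:8])  # b1_n1 b1_n2 b2_n1 b2_n2
    nlp <- fisher_exact_2x2(cc[, 1L], cc[, 2L], cc[, 3L], cc[, 4L],
                            alternative = alternative, log10 = TRUE)
    scored$p_value <- 10^(-nlp)
    scored$neg_log10_p <- nlp
    scored <- scored[order(scored$chrom, scored$pos), ]
    rownames(scored) <- NULL
  } else {
    scored$p_value <- numeric()
    scored$neg_log10_p <- numeric()
  }
  list(associated = scored[scored$neg_log10_p > threshold_neg_log10_p, ,
                           drop = FALSE],
       scored = scored)
}

#' Retained-SNP counts along a threshold ladder
#'
#' @param scored The `scored` table from [score_and_threshold()].
#' @param thresholds `-log10 p` thresholds (default `c(2, 5, 10, 16)`).
#' @return A data.frame `(threshold, n_retained)`; counts are necessarily
#'   non-increasing in the threshold.
#' @export
threshold_ladder <- function(scored, thresholds = c(2, 5, 10, 16)) {
  stopifnot(is.data.frame(scored), "neg_log10_p" %in% names(scored))
  data.frame(threshold = thresholds,
             n_retained = vapply(thresholds, function(t)
               sum(scored$neg_log10_p > t), integer(1)))
}

#' Write scored SNPs as TSV (1-based positions)
#'
#' @param scored A scored SNP data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_snp_table <- function(scored, path) {
  out <- scored
  out$pos <- out$pos + 1L
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Minimal VCF 4.2 export of scored SNPs
#'
#' REF is the reference base at the site (when a reference is supplied;
#' otherwise `allele_1`), ALT the other allele(s). Per-bulk allele depths
#' and the association score travel in INFO.
#'
#' @param scored A scored SNP data.frame from [score_and_threshold()].
#' @param path Output path.
#' @param reference Optional reference ([Biostrings::DNAStringSet] or FASTA
#'   path).
#' @return `path`, invisibly.
#' @export
write_snp_vcf <- function(scored, path, reference = NULL) {
  bulks <- attr(scored, "bulks")
  if (is.null(bulks)) bulks <- c("B1", "B2")
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##INFO=<ID=AD1,Number=2,Type=Integer,Description=\"%s allele depths (allele_1,allele_2)\">", bulks[1]),
    sprintf("##INFO=<ID=AD2,Number=2,Type=Integer,Description=\"%s allele depths (allele_1,allele_2)\">", bulks[2]),
    "##INFO=<ID=NLP,Number=1,Type=Float,Description=\"-log10 Fisher exact p\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  lines <- hdr
  if (nrow(scored)) {
    refbase <- scored$allele_1
    if (!is.null(reference)) {
      genome <- as_genome(reference)
      refbase <- vapply(seq_len(nrow(scored)), function(i) {
        as.character(Biostrings::subseq(
          genome[[scored$chrom[i]]], scored$pos[i] + 1L, scored$pos[i] + 1L))
      }, character(1))
    }
    alt <- ifelse(refbase == scored$allele_1, scored$allele_2,
                  ifelse(refbase == scored$allele_2, scored$allele_1,
                         paste(scored$allele_1, scored$allele_2, sep = ",")))
    cc <- as.matrix(scored[, 5:8])
    info <- sprintf("AD1=%d,%d;AD2=%d,%d;NLP=%.4f",
                    cc[, 1L], cc[, 2L], cc[, 3L], cc[, 4L],
                    scored$neg_log10_p)
    lines <- c(lines, sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s",
                              scored$chrom, scored$pos + 1L, refbase, alt,
                              info))
  }
  writeLines(lines, path)
  invisible(path)
}
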