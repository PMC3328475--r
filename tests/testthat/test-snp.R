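test_that("pileup tallies reference-oriented bases per bulk", {
  ref <- Biostrings::DNAStringSet(c(c1 = "CTAAGGTT"))
  reads <- make_reads("CTAA")
  pl <- data.frame(read_id = "r001", chrom = "c1", pos = 0L, strand = "+",
                   bulk = "RK", stringsAsFactors = FALSE)
  pu <- pileup(pl, reads, ref)
  expect_equal(pu$pos, 0:3)
  expect_equal(pu$RK_C, c(1L, 0L, 0L, 0L))
  expect_equal(pu$RK_T, c(0L, 1L, 0L, 0L))
  expect_equal(pu$RK_A, c(0L, 0L, 1L, 1L))

  # a minus-strand placement contributes the reverse complement
  rc <- make_reads("TTAG")  # revcomp "CTAA"
  plm <- data.frame(read_id = "r001", chrom = "c1", pos = 0L, strand = "-",
                    bulk = "RK", stringsAsFactors = FALSE)
  pum <- pileup(plm, rc, ref)
  expect_equal(pum$RK_C, pu$RK_C)
  expect_equal(pum$RK_A, pu$RK_A)
})

test_that("pileup validates bounds and handles empty input", {
  ref <- Biostrings::DNAStringSet(c(c1 = "CTAAGGTT"))
  empty <- pileup(data.frame(read_id = character(), chrom = character(),
                             pos = integer(), strand = character(),
                             bulk = character()),
                  make_reads(character()), ref)
  expect_equal(nrow(empty), 0L)
  pl <- data.frame(read_id = "r001", chrom = "c1", pos = 6L, strand = "+",
                   bulk = "RK", stringsAsFactors = FALSE)
  expect_error(pileup(pl, make_reads("CTAA"), ref), "beyond the reference")
})

test_that("pileup counts are conserved over a heterozygous site", {
  ref <- Biostrings::DNAStringSet(c(c1 = paste0("CT", random_dna(38,
                                                                 seed = 41))))
  base <- as.character(Biostrings::subseq(ref[["c1"]], 1, 20))
  alt <- base
  substr(alt, 10, 10) <- setdiff(c("A", "C", "G", "T"),
                                 substr(base, 10, 10))[1]
  reads <- make_reads(c(rep(base, 6), rep(alt, 4)))
  pl <- data.frame(read_id = reads$read_id, chrom = "c1", pos = 0L,
                   strand = "+", bulk = rep(c("RK", "SK"), c(6, 4)),
                   stringsAsFactors = FALSE)
  pu <- pileup(pl, reads, ref)
  at <- pu[pu$pos == 9L, ]
  expect_equal(sum(at[, grep("_[ACGT]$", names(at))]), 10L)
})

test_that("simple-SNP calling applies depth, purity and difference rules", {
  mk <- function(rk, sk) {
    pu <- data.frame(chrom = "c1", pos = 0L,
                     RK_A = rk[1], RK_C = rk[2], RK_G = rk[3], RK_T = rk[4],
                     SK_A = sk[1], SK_C = sk[2], SK_G = sk[3], SK_T = sk[4])
    call_simple_snps(pu)
  }
  clean <- mk(c(10, 0, 0, 0), c(0, 0, 10, 0))
  expect_equal(nrow(clean), 1L)
  expect_equal(clean$allele_1, "A")
  expect_equal(clean$allele_2, "G")
  expect_equal(unname(unlist(clean[1, 5:8])), c(10L, 0L, 0L, 10L))

  expect_equal(nrow(mk(c(3, 0, 0, 0), c(0, 0, 10, 0))), 0L)  # depth

  noisy <- mk(c(8, 1, 1, 0), c(0, 0, 10, 0))
  expect_equal(nrow(noisy), 1L)
  expect_equal(noisy$allele_1, "A")
  expect_equal(noisy$allele_2, "G")
  expect_equal(unname(unlist(noisy[1, 5:8])), c(8L, 1L, 0L, 10L))

  # three well-supported alleles: purity fails
  expect_equal(nrow(mk(c(6, 4, 0, 0), c(0, 0, 10, 0))), 0L)
  # identical allele frequencies in both bulks: degenerate, not a SNP
  expect_equal(nrow(mk(c(5, 5, 0, 0), c(5, 5, 0, 0))), 0L)
  # monomorphic site
  expect_equal(nrow(mk(c(10, 0, 0, 0), c(10, 0, 0, 0))), 0L)
})

test_that("Fisher exact test matches closed forms and stats::fisher.test", {
  expect_equal(fisher_exact_2x2(5, 5, 5, 5), 1)
  expect_equal(fisher_exact_2x2(10, 0, 0, 10), 2 / choose(20, 10))
  expect_equal(fisher_exact_2x2(20, 0, 0, 20, log10 = TRUE),
               log10(choose(40, 20) / 2), tolerance = 1e-12)
  # zero margins carry no information
  expect_equal(fisher_exact_2x2(0, 0, 3, 4), 1)
  expect_equal(fisher_exact_2x2(0, 3, 0, 4), 1)

  set.seed(43)
  for (i in 1:200) {
    tb <- matrix(rpois(4, 8), 2)
    mine <- fisher_exact_2x2(tb)
    ft <- stats::fisher.test(tb)$p.value
    expect_equal(mine, min(ft, 1), tolerance = 1e-10)
  }
  # one-sided tails
  tb <- matrix(c(9, 2, 3, 8), 2, byrow = TRUE)
  expect_equal(fisher_exact_2x2(tb, alternative = "greater"),
               stats::fisher.test(tb, alternative = "greater")$p.value,
               tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(tb, alternative = "less"),
               stats::fisher.test(tb, alternative = "less")$p.value,
               tolerance = 1e-12)
})

test_that("Fisher p is symmetric under row, column and transpose swaps", {
  set.seed(44)
  for (i in 1:50) {
    x <- rpois(4, 6)
    p <- fisher_exact_2x2(x[1], x[2], x[3], x[4])
    expect_equal(fisher_exact_2x2(x[3], x[4], x[1], x[2]), p)
    expect_equal(fisher_exact_2x2(x[2], x[1], x[4], x[3]), p)
    expect_equal(fisher_exact_2x2(x[1], x[3], x[2], x[4]), p)
    expect_gt(p, 0)
    expect_lte(p, 1)
  }
})

test_that("-log10 p over 16 needs combined depth near 60, fully split", {
  # fully differentiated tables at increasing depth
  nlp <- function(d1, d2) fisher_exact_2x2(d1, 0, 0, d2, log10 = TRUE)
  expect_lt(nlp(27, 27), 16)
  expect_lt(nlp(28, 28), 16)
  expect_gt(nlp(28, 29), 16)   # asymmetric margins drop the heavier tail
  expect_gt(nlp(30, 30), 16)
  expect_equal(nlp(28, 29),
               -log10(stats::fisher.test(matrix(c(28, 0, 0, 29), 2))$
                        p.value),
               tolerance = 1e-9)
})

test_that("association scoring thresholds strictly and nests", {
  cand <- data.frame(
    chrom = "c1", pos = c(10L, 20L, 30L),
    allele_1 = "A", allele_2 = "G",
    RK_n1 = c(5L, 30L, 12L), RK_n2 = c(5L, 0L, 0L),
    SK_n1 = c(5L, 0L, 0L), SK_n2 = c(5L, 30L, 12L))
  sc <- score_and_threshold(cand, 16)
  expect_equal(sc$scored$pos, c(10L, 20L, 30L))
  expect_equal(sc$associated$pos, 20L)   # p = 1 and the weak site excluded
  lad <- threshold_ladder(sc$scored, c(0, 2, 5, 10, 16))
  expect_false(is.unsorted(rev(lad$n_retained)))
  # nesting: every site above a higher threshold is above a lower one
  above <- lapply(c(2, 5, 10, 16), function(t)
    sc$scored$pos[sc$scored$neg_log10_p > t])
  for (k in 2:4)
    expect_true(all(above[[k]] %in% above[[k - 1]]))
  # p = 1 is excluded at any positive threshold and at zero
  expect_false(10L %in% sc$associated$pos)
  sc0 <- score_and_threshold(cand, 0)
  expect_false(10L %in% sc0$associated$pos)
})

test_that("scored SNPs export to TSV and minimal VCF", {
  cand <- data.frame(
    chrom = "c1", pos = c(4L, 9L),
    allele_1 = c("A", "C"), allele_2 = c("G", "T"),
    RK_n1 = c(20L, 15L), RK_n2 = c(0L, 1L),
    SK_n1 = c(0L, 0L), SK_n2 = c(20L, 14L))
  attr(cand, "bulks") <- c("RK", "SK")
  sc <- score_and_threshold(cand, 2)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_snp_table(sc$scored, tsv)
  back <- read.table(tsv, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
  expect_equal(back$pos, c(5L, 10L))  # 1-based in the export

  ref <- Biostrings::DNAStringSet(c(c1 = "AAAAAAAAACAAAA"))
  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_snp_vcf(sc$scored, vcf, reference = ref)
  lines <- readLines(vcf)
  expect_equal(lines[1], "##fileformat=VCFv4.2")
  body <- read.table(text = lines[!startsWith(lines, "#")], sep = "\t")
  expect_equal(body[[2]], c(5L, 10L))
  expect_equal(body[[4]], c("A", "C"))  # reference bases
  expect_equal(body[[5]], c("G", "T"))
})
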