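# a reference with unique 30 bp reads placeable at known positions
make_ref <- function(seed, len = 3000) {
  Biostrings::DNAStringSet(c(chrA = random_dna(len, seed = seed),
                             chrB = random_dna(len)))
}

test_that("index construction validates its inputs", {
  expect_error(build_index(Biostrings::DNAStringSet(), 30), "no sequences")
  short <- Biostrings::DNAStringSet(c(a = "ACGT"))
  expect_error(build_index(short, 30), "shorter than read_length")
  expect_silent(build_index(make_ref(31), 30))
})

test_that("unique reads place at their true position on either strand", {
  ref <- make_ref(32)
  idx <- build_index(ref, 30)
  fwd <- as.character(Biostrings::subseq(ref[["chrA"]], 101, 130))
  rev <- as.character(Biostrings::reverseComplement(
    Biostrings::subseq(ref[["chrB"]], 501, 530)))
  pr <- place_reads(make_reads(c(fwd, rev)), idx)
  expect_equal(nrow(pr$placements), 2L)
  p <- pr$placements[order(pr$placements$chrom), ]
  expect_equal(p$chrom, c("chrA", "chrB"))
  expect_equal(p$pos, c(100L, 500L))
  expect_equal(p$strand, c("+", "-"))
  # the reference substring under a kept placement equals the read
  # (reference-oriented)
  expect_equal(as.character(Biostrings::subseq(ref[["chrA"]], 101, 130)),
               fwd)
  expect_equal(pr$report$unique, 2L)
  expect_equal(pr$report$unmapped, 0L)
})

test_that("multi-hit reads are discarded and high-copy reads repeat-flagged", {
  motif <- random_dna(30, seed = 33)
  twice <- Biostrings::DNAStringSet(c(a = paste0(
    random_dna(50), motif, random_dna(50), motif, random_dna(50))))
  idx2 <- build_index(twice, 30)
  pr2 <- place_reads(make_reads(motif), idx2)
  expect_equal(nrow(pr2$placements), 0L)
  expect_equal(pr2$report$multi_discarded, 1L)
  expect_equal(pr2$report$repeat_flagged, 0L)

  many <- Biostrings::DNAStringSet(c(a = paste(
    rep(paste0(motif, "AATTCCGGAA"), 101), collapse = "")))
  idx101 <- build_index(many, 30)
  pr101 <- place_reads(make_reads(motif), idx101, repeat_threshold = 100L)
  expect_equal(pr101$report$multi_discarded, 1L)
  expect_equal(pr101$report$repeat_flagged, 1L)
})

test_that("palindromic reads count each genomic position once", {
  half <- random_dna(15, seed = 34)
  pal <- paste0(half, as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(half))))
  ref <- Biostrings::DNAStringSet(c(a = paste0(random_dna(60), pal,
                                               random_dna(60))))
  idx <- build_index(ref, 30)
  pr <- place_reads(make_reads(pal), idx)
  expect_equal(pr$report$unique, 1L)
  expect_equal(nrow(pr$placements), 1L)
  expect_equal(pr$placements$pos, 60L)
})

test_that("unmapped and malformed reads are accounted for", {
  ref <- make_ref(35)
  idx <- build_index(ref, 30)
  absent <- strrep("A", 30)  # vanishingly unlikely in random reference
  withn <- paste0("N", substr(as.character(ref[["chrA"]]), 2, 30))
  pr <- place_reads(make_reads(c(absent, withn)), idx)
  expect_equal(pr$report$unmapped, 2L)
  expect_error(place_reads(make_reads("ACGT"), idx),
               "read length differs")
})

test_that("placement does not depend on read order", {
  ref <- make_ref(36)
  idx <- build_index(ref, 30)
  refstr <- as.character(ref[["chrA"]])
  reads <- make_reads(vapply(seq(1, 800, by = 37), function(p)
    substr(refstr, p, p + 29), character(1)))
  a <- place_reads(reads, idx)
  b <- place_reads(reads[rev(seq_len(nrow(reads))), ], idx)
  expect_equal(a$placements, b$placements)
  expect_equal(a$report, b$report)
})

test_that("the haplotype panel maps variant-carrying reads, deduplicated", {
  ref <- make_ref(37)
  variants <- data.frame(chrom = "chrA", pos = 110L,
                         parent1 = substr(as.character(ref[["chrA"]]),
                                          111, 111),
                         parent2 = NA, stringsAsFactors = FALSE)
  variants$parent2 <- setdiff(c("A", "C", "G", "T"), variants$parent1)[1]
  idx <- build_index(ref, 30, variants = variants)
  # read carrying the parent-2 allele at offset 10 of window [101,130]
  alt_read <- as.character(Biostrings::subseq(ref[["chrA"]], 101, 130))
  substr(alt_read, 10, 10) <- variants$parent2
  # read without any variant in its window: matches both haplotypes at the
  # same position, which must count as one hit
  plain <- as.character(Biostrings::subseq(ref[["chrA"]], 501, 530))
  pr <- place_reads(make_reads(c(alt_read, plain)), idx)
  expect_equal(pr$report$unique, 2L)
  expect_equal(sort(pr$placements$pos), c(100L, 500L))
  expect_equal(pr$report$multi_discarded, 0L)
})

test_that("error-free simulated reads place uniquely at high rate", {
  rates <- vapply(1:10, function(s) {
    sim <- simulate_truth(small_sim_config(300 + s, base_error_rate = 0))
    bulks <- select_bulks(sim$phenotypes, bulk_size = 5L)
    reads <- simulate_bulk_reads(sim, bulks)
    idx <- build_index(sim$reference, 90, variants = sim$snps)
    place_reads(rbind(reads$RK, reads$SK), idx)$report$unique_fraction
  }, numeric(1))
  expect_true(all(rates >= 0.95))
})

test_that("SAM import applies the documented keep rules", {
  sam <- c(
    "@HD\tVN:1.6\tSO:unknown",
    "@SQ\tSN:chrA\tLN:1000",
    # kept: mapped, primary, MAPQ 60, forward
    "r1\t0\tchrA\t101\t60\t30M\t*\t0\t0\tACGTACGTACGTACGTACGTACGTACGTAC\tIIIIIIIIIIIIIIIIIIIIIIIIIIIIII",
    # kept: reverse strand; SEQ in SAM is reference-oriented
    "r2\t16\tchrA\t201\t60\t30M\t*\t0\t0\tAAAACCCCGGGGTTTTAAAACCCCGGGGTT\tIIIIIIIIIIIIIIIIIIIIIIIIIIIIII",
    # dropped: MAPQ 0 (multi-placed)
    "r3\t0\tchrA\t301\t0\t30M\t*\t0\t0\tACGTACGTACGTACGTACGTACGTACGTAC\tIIIIIIIIIIIIIIIIIIIIIIIIIIIIII",
    # dropped: secondary alignment
    "r4\t256\tchrA\t401\t60\t30M\t*\t0\t0\tACGTACGTACGTACGTACGTACGTACGTAC\tIIIIIIIIIIIIIIIIIIIIIIIIIIIIII",
    # dropped: unmapped
    "r5\t4\t*\t0\t0\t*\t*\t0\t0\tACGTACGTACGTACGTACGTACGTACGTAC\tIIIIIIIIIIIIIIIIIIIIIIIIIIIIII")
  path <- withr::local_tempfile(fileext = ".sam")
  writeLines(sam, path)
  res <- read_sam_placements(path)
  expect_equal(res$placements$read_id, c("r1", "r2"))
  expect_equal(res$placements$pos, c(100L, 200L))
  expect_equal(res$placements$strand, c("+", "-"))
  expect_equal(res$report$input, 5L)
  expect_equal(res$report$unique, 2L)
  expect_equal(res$report$multi_discarded, 2L)  # r3, r4
  # r2's as-sequenced read is the reverse complement of the SAM field
  expect_equal(res$reads$sequence[2], as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(
      "AAAACCCCGGGGTTTTAAAACCCCGGGGTT"))))
})
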