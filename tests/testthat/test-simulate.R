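test_that("the generator is deterministic given the seed", {
  a <- simulate_truth(small_sim_config(5))
  b <- simulate_truth(small_sim_config(5))
  expect_identical(as.character(a$reference), as.character(b$reference))
  expect_identical(a$snps, b$snps)
  expect_identical(a$phenotypes, b$phenotypes)
  bulks <- select_bulks(a$phenotypes, bulk_size = 5L)
  expect_identical(simulate_bulk_reads(a, bulks),
                   simulate_bulk_reads(b, bulks))
})

test_that("noise-free phenotypes sit exactly on the genotype class means", {
  sim <- simulate_truth(small_sim_config(6, phenotype_sd = 0))
  expect_true(all(sim$phenotypes$ssri %in% c(0.06, 0.50, 0.94)))
  expect_equal(unname(sim$phenotypes$ssri),
               unname(c(0.06, 0.50, 0.94)[sim$qtl$genotype + 1L]))
})

test_that("genotype class frequencies converge to 1:2:1", {
  sim <- simulate_truth(sim_config(7, n_chromosomes = 1L,
                                   chromosome_length_bp = 60000L,
                                   marker_snp_count = 8L,
                                   n_individuals = 10000L))
  freq <- apply(sim$genotypes, 2L, function(g)
    table(factor(g, levels = 0:2)) / length(g))
  expect_true(all(abs(freq[1, ] - 0.25) < 0.02))
  expect_true(all(abs(freq[2, ] - 0.50) < 0.02))
  expect_true(all(abs(freq[3, ] - 0.25) < 0.02))
})

test_that("marker truth matches the reference and its alternate alleles", {
  sim <- default_small_sim()
  ref1 <- vapply(seq_len(nrow(sim$snps)), function(i)
    as.character(Biostrings::subseq(sim$reference[[sim$snps$chrom[i]]],
                                    sim$snps$pos[i] + 1L,
                                    sim$snps$pos[i] + 1L)), character(1))
  expect_equal(ref1, sim$snps$parent1)
  expect_true(all(sim$snps$parent1 != sim$snps$parent2))
  expect_equal(sum(sim$snps$is_qtl), 1L)
  # every marker lies inside a size-selected fragment
  sel <- sim$selected
  covered <- vapply(seq_len(nrow(sim$snps)), function(i)
    any(sel$chrom == sim$snps$chrom[i] & sel$start <= sim$snps$pos[i] &
          sel$end > sim$snps$pos[i]), logical(1))
  expect_true(all(covered))
})

test_that("a QTL outside any selectable fragment is a configuration error", {
  sim <- default_small_sim()
  sel <- sim$selected
  # find a position not inside any selected fragment
  in_sel <- function(p) any(sel$start <= p & sel$end > p)
  p <- 0L
  while (in_sel(p)) p <- p + 1000L
  expect_error(
    simulate_truth(small_sim_config(42, qtl_pos_bp = p)),
    "selectable fragment")
})

test_that("reads start with the residual tag and mirror the haplotypes", {
  cfg <- small_sim_config(8, base_error_rate = 0)
  sim <- simulate_truth(cfg)
  bulks <- select_bulks(sim$phenotypes, bulk_size = 5L)
  reads <- simulate_bulk_reads(sim, bulks)
  for (b in names(reads)) {
    expect_true(all(startsWith(reads[[b]]$sequence, "CT")))
    expect_true(all(nchar(reads[[b]]$sequence) == cfg$read_length))
  }
  # error-free reads are exact substrings of one of the two parental
  # haplotype sequences
  idx <- build_index(sim$reference, cfg$read_length, variants = sim$snps)
  pr <- place_reads(rbind(reads$RK, reads$SK), idx)
  expect_equal(pr$report$mapped_fraction, 1)
})

test_that("mean depth over the accessible footprint is near target", {
  cfg <- small_sim_config(9, target_depth = 25)
  sim <- simulate_truth(cfg)
  bulks <- select_bulks(sim$phenotypes, bulk_size = 5L)
  reads <- simulate_bulk_reads(sim, bulks)
  # true origins are encoded in read names: <id>|chrom|start|strand|...
  for (b in names(reads)) {
    origin <- do.call(rbind, strsplit(reads[[b]]$read_id, "|", fixed = TRUE))
    start <- as.integer(origin[, 3])
    # depth at each marker from true origins
    depth <- vapply(seq_len(nrow(sim$snps)), function(i) {
      sum(origin[, 2] == sim$snps$chrom[i] &
            start <= sim$snps$pos[i] &
            start + cfg$read_length > sim$snps$pos[i])
    }, numeric(1))
    expect_lt(abs(mean(depth) - cfg$target_depth), 0.1 * cfg$target_depth)
  }
})

test_that("bulks are nearly pure for the QTL genotype", {
  purities <- vapply(1:20, function(s) {
    sim <- simulate_truth(small_sim_config(100 + s))
    bulks <- select_bulks(sim$phenotypes, bulk_size = 5L)
    g <- sim$qtl$genotype
    names(g) <- sim$phenotypes$individual_id
    mean(c(g[bulks$rk_ids] == 2L, g[bulks$sk_ids] == 0L))
  }, numeric(1))
  expect_gte(mean(purities), 0.90)
})

test_that("bulk allele-frequency divergence decays with map distance", {
  # long genetic map so recombination is visible along the chromosome
  div_by_bin <- matrix(0, 20, 3)
  for (s in 1:20) {
    sim <- simulate_truth(small_sim_config(200 + s, bp_per_cm = 2500))
    bulks <- select_bulks(sim$phenotypes, bulk_size = 5L)
    rk <- match(bulks$rk_ids, sim$phenotypes$individual_id)
    sk <- match(bulks$sk_ids, sim$phenotypes$individual_id)
    ch <- sim$qtl$chrom
    freq <- function(rows) colMeans(rbind(sim$hap1[[ch]][rows, , drop = FALSE],
                                          sim$hap2[[ch]][rows, , drop = FALSE]))
    dv <- abs(freq(rk) - freq(sk))
    d_cm <- abs(sim$snps$cM[sim$snps$chrom == ch] -
                  sim$snps$cM[sim$snps$is_qtl])
    bin <- cut(d_cm, c(-1, 5, 20, Inf), labels = FALSE)
    div_by_bin[s, ] <- tapply(dv, factor(bin, levels = 1:3), mean)
  }
  avg <- colMeans(div_by_bin, na.rm = TRUE)
  expect_true(all(diff(avg) < 0))
})

test_that("an empty bulk is rejected", {
  sim <- default_small_sim()
  fake <- structure(list(sk_ids = character(), rk_ids = sim$phenotypes$
                           individual_id[1:2],
                         low_cut = 0.1, high_cut = 0.9, bulk_size = 2L),
                    class = "bulk_assignment")
  expect_error(simulate_bulk_reads(sim, fake), "empty bulk")
})

test_that("simulation truth round-trips through the written files", {
  sim <- default_small_sim()
  dir <- withr::local_tempdir()
  write_simulation(sim, dir)
  ref <- Biostrings::readDNAStringSet(file.path(dir, "reference.fa"))
  expect_equal(as.character(ref), as.character(sim$reference))
  snps <- read.table(file.path(dir, "snps.tsv"), header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
  expect_equal(snps$pos, sim$snps$pos)
  ph <- read.table(file.path(dir, "phenotypes.tsv"), header = TRUE,
                   sep = "\t", stringsAsFactors = FALSE)
  expect_equal(ph$ssri, sim$phenotypes$ssri)
})
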