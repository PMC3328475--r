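#' Configuration for the synthetic BSA-RRL study
#'
#' Bundles every knob of the simulated study design: a random genome with
#' restriction sites at a controlled spacing, an F2 population segregating
#' 1:2:1 at one planted major QTL, a three-peak phenotype index (genotype
#' class means mirroring resistant/susceptible parent indices 0.94 / 0.06),
#' extreme-tail bulks, and per-bulk single-end restriction-tag reads.
#'
#' @param seed Integer seed; every downstream draw derives from it.
#' @param n_chromosomes,chromosome_length_bp Genome shape.
#' @param enzyme Library [enzyme()] (unambiguous site required; default
#'   AluI).
#' @param site_density_bp Mean spacing of planted recognition sites (bp).
#'   The default 256 matches the expected spacing of a 4-base cutter in
#'   random sequence, which puts roughly 10% of genome bases into fragments
#'   of the 450-550 bp selection window.
#' @param min_len,max_len Fragment size-selection window (bp).
#' @param n_individuals F2 population size (default 276).
#' @param qtl_chrom,qtl_pos_bp QTL location; by default the last chromosome,
#'   at the read-accessible position nearest its midpoint. A user-supplied
#'   position must fall inside a size-selected fragment, else the
#'   association scan could never see the QTL and configuration fails.
#' @param genotype_means Phenotype means for genotype classes 0 (homozygous
#'   parent 1, susceptible), 1 (heterozygous), 2 (homozygous parent 2,
#'   resistant): default `c(0.06, 0.50, 0.94)`.
#' @param phenotype_sd Gaussian phenotype noise sd (default 0.08); the index
#'   is truncated to `[0, 1]`.
#' @param qtl_effect When `FALSE` the phenotype is drawn from an independent
#'   1:2:1 class indicator instead of the true QTL genotype -- the no-QTL
#'   null in which bulks are uninformative about every locus.
#' @param marker_snp_count Biallelic parent-1/parent-2 marker SNPs planted
#'   in read-accessible parts of selectable fragments (default 600).
#' @param read_length Read length (bp, default 90).
#' @param target_depth Mean raw read depth over the read-accessible library
#'   footprint, per bulk (default 20).
#' @param base_error_rate Per-base substitution error rate (default 0.002).
#' @param base_quality Constant Phred quality assigned to simulated bases
#'   (default 30); alternatively supply `quality_profile`, a per-position
#'   integer vector of length `read_length`.
#' @param quality_profile Optional per-position Phred profile.
#' @param bulk_size Individuals per phenotype bulk (default 10).
#' @param bp_per_cm Physical-to-genetic scale for the Haldane map
#'   (default 250000 bp/cM).
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(seed,
                       n_chromosomes = 3L,
                       chromosome_length_bp = 900000L,
                       enzyme = blunt_enzymes()$AluI,
                       site_density_bp = 256,
                       min_len = 450L,
                       max_len = 550L,
                       n_individuals = 276L,
                       qtl_chrom = NULL,
                       qtl_pos_bp = NULL,
                       genotype_means = c(0.06, 0.50, 0.94),
                       phenotype_sd = 0.08,
                       qtl_effect = TRUE,
                       marker_snp_count = 600L,
                       read_length = 90L,
                       target_depth = 20,
                       base_error_rate = 0.002,
                       base_quality = 30L,
                       quality_profile = NULL,
                       bulk_size = 10L,
                       bp_per_cm = 250000) {
  seed <- as.integer(seed)
  stopifnot(!is.na(seed), n_chromosomes >= 1L, chromosome_length_bp >= 1000L,
            inherits(enzyme, "enzyme"), site_density_bp > nchar(enzyme$recognition_site),
            min_len <= max_len, n_individuals >= 3L,
            length(genotype_means) == 3L,
            all(genotype_means >= 0 & genotype_means <= 1),
            phenotype_sd >= 0, marker_snp_count >= 1L,
            read_length >= 20L, target_depth > 0,
            base_error_rate >= 0 && base_error_rate <= 1,
            bulk_size >= 1L, bp_per_cm > 0)
  if (site_is_degenerate(enzyme))
    stop("the simulator requires an enzyme with an unambiguous site",
         call. = FALSE)
  if (!is.null(quality_profile) &&
      length(quality_profile) != read_length)
    stop("quality_profile must have one entry per read position",
         call. = FALSE)
  chrom_names <- sprintf("A%02d", seq_len(n_chromosomes))
  if (is.null(qtl_chrom)) qtl_chrom <- chrom_names[n_chromosomes]
  if (!qtl_chrom %in% chrom_names)
    stop("qtl_chrom is not one of the simulated chromosomes", call. = FALSE)
  if (!is.null(qtl_pos_bp) &&
      (qtl_pos_bp < 0 || qtl_pos_bp >= chromosome_length_bp))
    stop("qtl_pos_bp outside its chromosome", call. = FALSE)
  structure(list(
    seed = seed, n_chromosomes = as.integer(n_chromosomes),
    chromosome_length_bp = as.integer(chromosome_length_bp),
    chrom_names = chrom_names, enzyme = enzyme,
    site_density_bp = site_density_bp,
    min_len = as.integer(min_len), max_len = as.integer(max_len),
    n_individuals = as.integer(n_individuals),
    qtl_chrom = qtl_chrom, qtl_pos_bp = qtl_pos_bp,
    genotype_means = genotype_means, phenotype_sd = phenotype_sd,
    qtl_effect = isTRUE(qtl_effect),
    marker_snp_count = as.integer(marker_snp_count),
    read_length = as.integer(read_length), target_depth = target_depth,
    base_error_rate = base_error_rate,
    base_quality = as.integer(base_quality),
    quality_profile = quality_profile,
    bulk_size = as.integer(bulk_size), bp_per_cm = bp_per_cm
  ), class = "sim_config")
}

DNA_BASES <- c("A", "C", "G", "T")

#' Haldane map function
#'
#' Recombination fraction between loci `d` centimorgans apart under the
#' Haldane model (crossovers Poisson, no interference):
#' `r = (1 - exp(-2 d / 100)) / 2`.
#'
#' @param d_cm Genetic distance in cM.
#' @return Recombination fraction in `[0, 0.5)`.
#' @export
haldane_r <- function(d_cm) (1 - exp(-2 * d_cm / 100)) / 2

# Build one chromosome with recognition sites planted at ~Exp(site_density)
# spacing and no accidental site occurrences elsewhere, so the digest of the
# chromosome is exactly the planted fragmentation.
build_chromosome <- function(len, enz, site_density_bp) {
  site <- strsplit(enz$recognition_site, "")[[1]]
  slen <- length(site)
  n_approx <- ceiling(len / site_density_bp * 1.6) + 10L
  gaps <- pmax(30L, round(stats::rexp(n_approx, 1 / (site_density_bp - slen))))
  starts <- cumsum(gaps + slen) - slen          # 0-based site starts
  starts <- starts[starts + slen <= len - 30L]
  chars <- sample(DNA_BASES, len, replace = TRUE)
  site_idx <- as.vector(outer(seq_len(slen), starts, `+`))  # 1-based
  chars[site_idx] <- rep(site, length(starts))
  planted <- logical(len)
  planted[site_idx] <- TRUE
  # scrub accidental occurrences (expected ~len/4^slen) without touching
  # planted site bases
  for (iter in 1:25) {
    hits <- BiocGenerics::start(Biostrings::matchPattern(
      Biostrings::DNAString(enz$recognition_site),
      Biostrings::DNAString(paste(chars, collapse = ""))))
    accidental <- setdiff(hits, starts + 1L)
    if (length(accidental) == 0L) break
    qs <- vapply(accidental, function(p) {
      free <- (p:(p + slen - 1L))[!planted[p:(p + slen - 1L)]]
      if (length(free)) free[1L] else NA_integer_  # inside planted: keep
    }, integer(1))
    qs <- unique(qs[!is.na(qs)])
    if (length(qs) == 0L) break
    shift <- sample.int(3L, length(qs), replace = TRUE)
    chars[qs] <- DNA_BASES[(match(chars[qs], DNA_BASES) - 1L + shift) %%
                             4L + 1L]
  }
  paste(chars, collapse = "")
}

# Read-accessible intervals of a selected fragment: the first and last
# read_length bases (reads start flush at the cut, so only these bases are
# ever sequenced). Marker-safe offsets additionally exclude one site length
# at each fragment boundary, so substituting an allele can never destroy or
# straddle a recognition site.
accessible_intervals <- function(fragments, read_length, site_len) {
  do.call(rbind, lapply(seq_len(nrow(fragments)), function(i) {
    s <- fragments$start[i]; e <- fragments$end[i]
    if (e - s <= 2L * read_length) {
      data.frame(chrom = fragments$chrom[i], start = s, end = e,
                 frag = i, end_label = "LR", stringsAsFactors = FALSE)
    } else {
      data.frame(chrom = fragments$chrom[i],
                 start = c(s, e - read_length),
                 end = c(s + read_length, e),
                 frag = i, end_label = c("L", "R"), stringsAsFactors = FALSE)
    }
  }))
}

safe_positions <- function(fragments, read_length, site_len) {
  out <- vector("list", nrow(fragments))
  for (i in seq_len(nrow(fragments))) {
    s <- fragments$start[i]; e <- fragments$end[i]
    left <- seq.int(s + site_len, min(s + read_length, e) - 1L)
    right <- seq.int(max(e - read_length, s), e - site_len - 1L)
    pos <- unique(sort(c(left, right)))
    out[[i]] <- data.frame(chrom = fragments$chrom[i], pos = pos, frag = i,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# pick an alternative allele at `pos` (0-based) that does not create a new
# recognition-site occurrence in the surrounding window
pick_alt_allele <- function(chrom_seq, pos, enz) {
  slen <- nchar(enz$recognition_site)
  lo <- max(1L, pos + 1L - slen + 1L)
  hi <- min(nchar(chrom_seq), pos + 1L + slen - 1L)
  ctx <- substr(chrom_seq, lo, hi)
  at <- pos + 1L - lo + 1L
  ref <- substr(ctx, at, at)
  for (alt in sample(setdiff(DNA_BASES, ref))) {
    mod <- ctx
    substr(mod, at, at) <- alt
    if (!grepl(enz$recognition_site, mod, fixed = TRUE)) return(alt)
  }
  NA_character_
}

#' Simulate the ground truth of a BSA-RRL study
#'
#' Builds the reference genome (recognition sites planted at roughly
#' `site_density_bp` spacing, none elsewhere), selects the library
#' fragments, plants biallelic marker SNPs inside their read-accessible
#' footprint (one marker coincides with the QTL), and simulates the F2
#' population: each individual carries two recombinant gametes per
#' chromosome generated under the Haldane model, and its phenotype is the
#' QTL-genotype class mean plus Gaussian noise, truncated to `[0, 1]`.
#'
#' @param config A [sim_config()].
#' @return An object of class `"bsa_simulation"`: a list with `config`,
#'   `reference` (named [Biostrings::DNAStringSet]), `fragments` (all
#'   digest fragments), `selected` (size-selected fragments), `snps` (marker
#'   truth table: `chrom`, `pos` 0-based, `parent1`, `parent2`, `cM`,
#'   `is_qtl`), `hap1`/`hap2` (per-chromosome 0/1 gamete matrices,
#'   individuals x markers), `genotypes` (individuals x all markers, codes
#'   0/1/2), `qtl` (list: chrom, pos, genotype vector) and `phenotypes`
#'   (`individual_id`, `ssri`).
#' @export
simulate_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  enz <- config$enzyme
  slen <- nchar(enz$recognition_site)

  chroms <- lapply(config$chrom_names, function(nm)
    build_chromosome(config$chromosome_length_bp, enz, config$site_density_bp))
  names(chroms) <- config$chrom_names
  reference <- Biostrings::DNAStringSet(unlist(chroms))

  fragments <- digest_genome(reference, enz, with_sequence = FALSE)
  selected <- size_select(fragments, config$min_len, config$max_len)
  if (nrow(selected) == 0L)
    stop("no fragments in the size-selection window; increase genome size ",
         "or adjust site_density_bp", call. = FALSE)
  rownames(selected) <- NULL

  safe <- safe_positions(selected, config$read_length, slen)

  # QTL placement
  qtl_chrom <- config$qtl_chrom
  if (is.null(config$qtl_pos_bp)) {
    cand <- safe[safe$chrom == qtl_chrom, ]
    if (nrow(cand) == 0L)
      stop("no selectable fragment on the QTL chromosome", call. = FALSE)
    qtl_pos <- cand$pos[which.min(abs(cand$pos -
                                        config$chromosome_length_bp / 2))]
  } else {
    qtl_pos <- as.integer(config$qtl_pos_bp)
    sel_q <- selected[selected$chrom == qtl_chrom &
                        selected$start <= qtl_pos & selected$end > qtl_pos, ]
    if (nrow(sel_q) == 0L)
      stop("QTL position is not covered by any selectable fragment; ",
           "the association scan could never observe it", call. = FALSE)
    if (!any(safe$chrom == qtl_chrom & safe$pos == qtl_pos))
      stop("QTL position is not read-accessible (fragment interior or ",
           "restriction-site bases)", call. = FALSE)
  }

  # markers: QTL plus a uniform draw over remaining safe positions
  pool <- safe[!(safe$chrom == qtl_chrom & safe$pos == qtl_pos), ]
  n_extra <- config$marker_snp_count - 1L
  if (n_extra > nrow(pool))
    stop("marker_snp_count exceeds available accessible positions",
         call. = FALSE)
  take <- pool[sample.int(nrow(pool), n_extra), ]
  snps <- rbind(take[, c("chrom", "pos")],
                data.frame(chrom = qtl_chrom, pos = qtl_pos))
  snps$is_qtl <- c(rep(FALSE, n_extra), TRUE)
  snps <- snps[order(snps$chrom, snps$pos), ]
  rownames(snps) <- NULL
  snps$parent1 <- mapply(function(ch, p)
    substr(chroms[[ch]], p + 1L, p + 1L), snps$chrom, snps$pos)
  snps$parent2 <- mapply(function(ch, p)
    pick_alt_allele(chroms[[ch]], p, enz), snps$chrom, snps$pos)
  bad <- is.na(snps$parent2)
  if (any(bad)) snps <- snps[!bad, ]
  snps$cM <- snps$pos / config$bp_per_cm
  snps <- snps[, c("chrom", "pos", "parent1", "parent2", "cM", "is_qtl")]

  # F2 gametes per chromosome (Haldane, no interference)
  n <- config$n_individuals
  ids <- sprintf("F2_%03d", seq_len(n))
  sim_gametes <- function(cm) {
    m <- length(cm)
    g <- matrix(0L, n, m)
    g[, 1L] <- stats::rbinom(n, 1L, 0.5)
    if (m > 1L) {
      r <- haldane_r(diff(cm))
      for (j in 2L:m) {
        sw <- stats::rbinom(n, 1L, r[j - 1L])
        g[, j] <- bitwXor(g[, j - 1L], sw)
      }
    }
    g
  }
  hap1 <- hap2 <- list()
  for (ch in config$chrom_names) {
    cm <- snps$cM[snps$chrom == ch]
    if (length(cm) == 0L) next
    h1 <- sim_gametes(cm); h2 <- sim_gametes(cm)
    key <- sprintf("%s:%d", ch, snps$pos[snps$chrom == ch])
    dimnames(h1) <- dimnames(h2) <- list(ids, key)
    hap1[[ch]] <- h1; hap2[[ch]] <- h2
  }
  genotypes <- do.call(cbind, lapply(names(hap1), function(ch)
    hap1[[ch]] + hap2[[ch]]))

  qtl_key <- sprintf("%s:%d", qtl_chrom, qtl_pos)
  qtl_geno <- genotypes[, qtl_key]

  pheno_class <- if (config$qtl_effect) qtl_geno else
    sample(0:2, n, replace = TRUE, prob = c(0.25, 0.5, 0.25))
  ssri <- config$genotype_means[pheno_class + 1L] +
    stats::rnorm(n, 0, config$phenotype_sd)
  ssri <- pmin(1, pmax(0, ssri))

  structure(list(
    config = config, reference = reference, fragments = fragments,
    selected = selected, snps = snps, hap1 = hap1, hap2 = hap2,
    genotypes = genotypes,
    qtl = list(chrom = qtl_chrom, pos = qtl_pos, genotype = qtl_geno),
    phenotypes = data.frame(individual_id = ids, ssri = ssri,
                            stringsAsFactors = FALSE)
  ), class = "bsa_simulation")
}

#' @export
print.bsa_simulation <- function(x, ...) {
  cat(sprintf(paste0(
    "<bsa_simulation> %d chromosomes x %d bp, %d F2 individuals\n",
    "  %d/%d fragments in [%d,%d] bp window, %d marker SNPs\n",
    "  QTL at %s:%d (effect %s)\n"),
    x$config$n_chromosomes, x$config$chromosome_length_bp,
    x$config$n_individuals, nrow(x$selected), nrow(x$fragments),
    x$config$min_len, x$config$max_len, nrow(x$snps),
    x$qtl$chrom, x$qtl$pos, if (x$config$qtl_effect) "on" else "off"))
  invisible(x)
}

# vectorized in-place substring substitution tolerating duplicate targets
apply_subs <- function(strings, idx, at, value) {
  while (length(idx)) {
    first <- !duplicated(idx)
    s <- strings[idx[first]]
    substr(s, at[first], at[first]) <- value[first]
    strings[idx[first]] <- s
    idx <- idx[!first]; at <- at[!first]; value <- value[!first]
  }
  strings
}

#' Simulate restriction-tag reads for the phenotype bulks
#'
#' For each bulk, samples single-end reads from the size-selected fragments
#' of its members' haplotypes: each read starts flush at a fragment end (so
#' it begins with the enzyme's residual tag, e.g. `CT` for AluI), either end
#' being chosen with equal probability; reverse-end reads are emitted
#' reverse-complemented. Enough reads are drawn to reach `target_depth` over
#' the read-accessible footprint, uniform substitution errors are applied at
#' `base_error_rate`, and constant (or profiled) Phred qualities are
#' attached. Because marker alleles are planted away from recognition
#' sites, every haplotype digests identically to the reference, and reads
#' are reference fragment-end windows with the member's alleles substituted.
#'
#' Read names encode the true origin as
#' `<bulk>_<serial>|<chrom>|<start>|<strand>|<member>|h<1|2>`.
#'
#' @param sim A [simulate_truth()] result.
#' @param bulks A [select_bulks()] assignment over the simulated population.
#' @param out_dir Optional directory; when given, `RK.fastq` and `SK.fastq`
#'   (4-line records, Phred+33) are written there.
#' @return A named list of read data.frames (`RK`, `SK`), each with columns
#'   `read_id`, `sequence`, `quality`; file paths attached as attribute
#'   `"paths"` when written.
#' @export
simulate_bulk_reads <- function(sim, bulks, out_dir = NULL) {
  stopifnot(inherits(sim, "bsa_simulation"),
            inherits(bulks, "bulk_assignment"))
  cfg <- sim$config
  set.seed((cfg$seed + 104729L) %% .Machine$integer.max)
  rl <- cfg$read_length
  ids <- sim$phenotypes$individual_id
  members <- list(RK = bulks$rk_ids, SK = bulks$sk_ids)
  for (b in names(members)) {
    if (length(members[[b]]) == 0L) stop("empty bulk: ", b, call. = FALSE)
    if (!all(members[[b]] %in% ids))
      stop("bulk ", b, " contains unknown individuals", call. = FALSE)
  }

  sel <- sim$selected
  nf <- nrow(sel)
  chrom_str <- vapply(seq_along(sim$reference),
                      function(i) as.character(sim$reference[[i]]),
                      character(1))
  names(chrom_str) <- names(sim$reference)

  # forward-strand end windows and the markers they cover
  win_start <- matrix(0L, nf, 2L)   # col 1 = left end, col 2 = right end
  win_start[, 1L] <- sel$start
  win_start[, 2L] <- pmax(sel$end - rl, sel$start)
  win_len <- pmin(sel$length, rl)
  templ <- matrix("", nf, 2L)
  for (e in 1:2)
    templ[, e] <- substr(chrom_str[sel$chrom], win_start[, e] + 1L,
                         win_start[, e] + win_len)
  marker_map <- vector("list", nf)   # per fragment: markers per end
  snp_key <- sprintf("%s:%d", sim$snps$chrom, sim$snps$pos)
  for (i in seq_len(nf)) {
    on_frag <- sim$snps$chrom == sel$chrom[i] &
      sim$snps$pos >= sel$start[i] & sim$snps$pos < sel$end[i]
    if (!any(on_frag)) next
    sub <- sim$snps[on_frag, ]
    marker_map[[i]] <- lapply(1:2, function(e) {
      off <- sub$pos - win_start[i, e]
      keep <- off >= 0L & off < win_len[i]
      data.frame(key = snp_key[on_frag][keep], at = off[keep] + 1L,
                 alt = sub$parent2[keep], stringsAsFactors = FALSE)
    })
  }

  accessible_bp <- sum(pmin(sel$length, 2L * rl))
  n_reads <- max(1L, round(cfg$target_depth * accessible_bp / rl))
  qual_chars <- if (is.null(cfg$quality_profile))
    strrep(intToUtf8(33L + cfg$base_quality), rl) else
      intToUtf8(33L + as.integer(cfg$quality_profile), multiple = FALSE)

  out <- list()
  for (b in names(members)) {
    mem <- sort(members[[b]])
    midx <- sample.int(length(mem), n_reads, replace = TRUE)
    hap <- sample.int(2L, n_reads, replace = TRUE)
    frag <- sample.int(nf, n_reads, replace = TRUE)
    side <- sample.int(2L, n_reads, replace = TRUE)
    seqs <- templ[cbind(frag, side)]
    rows <- match(mem[midx], ids)

    # substitute parent-2 alleles according to the member haplotype
    has_m <- which(!vapply(marker_map, is.null, logical(1)))
    for (i in has_m) {
      for (e in 1:2) {
        mk <- marker_map[[i]][[e]]
        if (nrow(mk) == 0L) next
        rd <- which(frag == i & side == e)
        if (length(rd) == 0L) next
        ch <- sel$chrom[i]
        for (k in seq_len(nrow(mk))) {
          al <- ifelse(hap[rd] == 1L,
                       sim$hap1[[ch]][cbind(rows[rd], match(mk$key[k], colnames(sim$hap1[[ch]])))],
                       sim$hap2[[ch]][cbind(rows[rd], match(mk$key[k], colnames(sim$hap2[[ch]])))])
          carrier <- rd[al == 1L]
          if (length(carrier))
            seqs <- apply_subs(seqs, carrier, rep(mk$at[k], length(carrier)),
                               rep(mk$alt[k], length(carrier)))
        }
      }
    }

    # orientation: right-end reads are sequenced off the other strand
    rev <- which(side == 2L)
    if (length(rev))
      seqs[rev] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(seqs[rev])))

    # sequencing errors
    total_bases <- sum(nchar(seqs))
    ne <- stats::rbinom(1L, total_bases, cfg$base_error_rate)
    if (ne > 0L) {
      gpos <- sample.int(n_reads * rl, ne)  # windows shorter than rl: clamp
      ridx <- (gpos - 1L) %/% rl + 1L
      at <- pmin((gpos - 1L) %% rl + 1L, nchar(seqs[ridx]))
      old <- substring(seqs[ridx], at, at)
      shift <- sample.int(3L, ne, replace = TRUE)
      newb <- DNA_BASES[(match(old, DNA_BASES) - 1L + shift) %% 4L + 1L]
      seqs <- apply_subs(seqs, ridx, at, newb)
    }

    strand <- c("+", "-")[side]
    start0 <- win_start[cbind(frag, side)]
    rid <- sprintf("%s_%06d|%s|%d|%s|%s|h%d", b, seq_len(n_reads),
                   sel$chrom[frag], start0, strand, mem[midx], hap)
    qual <- substr(rep(qual_chars, n_reads), 1L, nchar(seqs))
    out[[b]] <- data.frame(read_id = rid, sequence = seqs, quality = qual,
                           stringsAsFactors = FALSE)
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- vapply(names(out), function(b) {
      p <- file.path(out_dir, paste0(b, ".fastq"))
      write_fastq(out[[b]], p)
      p
    }, character(1))
    attr(out, "paths") <- paths
  }
  out
}

#' Write simulation truth to a directory
#'
#' Emits `reference.fa`, `snps.tsv` (marker truth), `genotypes.tsv`
#' (individuals x markers, codes 0/1/2) and `phenotypes.tsv`.
#'
#' @param sim A [simulate_truth()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "bsa_simulation"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Biostrings::writeXStringSet(sim$reference, file.path(dir, "reference.fa"))
  utils::write.table(sim$snps, file.path(dir, "snps.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  gt <- data.frame(individual_id = rownames(sim$genotypes),
                   sim$genotypes, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(gt, file.path(dir, "genotypes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$phenotypes, file.path(dir, "phenotypes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
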