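# Shared fixtures, built in code. Expensive simulations are cached per test
# session so several test files can reuse them.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

make_reads <- function(sequences, quality_char = "?", ids = NULL) {
  if (is.null(ids)) ids <- sprintf("r%03d", seq_along(sequences))
  data.frame(read_id = ids, sequence = sequences,
             quality = strrep(quality_char, nchar(sequences)),
             stringsAsFactors = FALSE)
}

# small study used by several module tests: 1 chromosome, fast to simulate
small_sim_config <- function(seed, ...) {
  args <- list(seed = seed, n_chromosomes = 1L,
               chromosome_length_bp = 150000L, marker_snp_count = 40L,
               n_individuals = 100L, target_depth = 20)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

default_small_sim <- function() {
  cached("small_sim", simulate_truth(small_sim_config(42)))
}

# full-size default-condition study shared between tests
default_sim <- function() {
  cached("default_sim", simulate_truth(sim_config(42)))
}

# brute-force digestion oracle: scan every substring for the site
oracle_digest_lengths <- function(seq, enz) {
  site <- enz$recognition_site
  slen <- nchar(site)
  n <- nchar(seq)
  # regex with IUPAC classes
  classes <- c(A = "A", C = "C", G = "G", T = "T", R = "[AG]", Y = "[CT]",
               S = "[CG]", W = "[AT]", K = "[GT]", M = "[AC]",
               B = "[CGT]", D = "[AGT]", H = "[ACT]", V = "[ACG]",
               N = "[ACGT]")
  rx <- paste(classes[strsplit(site, "")[[1]]], collapse = "")
  cuts <- integer()
  if (n >= slen)
    for (p in seq_len(n - slen + 1L))
      if (grepl(paste0("^", rx, "$"), substr(seq, p, p + slen - 1L)))
        cuts <- c(cuts, p - 1L + enz$cut_offset)
  cuts <- sort(unique(cuts[cuts > 0L & cuts < n]))
  diff(c(0L, cuts, n))
}

# brute-force anchored-window cluster oracle (O(n^2))
oracle_clusters <- function(snps, window_bp, min_count) {
  out <- list()
  for (ch in unique(snps$chrom)) {
    pos <- sort(snps$pos[snps$chrom == ch])
    qual <- list()
    for (i in seq_along(pos)) {
      inw <- pos[pos >= pos[i] & pos < pos[i] + window_bp]
      if (length(inw) >= min_count)
        qual[[length(qual) + 1L]] <- c(pos[i], pos[i] + window_bp)
    }
    if (!length(qual)) next
    qual <- do.call(rbind, qual)
    qual <- qual[order(qual[, 1L]), , drop = FALSE]
    merged <- list(qual[1L, ])
    for (k in seq_len(nrow(qual))[-1L]) {
      last <- merged[[length(merged)]]
      if (qual[k, 1L] <= last[2L])
        merged[[length(merged)]] <- c(last[1L], max(last[2L], qual[k, 2L]))
      else merged[[length(merged) + 1L]] <- qual[k, ]
    }
    for (mw in merged) {
      members <- pos[pos >= mw[1L] & pos < mw[2L]]
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = min(members), end = max(members) + 1L,
        snp_count = length(members), stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(data.frame(chrom = character(), start = integer(),
                                      end = integer(),
                                      snp_count = integer()))
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start), ]
}
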