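#' Pipeline configuration
#'
#' Collects every stage parameter of the end-to-end BSA-RRL pipeline; all
#' module constraints are re-validated here, before any stage runs. With no
#' input paths the pipeline runs in demonstration mode on fully synthetic
#' data; supplying `reference`, `rk_fastq`/`sk_fastq` and `phenotypes`
#' paths runs the same stages on user data.
#'
#' @param seed Integer seed for the synthetic stages.
#' @param enzyme Library [enzyme()] (default AluI).
#' @param min_len,max_len Fragment size-selection window (bp).
#' @param low_cut,high_cut,bulk_size Bulk selection (see [select_bulks()]).
#' @param boundaries Segregation class boundaries (see
#'   [segregation_chi_square()]).
#' @param min_mean_q Mean-quality threshold (see [quality_filter()]).
#' @param apply_tag_filter Toggle the residual-tag filter.
#' @param repeat_threshold Repeat flagging threshold (see [place_reads()]).
#' @param min_depth_per_bulk,max_minor_fraction Simple-SNP calling (see
#'   [call_simple_snps()]).
#' @param neg_log10_p Association threshold (see [score_and_threshold()]).
#' @param ladder Threshold ladder reported alongside.
#' @param cluster_window_bp,cluster_min_count Cluster scan (see
#'   [scan_clusters()]).
#' @param reference,rk_fastq,sk_fastq,phenotypes Optional input paths; all
#'   or none of reference + fastqs must be given.
#' @param variants Optional TSV of known biallelic sites (`chrom`, `pos`
#'   0-based, `parent1`, `parent2`) extending the placement index to the
#'   second parental haplotype (see [build_index()]); used in file mode
#'   only.
#' @param sim A [sim_config()] for demonstration mode; defaults to
#'   `sim_config(seed)` with the parameters above folded in.
#' @return An object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(seed = 1L,
                            enzyme = blunt_enzymes()$AluI,
                            min_len = 450L, max_len = 550L,
                            low_cut = 0.10, high_cut = 0.90,
                            bulk_size = 10L,
                            boundaries = c(0.30, 0.70),
                            min_mean_q = 25,
                            apply_tag_filter = TRUE,
                            repeat_threshold = 100L,
                            min_depth_per_bulk = 4L,
                            max_minor_fraction = 0.1,
                            neg_log10_p = 16,
                            ladder = c(2, 5, 10, 16),
                            cluster_window_bp = 400000L,
                            cluster_min_count = 5L,
                            reference = NULL, rk_fastq = NULL,
                            sk_fastq = NULL, phenotypes = NULL,
                            variants = NULL, sim = NULL) {
  stopifnot(inherits(enzyme, "enzyme"), min_len <= max_len,
            low_cut < high_cut, bulk_size >= 1L, min_mean_q >= 0,
            repeat_threshold >= 1L, min_depth_per_bulk >= 1L,
            max_minor_fraction >= 0 && max_minor_fraction < 1,
            neg_log10_p >= 0)
  if (length(boundaries) != 2L || !(boundaries[1] < boundaries[2]))
    stop("boundaries must be a strictly increasing pair", call. = FALSE)
  if (cluster_window_bp <= 0L)
    stop("cluster_window_bp must be positive", call. = FALSE)
  if (cluster_min_count < 2L)
    stop("cluster_min_count must be at least 2", call. = FALSE)
  file_inputs <- c(reference = !is.null(reference),
                   rk = !is.null(rk_fastq), sk = !is.null(sk_fastq))
  if (any(file_inputs) && !all(file_inputs))
    stop("supply reference, rk_fastq and sk_fastq together", call. = FALSE)
  simulate <- !any(file_inputs)
  if (simulate && is.null(sim))
    sim <- sim_config(seed, enzyme = enzyme, min_len = min_len,
                      max_len = max_len, bulk_size = bulk_size)
  structure(list(
    seed = as.integer(seed), enzyme = enzyme,
    min_len = as.integer(min_len), max_len = as.integer(max_len),
    low_cut = low_cut, high_cut = high_cut,
    bulk_size = as.integer(bulk_size), boundaries = boundaries,
    min_mean_q = min_mean_q, apply_tag_filter = isTRUE(apply_tag_filter),
    repeat_threshold = as.integer(repeat_threshold),
    min_depth_per_bulk = as.integer(min_depth_per_bulk),
    max_minor_fraction = max_minor_fraction, neg_log10_p = neg_log10_p,
    ladder = ladder,
    cluster_window_bp = as.integer(cluster_window_bp),
    cluster_min_count = as.integer(cluster_min_count),
    reference = reference, rk_fastq = rk_fastq, sk_fastq = sk_fastq,
    phenotypes = phenotypes, variants = variants,
    simulate = simulate, sim = sim
  ), class = "pipeline_config")
}

#' Read a flat key=value pipeline configuration file
#'
#' Lines of the form `key = value`; `#` starts a comment. Keys are the
#' arguments of [pipeline_config()] (enzymes by name among the shipped
#' [blunt_enzymes()]; `boundaries`/`ladder` as comma-separated numbers).
#' Unknown keys are an error.
#'
#' @param path Config file path.
#' @param overrides Named list overriding file values (e.g. parsed CLI
#'   flags).
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path, overrides = list()) {
  if (!file.exists(path)) stop("cannot read config file: ", path,
                               call. = FALSE)
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- vapply(kv, length, integer(1)) != 2L
  if (any(bad)) stop("malformed config line: ", lines[bad][1], call. = FALSE)
  vals <- stats::setNames(lapply(kv, `[[`, 2L), vapply(kv, `[[`, 1L,
                                                       FUN.VALUE = ""))
  vals[names(overrides)] <- overrides
  numeric_keys <- c("seed", "min_len", "max_len", "low_cut", "high_cut",
                    "bulk_size", "min_mean_q", "repeat_threshold",
                    "min_depth_per_bulk", "max_minor_fraction",
                    "neg_log10_p", "cluster_window_bp", "cluster_min_count")
  args <- list()
  for (key in names(vals)) {
    v <- vals[[key]]
    args[[key]] <- switch(key,
      enzyme = {
        enzlist <- blunt_enzymes()
        if (!v %in% names(enzlist))
          stop("unknown enzyme in config: ", v, call. = FALSE)
        enzlist[[v]]
      },
      apply_tag_filter = toupper(v) %in% c("TRUE", "1", "YES", "ON"),
      boundaries = , ladder = as.numeric(strsplit(v, ",")[[1]]),
      reference = , rk_fastq = , sk_fastq = , phenotypes = , variants = v,
      {
        if (!key %in% numeric_keys)
          stop("unknown config key: ", key, call. = FALSE)
        as.numeric(v)
      })
  }
  do.call(pipeline_config, args)
}

log_stage <- function(stage, ...) {
  message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"),
                  stage, sprintf(...)))
}

write_stage_tsv <- function(df, path, params = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(params))
    writeLines(sprintf("# %s", paste(names(params), unlist(params),
                                     sep = "=", collapse = " ")), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full BSA-RRL pipeline
#'
#' Executes phenotyping, bulk selection, the enzyme digest survey, read QC,
#' placement, SNP association and the cluster scan, writing every stage
#' report into `out_dir` together with a `MANIFEST` marking stage
#' completion. Identical configuration and seed give byte-identical
#' outputs. A stage failure aborts the run with the stage name; outputs of
#' completed stages are retained.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Run directory (created if needed).
#' @return Invisibly, a list with the in-memory results of every stage
#'   (`simulation`, `phenotypes`, `segregation`, `bulks`, `digest_survey`,
#'   `qc`, `mapping`, `snps`, `ladder`, `clusters`, `distribution`).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest_path <- file.path(out_dir, "MANIFEST")
  done <- character()
  note_done <- function(stage) {
    done <<- c(done, stage)
    writeLines(sprintf("%s\tdone", done), manifest_path)
  }
  run_stage <- function(stage, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE))
    log_stage(stage, "done in %.1fs",
              as.numeric(difftime(Sys.time(), t0, units = "secs")))
    note_done(stage)
    res
  }
  results <- list()

  # --- inputs -------------------------------------------------------------
  sim <- NULL
  if (config$simulate) {
    sim <- run_stage("simulate", simulate_truth(config$sim))
    results$simulation <- sim
    reference <- sim$reference
    phen <- sim$phenotypes
  } else {
    reference <- as_genome(config$reference)
    phen <- if (!is.null(config$phenotypes))
      read_phenotypes(config$phenotypes) else NULL
  }

  # --- phenotyping and bulks ---------------------------------------------
  bulks <- NULL
  if (!is.null(phen)) {
    results$phenotypes <- phen
    results$segregation <- run_stage("phenotype", {
      seg <- segregation_chi_square(phen, config$boundaries)
      write_stage_tsv(phen, file.path(out_dir, "phenotypes.tsv"))
      write_stage_tsv(
        data.frame(statistic = seg$statistic, p_value = seg$p_value,
                   n_low = seg$counts["low"], n_mid = seg$counts["mid"],
                   n_high = seg$counts["high"]),
        file.path(out_dir, "segregation.tsv"),
        params = list(boundaries = paste(config$boundaries, collapse = ",")))
      seg
    })
    bulks <- run_stage("select-bulks", {
      b <- select_bulks(phen, config$low_cut, config$high_cut,
                        config$bulk_size)
      write_bulks(b, file.path(out_dir, "bulks.tsv"))
      b
    })
    results$bulks <- bulks
  }

  # --- digest survey ------------------------------------------------------
  results$digest_survey <- run_stage("digest-scan", {
    rep <- rank_enzymes(reference, min_len = config$min_len,
                        max_len = config$max_len)
    write_digest_report(rep, file.path(out_dir, "digest_report.tsv"))
    rep
  })

  # --- reads --------------------------------------------------------------
  reads <- run_stage("reads", {
    if (config$simulate) {
      simulate_bulk_reads(sim, bulks)
    } else {
      list(RK = read_fastq(config$rk_fastq),
           SK = read_fastq(config$sk_fastq))
    }
  })

  # --- qc -----------------------------------------------------------------
  qc <- run_stage("qc", {
    res <- lapply(names(reads), function(b) {
      if (config$apply_tag_filter)
        run_qc(reads[[b]], config$enzyme, config$min_mean_q,
               library_name = b)
      else {
        qf <- quality_filter(reads[[b]], config$min_mean_q)
        list(reads = qf$reads,
             report = data.frame(library = b, total = nrow(reads[[b]]),
                                 tag_present = NA_integer_,
                                 tag_present_pct = NA_real_,
                                 pass_qc = unname(qf$counts["pass"]),
                                 pass_qc_pct = 100 *
                                   unname(qf$counts["pass"]) /
                                   max(1L, nrow(reads[[b]]))))
      }
    })
    names(res) <- names(reads)
    report <- do.call(rbind, lapply(res, `[[`, "report"))
    write_stage_tsv(report, file.path(out_dir, "qc_report.tsv"),
                    params = list(min_mean_q = config$min_mean_q,
                                  tag = residual_tag(config$enzyme)))
    res
  })
  results$qc <- lapply(qc, `[[`, "report")

  # --- mapping ------------------------------------------------------------
  mapping <- run_stage("map", {
    all_reads <- do.call(rbind, lapply(names(qc), function(b) {
      r <- qc[[b]]$reads
      if (nrow(r)) r$bulk <- b
      r
    }))
    variants <- if (config$simulate) sim$snps else
      if (!is.null(config$variants)) utils::read.table(
        config$variants, header = TRUE, sep = "\t",
        stringsAsFactors = FALSE) else NULL
    idx <- build_index(reference, nchar(all_reads$sequence[1]),
                       variants = variants)
    pr <- place_reads(all_reads, idx, config$repeat_threshold)
    write_placements(pr$placements, file.path(out_dir, "placements.tsv"))
    write_stage_tsv(pr$report, file.path(out_dir, "mapping_report.tsv"),
                    params = list(repeat_threshold = config$repeat_threshold))
    c(pr, list(reads = all_reads))
  })
  results$mapping <- mapping$report

  # --- snp association ----------------------------------------------------
  snps <- run_stage("call-snps", {
    pu <- pileup(mapping$placements, mapping$reads, reference)
    cand <- call_simple_snps(pu, config$min_depth_per_bulk,
                             config$max_minor_fraction)
    sc <- score_and_threshold(cand, config$neg_log10_p)
    write_snp_table(sc$scored, file.path(out_dir, "snps_scored.tsv"))
    write_snp_table(sc$associated, file.path(out_dir, "snps_associated.tsv"))
    write_snp_vcf(sc$associated, file.path(out_dir, "snps_associated.vcf"),
                  reference = reference)
    sc
  })
  results$snps <- snps
  results$ladder <- run_stage("ladder", {
    lad <- threshold_ladder(snps$scored, config$ladder)
    write_stage_tsv(lad, file.path(out_dir, "threshold_ladder.tsv"))
    lad
  })

  # --- clusters -----------------------------------------------------------
  results$clusters <- run_stage("scan-clusters", {
    cl <- scan_clusters(snps$associated, config$cluster_window_bp,
                        config$cluster_min_count)
    write_clusters(cl, bed_path = file.path(out_dir, "clusters.bed"),
                   tsv_path = file.path(out_dir, "clusters.tsv"))
    cl
  })
  results$distribution <- run_stage("distribution", {
    dist <- summarize_distribution(
      snps$associated,
      stats::setNames(Biostrings::width(reference), names(reference)))
    write_stage_tsv(dist, file.path(out_dir, "distribution.tsv"))
    dist
  })

  writeLines(sprintf("%s\tdone", done), manifest_path)
  invisible(results)
}
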