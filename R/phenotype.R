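#' Silique shattering resistance index (SSRI)
#'
#' From a random impact test -- `n_replicates` drums of `pods_per_replicate`
#' intact pods shaken with steel balls, counting broken and damaged pods per
#' replicate -- the index is
#' \deqn{SSRI = 1 - \frac{\sum_i x_i}{N \cdot P}}
#' where `x_i` is the broken-pod count of replicate `i`, `N` the number of
#' replicates and `P` the pods per replicate. 1 means fully resistant (no
#' pod broke), 0 fully susceptible.
#'
#' @param replicate_counts Non-negative integer vector of broken/damaged pod
#'   counts, one per replicate.
#' @param pods_per_replicate Pods loaded per replicate (default 20).
#' @return SSRI in `[0, 1]`.
#' @examples
#' compute_ssri(c(1, 2, 1, 0, 3, 1, 2, 0, 1, 1))  # 0.94
#' @export
compute_ssri <- function(replicate_counts, pods_per_replicate = 20L) {
  if (length(replicate_counts) == 0L)
    stop("replicate_counts is empty", call. = FALSE)
  if (anyNA(replicate_counts) || any(replicate_counts < 0))
    stop("replicate counts must be non-negative", call. = FALSE)
  if (length(pods_per_replicate) != 1L || pods_per_replicate < 1)
    stop("pods_per_replicate must be a positive scalar", call. = FALSE)
  if (any(replicate_counts > pods_per_replicate))
    stop("a replicate count exceeds pods_per_replicate", call. = FALSE)
  1 - sum(replicate_counts) / (length(replicate_counts) * pods_per_replicate)
}

#' Phenotype table from impact-test records
#'
#' Computes one SSRI per record and averages repeated assays of the same
#' individual (accessions are typically tested twice and averaged).
#'
#' @param impact A data.frame with column `individual_id` and one column per
#'   replicate count (any columns other than `individual_id`, e.g.
#'   `rep1..repN`). One row per assay; repeated rows per individual are
#'   averaged.
#' @param pods_per_replicate Pods per replicate (default 20).
#' @return A data.frame `(individual_id, ssri)`, one row per individual, in
#'   order of first appearance.
#' @export
phenotypes_from_impact <- function(impact, pods_per_replicate = 20L) {
  stopifnot(is.data.frame(impact), "individual_id" %in% names(impact))
  repcols <- setdiff(names(impact), "individual_id")
  if (length(repcols) == 0L)
    stop("no replicate-count columns found", call. = FALSE)
  per_assay <- vapply(seq_len(nrow(impact)), function(i)
    compute_ssri(as.numeric(impact[i, repcols]), pods_per_replicate),
    numeric(1))
  ids <- as.character(impact$individual_id)
  means <- tapply(per_assay, ids, mean)
  first <- ids[!duplicated(ids)]
  data.frame(individual_id = first, ssri = as.numeric(means[first]),
             stringsAsFactors = FALSE)
}

#' Read a phenotype TSV
#'
#' Accepts either a precomputed index (`individual_id`, `ssri`) or raw
#' impact-test counts (`individual_id` plus replicate columns), with header.
#'
#' @param path TSV path.
#' @param pods_per_replicate Pods per replicate when counts are supplied.
#' @return A data.frame `(individual_id, ssri)`.
#' @export
read_phenotypes <- function(path, pods_per_replicate = 20L) {
  if (!file.exists(path)) stop("cannot read phenotype file: ", path,
                               call. = FALSE)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!"individual_id" %in% names(tab))
    stop("phenotype table lacks an individual_id column", call. = FALSE)
  if ("ssri" %in% names(tab)) {
    out <- data.frame(individual_id = as.character(tab$individual_id),
                      ssri = as.numeric(tab$ssri), stringsAsFactors = FALSE)
    if (any(is.na(out$ssri) | out$ssri < 0 | out$ssri > 1))
      stop("ssri values must lie in [0, 1]", call. = FALSE)
    return(out)
  }
  phenotypes_from_impact(tab, pods_per_replicate)
}

#' Chi-square test of 1:2:1 segregation
#'
#' Classifies individuals into low/mid/high phenotype classes at the given
#' boundaries and tests the class counts against the 1:2:1 ratio expected
#' for a single codominant locus in an F2 (Pearson chi-square, 2 df).
#'
#' Class boundaries must be located by the analyst (e.g. from the antimodes
#' of the phenotype distribution); the defaults `(0.30, 0.70)` suit an index
#' with genotype-class modes near 0.06 / 0.50 / 0.94. Values below the first
#' boundary are "low", above the second "high", boundary values "mid".
#'
#' @param phenotypes A numeric vector of index values, or a data.frame with
#'   an `ssri` column.
#' @param boundaries Strictly increasing pair of class boundaries.
#' @return A list with `statistic`, `p_value`, `counts` (named low/mid/high)
#'   and `expected`.
#' @export
segregation_chi_square <- function(phenotypes, boundaries = c(0.30, 0.70)) {
  x <- if (is.data.frame(phenotypes)) phenotypes$ssri else phenotypes
  stopifnot(is.numeric(x))
  if (length(boundaries) != 2L || !(boundaries[1] < boundaries[2]))
    stop("boundaries must be a strictly increasing pair", call. = FALSE)
  if (length(x) < 3L)
    stop("need at least 3 individuals", call. = FALSE)
  counts <- c(low = sum(x < boundaries[1]),
              mid = sum(x >= boundaries[1] & x <= boundaries[2]),
              high = sum(x > boundaries[2]))
  ht <- suppressWarnings(
    stats::chisq.test(counts, p = c(0.25, 0.50, 0.25)))
  list(statistic = unname(ht$statistic), p_value = unname(ht$p.value),
       counts = counts, expected = unname(ht$expected))
}

#' Assign extreme individuals to phenotype bulks
#'
#' Selects the `bulk_size` lowest-index individuals with index strictly
#' below `low_cut` as the susceptible bulk (SK) and the `bulk_size` highest
#' with index strictly above `high_cut` as the resistant bulk (RK). Ties are
#' broken by `individual_id` (lexicographic), so the result does not depend
#' on input order.
#'
#' @param phenotypes A data.frame `(individual_id, ssri)`.
#' @param low_cut,high_cut Strict qualification cuts (defaults 0.10 / 0.90).
#' @param bulk_size Individuals per bulk (default 10).
#' @return An object of class `"bulk_assignment"`: a list with `sk_ids`,
#'   `rk_ids`, the cuts and `bulk_size`.
#' @export
select_bulks <- function(phenotypes, low_cut = 0.10, high_cut = 0.90,
                         bulk_size = 10L) {
  stopifnot(is.data.frame(phenotypes),
            all(c("individual_id", "ssri") %in% names(phenotypes)))
  if (!(low_cut < high_cut))
    stop("low_cut must be below high_cut", call. = FALSE)
  bulk_size <- as.integer(bulk_size)
  if (bulk_size < 1L) stop("bulk_size must be positive", call. = FALSE)
  if (anyDuplicated(phenotypes$individual_id))
    stop("duplicated individual_id in phenotype table", call. = FALSE)
  ids <- as.character(phenotypes$individual_id)
  ssri <- phenotypes$ssri

  low_q <- which(ssri < low_cut)
  high_q <- which(ssri > high_cut)
  deficient <- c(
    if (length(low_q) < bulk_size) sprintf(
      "susceptible tail (SSRI < %g): %d qualifying, %d needed",
      low_cut, length(low_q), bulk_size),
    if (length(high_q) < bulk_size) sprintf(
      "resistant tail (SSRI > %g): %d qualifying, %d needed",
      high_cut, length(high_q), bulk_size))
  if (length(deficient))
    stop("insufficient extremes -- ", paste(deficient, collapse = "; "),
         call. = FALSE)

  sk <- low_q[order(ssri[low_q], ids[low_q])][seq_len(bulk_size)]
  rk <- high_q[order(-ssri[high_q], ids[high_q])][seq_len(bulk_size)]
  structure(list(sk_ids = ids[sk], rk_ids = ids[rk],
                 low_cut = low_cut, high_cut = high_cut,
                 bulk_size = bulk_size),
            class = "bulk_assignment")
}

#' @export
print.bulk_assignment <- function(x, ...) {
  cat(sprintf("<bulk_assignment> %d per bulk (SK: SSRI < %g, RK: SSRI > %g)\n",
              x$bulk_size, x$low_cut, x$high_cut))
  cat(" SK:", paste(x$sk_ids, collapse = " "), "\n")
  cat(" RK:", paste(x$rk_ids, collapse = " "), "\n")
  invisible(x)
}

#' Write a bulk assignment as two-column TSV
#'
#' @param bulks A [select_bulks()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bulks <- function(bulks, path) {
  stopifnot(inherits(bulks, "bulk_assignment"))
  tab <- data.frame(
    individual_id = c(bulks$sk_ids, bulks$rk_ids),
    bulk = rep(c("SK", "RK"), times = c(length(bulks$sk_ids),
                                        length(bulks$rk_ids))),
    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
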