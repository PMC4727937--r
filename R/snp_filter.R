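#' Filter configuration for the SNP quality cascade
#'
#' @param poisson_percentile per-replicate high-coverage cut: rows above
#'   this percentile of a Poisson with lambda = median coverage are
#'   dropped (default 0.99).
#' @param tail_quantile symmetric coverage trim applied to the combined
#'   table (default 0.01, i.e. the top and bottom 1% of coverage).
#' @param flags_to_drop panel flags whose rows are removed (subset of
#'   `"ambiguous_reference"`, `"mismatch"`).
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(poisson_percentile = 0.99, tail_quantile = 0.01,
                          flags_to_drop = c("ambiguous_reference",
                                            "mismatch")) {
  stopifnot(poisson_percentile > 0, poisson_percentile < 1,
            tail_quantile >= 0, tail_quantile < 0.5,
            all(flags_to_drop %in% c("ambiguous_reference", "mismatch")))
  structure(list(poisson_percentile = poisson_percentile,
                 tail_quantile = tail_quantile,
                 flags_to_drop = flags_to_drop),
            class = "filter_config")
}

#' Build the informative SNP panel from two accession SNP lists
#'
#' Keeps every position where the two accessions carry different alleles,
#' taking the reference base where an accession has no record; positions
#' where both accessions share the same variant are removed.
#'
#' @param snp_list_A,snp_list_B data frames as returned by
#'   [read_snp_list()], with columns `chrom`, `pos`, `ref`, `alt`.
#' @return A [snp_panel()] with allele_A from accession A and allele_B
#'   from accession B.
#' @export
build_informative_panel <- function(snp_list_A, snp_list_B) {
  need <- c("chrom", "pos", "ref", "alt")
  stopifnot(all(need %in% names(snp_list_A)),
            all(need %in% names(snp_list_B)))
  merged <- merge(snp_list_A[need], snp_list_B[need],
                  by = c("chrom", "pos"), all = TRUE,
                  suffixes = c("_A", "_B"))
  both <- !is.na(merged$alt_A) & !is.na(merged$alt_B)
  if (any(both & merged$ref_A != merged$ref_B))
    stop("reference base disagrees between the two SNP lists")
  allele_A <- ifelse(is.na(merged$alt_A), merged$ref_B, merged$alt_A)
  allele_B <- ifelse(is.na(merged$alt_B), merged$ref_A, merged$alt_B)
  keep <- allele_A != allele_B  # drops SNPs common to both accessions
  merged <- merged[keep, , drop = FALSE]
  ord <- order(merged$chrom, merged$pos)
  merged <- merged[ord, , drop = FALSE]
  snp_panel(merged$chrom, merged$pos,
            allele_A[keep][ord], allele_B[keep][ord])
}

#' Drop panel-flagged SNPs from a count table
#'
#' Removes rows whose panel flags intersect `flags_to_drop` (positions
#' ambiguous in the reference, or mismatching the published SNP lists).
#'
#' @param table a [snp_table()], positions a subset of the panel.
#' @param panel a `snp_panel`.
#' @param config a [filter_config()].
#' @return The filtered `snp_table`.
#' @export
drop_flagged <- function(table, panel, config = filter_config()) {
  key_t <- paste(table$chrom, table$pos)
  key_p <- paste(panel$chrom, panel$pos)
  idx <- match(key_t, key_p)
  if (anyNA(idx))
    stop("table contains positions absent from the panel (first: ",
         key_t[which(is.na(idx))[1]], ")")
  bad <- rep(FALSE, nrow(table))
  if ("ambiguous_reference" %in% config$flags_to_drop)
    bad <- bad | panel$flag_ambiguous[idx]
  if ("mismatch" %in% config$flags_to_drop)
    bad <- bad | panel$flag_mismatch[idx]
  .keep_rows(table, !bad)
}

#' Remove SNPs with implausibly high coverage
#'
#' Computes lambda as the median per-SNP coverage of the table and removes
#' rows whose coverage is strictly above the `poisson_percentile` quantile
#' of a Poisson(lambda) distribution (the smallest integer k whose CDF
#' reaches the percentile).
#'
#' @inheritParams drop_flagged
#' @return The filtered `snp_table`.
#' @export
filter_high_coverage <- function(table, config = filter_config()) {
  if (nrow(table) == 0) stop("empty table")
  cov <- snp_coverage(table)
  lambda <- median(cov)
  cutoff <- qpois(config$poisson_percentile, lambda)
  .keep_rows(table, cov <= cutoff)
}

#' Combine replicate tables by summing read counts per SNP
#'
#' Takes the union of positions; per position, `count_A` and `count_B` are
#' summed across replicates (replicates lacking a position contribute 0).
#' The replicate id of the result is cleared.
#'
#' @param tables a list of [snp_table()]s from the same pool.
#' @return A combined `snp_table`.
#' @export
combine_replicates <- function(tables) {
  if (!is.list(tables) || length(tables) == 0)
    stop("need at least one replicate table")
  pools <- unique(unlist(lapply(tables, attr, "pool")))
  if (length(pools) > 1)
    stop("replicates come from different pools: ",
         paste(pools, collapse = ", "))
  for (t in tables) .validate_snp_positions(t)
  all <- do.call(rbind, lapply(tables, as.data.frame))
  agg <- stats::aggregate(cbind(count_A, count_B) ~ chrom + pos, data = all,
                          FUN = sum)
  agg <- agg[order(agg$chrom, agg$pos), , drop = FALSE]
  snp_table(agg$chrom, agg$pos, agg$count_A, agg$count_B,
            pool = if (length(pools)) pools else NULL)
}

#' Discard SNPs lacking reads for either allele
#'
#' Rows of the combined table with `count_A == 0` or `count_B == 0` are
#' removed.
#'
#' @param table a combined [snp_table()].
#' @return The filtered `snp_table`.
#' @export
drop_monoallelic <- function(table) {
  .keep_rows(table, table$count_A > 0 & table$count_B > 0)
}

#' Trim the coverage distribution tails
#'
#' Removes rows whose coverage falls strictly outside the closed interval
#' between the `tail_quantile` and `1 - tail_quantile` empirical coverage
#' quantiles (linear interpolation between order statistics, quantile
#' type 7).
#'
#' @inheritParams drop_flagged
#' @return The filtered `snp_table`.
#' @export
trim_coverage_quantiles <- function(table, config = filter_config()) {
  if (nrow(table) == 0) stop("empty table")
  q <- config$tail_quantile
  if (q == 0) return(table)
  cov <- snp_coverage(table)
  bounds <- quantile(cov, c(q, 1 - q), type = 7, names = FALSE)
  .keep_rows(table, cov >= bounds[1] & cov <= bounds[2])
}

#' Run the full per-pool filter cascade
#'
#' Per replicate: [drop_flagged()] then [filter_high_coverage()]; the
#' replicates are then combined with [combine_replicates()], and the
#' combined table passes [drop_monoallelic()] and
#' [trim_coverage_quantiles()]. Stage-by-stage row counts are recorded.
#'
#' @param tables list of per-replicate [snp_table()]s for one pool.
#' @param panel a `snp_panel`.
#' @param config a [filter_config()].
#' @return A list with `table` (the filtered combined `snp_table`) and
#'   `report` (data frame of stage names and row counts).
#' @export
filter_pipeline <- function(tables, panel, config = filter_config()) {
  stages <- character(0); rows <- integer(0)
  note <- function(stage, n) {
    stages <<- c(stages, stage); rows <<- c(rows, n)
  }
  filtered <- lapply(seq_along(tables), function(i) {
    t <- tables[[i]]
    note(sprintf("replicate_%d_input", i), nrow(t))
    t <- drop_flagged(t, panel, config)
    note(sprintf("replicate_%d_drop_flagged", i), nrow(t))
    t <- filter_high_coverage(t, config)
    note(sprintf("replicate_%d_high_coverage", i), nrow(t))
    t
  })
  combined <- combine_replicates(filtered)
  note("combined", nrow(combined))
  combined <- drop_monoallelic(combined)
  note("drop_monoallelic", nrow(combined))
  combined <- trim_coverage_quantiles(combined, config)
  note("trim_coverage_quantiles", nrow(combined))
  list(table = combined, report = data.frame(stage = stages, rows = rows))
}
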