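#' Per-SNP biallelic read-count table
#'
#' The unit that flows through the filtering cascade: one row per SNP with
#' counts of reads supporting the maternal-accession allele (A) and the
#' paternal-accession allele (B). Pool label and replicate id are carried
#' as attributes; the replicate id is cleared by [combine_replicates()].
#'
#' @param chrom chromosome names.
#' @param pos 1-based physical positions, unique and sorted within
#'   chromosomes.
#' @param count_A,count_B nonnegative integer read counts.
#' @param pool optional pool label (e.g. `"mea"`, `"WT"`).
#' @param replicate optional replicate id.
#' @return A data frame of class `snp_table`.
#' @export
snp_table <- function(chrom, pos, count_A, count_B,
                      pool = NULL, replicate = NULL) {
  n <- length(pos)
  chrom <- rep_len(as.character(chrom), n)
  pos <- as.integer(pos)
  count_A <- rep_len(as.integer(count_A), n)
  count_B <- rep_len(as.integer(count_B), n)
  if (any(count_A < 0) || any(count_B < 0))
    stop("read counts must be nonnegative")
  tab <- data.frame(chrom = chrom, pos = pos,
                    count_A = count_A, count_B = count_B)
  .validate_snp_positions(tab)
  .as_snp_table(tab, pool = pool, replicate = replicate)
}

.validate_snp_positions <- function(tab) {
  key <- paste(tab$chrom, tab$pos)
  if (anyDuplicated(key))
    stop("duplicate SNP positions within a table")
  for (nm in unique(tab$chrom)) {
    p <- tab$pos[tab$chrom == nm]
    if (is.unsorted(p))
      stop("positions must be sorted within chromosome ", nm)
  }
  invisible(tab)
}

.as_snp_table <- function(tab, pool = NULL, replicate = NULL) {
  rownames(tab) <- NULL
  class(tab) <- c("snp_table", "data.frame")
  attr(tab, "pool") <- pool
  attr(tab, "replicate") <- replicate
  tab
}

# Row subsetting that preserves snp_table metadata (filters are row-subset
# operations and must not touch counts or attributes).
.keep_rows <- function(tab, keep) {
  out <- tab[keep, , drop = FALSE]
  .as_snp_table(as.data.frame(out),
                pool = attr(tab, "pool"),
                replicate = attr(tab, "replicate"))
}

#' @export
print.snp_table <- function(x, ...) {
  cat(sprintf("snp_table: %d SNPs, %d chromosome(s)%s%s\n",
              nrow(x), length(unique(x$chrom)),
              if (!is.null(attr(x, "pool")))
                paste0(", pool=", attr(x, "pool")) else "",
              if (!is.null(attr(x, "replicate")))
                paste0(", replicate=", attr(x, "replicate")) else ""))
  print(utils::head(as.data.frame(x)), ...)
  invisible(x)
}

#' Total read coverage per SNP
#'
#' @param table a `snp_table`.
#' @return Integer vector `count_A + count_B`.
#' @export
snp_coverage <- function(table) table$count_A + table$count_B
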