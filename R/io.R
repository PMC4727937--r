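#' Read an accession SNP list
#'
#' Tab-delimited rows of (chromosome, 1-based position, reference base,
#' accession base), optional header, `#` comment lines ignored.
#'
#' @param path file path.
#' @return Data frame with columns `chrom`, `pos`, `ref`, `alt`, sorted by
#'   chromosome and position.
#' @export
read_snp_list <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  lines <- lines[keep]
  line_no <- which(keep)
  if (length(lines) == 0) {
    warning("empty SNP list: ", path)
    return(data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  # optional single header line: position field not numeric
  if (suppressWarnings(is.na(as.integer(fields[[1]][2])))) {
    fields <- fields[-1]; line_no <- line_no[-1]
  }
  bad_len <- which(lengths(fields) < 4)
  if (length(bad_len))
    stop("malformed SNP list row at line ", line_no[bad_len[1]],
         ": expected 4 tab-separated fields")
  mat <- do.call(rbind, lapply(fields, `[`, 1:4))
  pos <- suppressWarnings(as.integer(mat[, 2]))
  if (anyNA(pos))
    stop("non-numeric position at line ", line_no[which(is.na(pos))[1]])
  ref <- toupper(mat[, 3]); alt <- toupper(mat[, 4])
  bad <- which(!(ref %in% c("A", "C", "G", "T")) |
                 !(alt %in% c("A", "C", "G", "T")))
  if (length(bad))
    stop("invalid base at line ", line_no[bad[1]],
         " (only A/C/G/T are allowed)")
  out <- data.frame(chrom = mat[, 1], pos = pos, ref = ref, alt = alt)
  key <- paste(out$chrom, out$pos)
  if (anyDuplicated(key)) {
    d <- which(duplicated(key))[1]
    stop("duplicate position at line ", line_no[d], ": ", key[d])
  }
  out[order(out$chrom, out$pos), , drop = FALSE]
}

.header_lines <- function(seed = NULL, config_hash = NULL) {
  c(paste0("# bulkscan ", as.character(packageVersion("bulkscan"))),
    if (!is.null(seed)) paste0("# seed=", seed),
    if (!is.null(config_hash)) paste0("# config=", config_hash))
}

#' Write / read a per-SNP count table (TSV dialect)
#'
#' Columns `chrom`, `pos` (1-based), `count_A`, `count_B` and, when the
#' table carries a replicate id, `replicate`; metadata in `#`-prefixed
#' header lines. Writing then reading reproduces the table exactly.
#'
#' @param table a [snp_table()].
#' @param path file path.
#' @param seed,config_hash optional provenance recorded in the header.
#' @return `write_count_table` returns `path` invisibly;
#'   `read_count_table` returns a [snp_table()].
#' @export
write_count_table <- function(table, path, seed = NULL, config_hash = NULL) {
  hdr <- .header_lines(seed, config_hash)
  pool <- attr(table, "pool"); repl <- attr(table, "replicate")
  if (!is.null(pool)) hdr <- c(hdr, paste0("# pool=", pool))
  df <- as.data.frame(table)
  cols <- c("chrom", "pos", "count_A", "count_B")
  if (!is.null(repl)) { df$replicate <- repl; cols <- c(cols, "replicate") }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(paste(cols, collapse = "\t"), con)
  write.table(df[cols], con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_count_table
#' @export
read_count_table <- function(path) {
  lines <- readLines(path)
  meta <- lines[grepl("^#", lines)]
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(body) < 1) stop("count table has no header row: ", path)
  cols <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  need <- c("chrom", "pos", "count_A", "count_B")
  miss <- setdiff(need, cols)
  if (length(miss))
    stop("count table is missing column(s): ", paste(miss, collapse = ", "))
  if (length(body) == 1)
    return(snp_table(character(), integer(), integer(), integer()))
  df <- read.delim(text = body[-1], header = FALSE, col.names = cols,
                   colClasses = setNames(
                     ifelse(cols == "chrom", "character", "integer"), cols))
  if (any(df$count_A < 0) || any(df$count_B < 0))
    stop("negative counts in ", path)
  repl <- if ("replicate" %in% cols) unique(df$replicate) else NULL
  if (length(repl) > 1)
    stop("count table mixes replicates; split it first: ", path)
  key <- paste(df$chrom, df$pos)
  if (anyDuplicated(key))
    stop("duplicate (chrom, pos) in ", path, ": ",
         key[duplicated(key)][1])
  pool <- sub("^# pool=", "", grep("^# pool=", meta, value = TRUE))
  snp_table(df$chrom, df$pos, df$count_A, df$count_B,
            pool = if (length(pool)) pool else NULL,
            replicate = repl)
}

#' Write a window track
#'
#' BED output uses 0-based half-open window spans with the value in the
#' fourth column; TSV output keeps 1-based centres.
#'
#' @param track a `window_profile` or `enrichment_track`.
#' @param path file path.
#' @param format `"bed"` or `"tsv"`.
#' @param value_col column holding the track value.
#' @param seed,config_hash optional provenance for the header (TSV only;
#'   BED is kept header-free for browser compatibility).
#' @return `path`, invisibly.
#' @export
write_track <- function(track, path, format = c("bed", "tsv"),
                        value_col = NULL, seed = NULL, config_hash = NULL) {
  format <- match.arg(format)
  if (is.null(value_col))
    value_col <- if ("enrichment" %in% names(track)) "enrichment" else "prop_B"
  df <- as.data.frame(track)
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "bed") {
    out <- data.frame(chrom = df$chrom, start = df$start - 1, end = df$end,
                      value = df[[value_col]])
    write.table(out, con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  } else {
    writeLines(.header_lines(seed, config_hash), con)
    cols <- c("chrom", "center", value_col)
    writeLines(paste(cols, collapse = "\t"), con)
    write.table(df[cols], con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Write called peaks
#'
#' BED6-style output (`chrom start end name score strand`) with the
#' enrichment value in the score column, or a plain TSV with 1-based
#' positions.
#'
#' @param peaks a `peak_set` from [call_peaks()].
#' @inheritParams write_track
#' @return `path`, invisibly.
#' @export
write_peaks <- function(peaks, path, format = c("bed", "tsv"),
                        seed = NULL, config_hash = NULL) {
  format <- match.arg(format)
  df <- as.data.frame(peaks)
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "bed") {
    out <- data.frame(chrom = df$chrom, start = df$pos - 1, end = df$pos,
                      name = if (nrow(df)) paste0("peak_", seq_len(nrow(df)))
                             else character(0),
                      score = df$enrichment,
                      strand = rep(".", nrow(df)))
    write.table(out, con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  } else {
    writeLines(.header_lines(seed, config_hash), con)
    writeLines("chrom\tpos\tenrichment", con)
    write.table(df[c("chrom", "pos", "enrichment")], con, sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

# Tiny polynomial string hash (mod 2^31 - 1); stamps outputs with a
# config fingerprint without pulling in a digest dependency.
.str_hash <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

config_hash <- function(config) {
  .str_hash(as.character(jsonlite::toJSON(config, auto_unbox = TRUE,
                                          digits = NA)))
}
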