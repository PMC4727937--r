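#' Enrichment-scan configuration
#'
#' @param window_size number of consecutive SNPs summed per rolling window
#'   (default 50).
#' @param smooth_window rolling-median span in window units (default 100;
#'   even values are widened to the next odd number so the window is
#'   centred).
#' @param peak_threshold minimum smoothed enrichment for a peak
#'   (default 0.10).
#' @param min_peak_separation_bp peaks closer than this on one chromosome
#'   are merged, keeping the higher one (default 2 Mb).
#' @param min_prominence minimum topographic prominence of a reported
#'   maximum: it must rise at least this far above the deepest saddle
#'   separating it from higher terrain on the same chromosome. Defaults
#'   to `peak_threshold / 2`. Under multiplicative multi-locus selection
#'   whole chromosomes are elevated, so shoulder wiggles would otherwise
#'   be reported as peaks.
#' @return An object of class `enrichment_config`.
#' @export
enrichment_config <- function(window_size = 50, smooth_window = 100,
                              peak_threshold = 0.10,
                              min_peak_separation_bp = 2e6,
                              min_prominence = peak_threshold / 2) {
  stopifnot(window_size >= 1, smooth_window >= 1, peak_threshold >= 0,
            min_peak_separation_bp >= 0, min_prominence >= 0)
  structure(list(window_size = as.integer(window_size),
                 smooth_window = as.integer(smooth_window),
                 peak_threshold = peak_threshold,
                 min_peak_separation_bp = min_peak_separation_bp,
                 min_prominence = min_prominence),
            class = "enrichment_config")
}

#' Rolling-window allele-count profile
#'
#' Slides a window of `window_size` consecutive SNPs (step 1 SNP, never
#' spanning a chromosome boundary) along the table, summing read counts
#' and computing the pooled B-allele proportion per window. The window
#' centre is the median member-SNP position.
#'
#' @param table a sorted [snp_table()].
#' @param window_size number of SNPs per window.
#' @return A data frame of class `window_profile` with columns `chrom`,
#'   `center`, `start`, `end`, `count_A`, `count_B`, `prop_B`.
#' @export
rolling_counts <- function(table, window_size = 50) {
  if (window_size < 1) stop("window_size must be >= 1")
  .validate_snp_positions(table)
  w <- as.integer(window_size)
  out <- lapply(unique(table$chrom), function(nm) {
    t <- table[table$chrom == nm, , drop = FALSE]
    n <- nrow(t)
    if (n < w) return(NULL)
    # windowed sums via cumulative sums
    csA <- cumsum(as.numeric(t$count_A)); csB <- cumsum(as.numeric(t$count_B))
    i <- seq_len(n - w + 1)
    sumA <- csA[i + w - 1] - c(0, csA)[i]
    sumB <- csB[i + w - 1] - c(0, csB)[i]
    # median member position of a sorted window, vectorised
    center <- (t$pos[i + (w - 1L) %/% 2L] + t$pos[i + w %/% 2L]) / 2
    data.frame(chrom = nm, center = center,
               start = t$pos[i], end = t$pos[i + w - 1],
               count_A = sumA, count_B = sumB,
               prop_B = sumB / (sumA + sumB))
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(chrom = character(), center = numeric(),
                      start = numeric(), end = numeric(),
                      count_A = numeric(), count_B = numeric(),
                      prop_B = numeric())
  rownames(out) <- NULL
  structure(out, class = c("window_profile", "data.frame"),
            window_size = w, pool = attr(table, "pool"))
}

#' Relative enrichment of the B allele between two pools
#'
#' Per aligned window, `enrichment = (p_mea - p_wt) / p_wt`, the relative
#' excess of the paternal-accession allele proportion in the selective
#' pool over the control pool. Both profiles must be built on the
#' identical SNP set (see [align_tables()]); windows with `p_wt == 0` are
#' undefined and excluded (with a message).
#'
#' @param mea_profile,wt_profile [rolling_counts()] profiles on the same
#'   SNP index.
#' @return A data frame of class `enrichment_track` with columns `chrom`,
#'   `center`, `start`, `end`, `enrichment`.
#' @export
enrichment_track <- function(mea_profile, wt_profile) {
  if (nrow(mea_profile) != nrow(wt_profile) ||
      !all(mea_profile$chrom == wt_profile$chrom) ||
      !all(mea_profile$center == wt_profile$center))
    stop("profiles are not aligned window-for-window; ",
         "reduce both pools to their common SNP set first")
  ok <- wt_profile$prop_B > 0
  if (any(!ok))
    message(sum(!ok), " window(s) with zero control proportion excluded")
  out <- data.frame(chrom = mea_profile$chrom[ok],
                    center = mea_profile$center[ok],
                    start = mea_profile$start[ok],
                    end = mea_profile$end[ok],
                    enrichment = (mea_profile$prop_B[ok] -
                                    wt_profile$prop_B[ok]) /
                      wt_profile$prop_B[ok])
  rownames(out) <- NULL
  structure(out, class = c("enrichment_track", "data.frame"),
            smoothed = FALSE)
}

#' Reduce two count tables to their common SNP set
#'
#' @param table_a,table_b [snp_table()]s.
#' @return A list of the two tables restricted to shared (chrom, pos)
#'   rows, in identical order.
#' @export
align_tables <- function(table_a, table_b) {
  key_a <- paste(table_a$chrom, table_a$pos)
  key_b <- paste(table_b$chrom, table_b$pos)
  common <- intersect(key_a, key_b)
  list(.keep_rows(table_a, key_a %in% common),
       .keep_rows(table_b, key_b %in% common))
}

#' Rolling-median smoothing of an enrichment track
#'
#' Centred rolling median over consecutive window values within each
#' chromosome. At chromosome edges the window shrinks symmetrically; the
#' output index set is unchanged. Even spans are widened to the next odd
#' number.
#'
#' @param track an [enrichment_track()].
#' @param smooth_window span in track units.
#' @return The track with `enrichment` replaced by its rolling median.
#' @export
smooth_median <- function(track, smooth_window = 100) {
  stopifnot(smooth_window >= 1)
  w <- as.integer(smooth_window)
  if (w %% 2 == 0) w <- w + 1L
  h <- (w - 1L) %/% 2L
  out <- track
  shrunk <- function(x, i, n) {
    k <- min(h, i - 1L, n - i)
    median(x[(i - k):(i + k)])
  }
  for (nm in unique(track$chrom)) {
    idx <- which(track$chrom == nm)
    x <- track$enrichment[idx]
    n <- length(x)
    if (n >= w) {
      # fast centred medians in the interior, shrinking windows at edges
      y <- stats::runmed(x, w, endrule = "keep")
      edge <- c(seq_len(h), seq(n - h + 1L, n))
      y[edge] <- vapply(edge, shrunk, numeric(1), x = x, n = n)
    } else {
      y <- vapply(seq_len(n), shrunk, numeric(1), x = x, n = n)
    }
    out$enrichment[idx] <- y
  }
  attr(out, "smoothed") <- TRUE
  out
}

# Topographic prominence of a local maximum at index i of track values v:
# on each side walk to the nearest strictly higher point; the saddle is
# the minimum value of that stretch; prominence is the drop from v[i] to
# the higher of the two saddles. A side with no higher terrain imposes no
# constraint; a chromosome-wide maximum has infinite prominence.
.prominence <- function(v, i) {
  n <- length(v)
  saddle <- -Inf
  left <- if (i > 1) which(v[seq_len(i - 1)] > v[i]) else integer(0)
  if (length(left)) saddle <- max(saddle, min(v[max(left):(i - 1)]))
  right <- if (i < n) i + which(v[(i + 1):n] > v[i]) else integer(0)
  if (length(right)) saddle <- max(saddle, min(v[(i + 1):min(right)]))
  v[i] - saddle
}

#' Call enrichment peaks on a smoothed track
#'
#' Local maxima with enrichment at or above `peak_threshold` and
#' topographic prominence at least `min_prominence`; maxima closer than
#' `min_peak_separation_bp` on the same chromosome are merged keeping the
#' higher value (ties broken toward the smaller position).
#'
#' @param track a smoothed [enrichment_track()].
#' @param config an [enrichment_config()].
#' @return A data frame of class `peak_set` with columns `chrom`, `pos`,
#'   `enrichment`, sorted by chromosome and position.
#' @export
call_peaks <- function(track, config = enrichment_config()) {
  peaks <- lapply(unique(track$chrom), function(nm) {
    t <- track[track$chrom == nm, , drop = FALSE]
    v <- t$enrichment
    n <- length(v)
    if (n == 0) return(NULL)
    # first index of each plateau counts as the maximum
    is_max <- (v > c(-Inf, v[-n])) & (v >= c(v[-1], -Inf)) &
      v >= config$peak_threshold
    cand <- which(is_max)
    if (config$min_prominence > 0 && length(cand))
      cand <- cand[vapply(cand, function(i) .prominence(v, i),
                          numeric(1)) >= config$min_prominence]
    if (length(cand) == 0) return(NULL)
    # greedy merge: strongest first, smaller position wins ties
    cand <- cand[order(-v[cand], t$center[cand])]
    kept <- integer(0)
    for (i in cand) {
      if (all(abs(t$center[i] - t$center[kept]) >=
                config$min_peak_separation_bp))
        kept <- c(kept, i)
    }
    data.frame(chrom = nm, pos = t$center[kept], enrichment = v[kept])
  })
  peaks <- do.call(rbind, peaks)
  if (is.null(peaks))
    peaks <- data.frame(chrom = character(), pos = numeric(),
                        enrichment = numeric())
  peaks <- peaks[order(peaks$chrom, peaks$pos), , drop = FALSE]
  rownames(peaks) <- NULL
  structure(peaks, class = c("peak_set", "data.frame"))
}
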