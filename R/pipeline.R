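#' Run the full bulk-segregant pipeline
#'
#' Deterministic given the configuration seed: simulates (or reads) the
#' per-replicate count tables of both pools, applies the per-replicate
#' and combined SNP filters, reduces the pools to their common SNP set,
#' computes rolling-window allele proportions, the between-pool
#' enrichment track, its rolling-median smoothing, and peak calls.
#' Optionally writes every stage output plus a JSON run manifest
#' (package version, seed, configuration hash, per-stage row counts).
#'
#' @param config a configuration list, see [default_run_config()]; may
#'   instead carry `counts = list(mea = paths, wt = paths)` to analyse
#'   existing count tables.
#' @param out_dir optional output directory (created if missing).
#' @param map a [genetic_map()]; defaults to [arabidopsis_map()].
#' @return A list with `tables` (filtered combined tables per pool),
#'   `profiles`, `track` (raw enrichment), `smoothed`, `peaks`,
#'   `filter_reports` and `manifest`.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir = NULL,
                         map = arabidopsis_map()) {
  if (!is.null(config$seed)) set.seed(config$seed)
  hash <- config_hash(config)

  if (!is.null(config$counts)) {
    tables <- list(mea = lapply(config$counts$mea, read_count_table),
                   wt = lapply(config$counts$wt, read_count_table))
    panel <- NULL
  } else {
    panel <- make_snp_panel(map, n_snps = config$panel$n_snps,
                            frac_ambiguous = config$panel$frac_ambiguous,
                            frac_mismatch = config$panel$frac_mismatch)
    viability <- .config_viability(config)
    distortions <- config$distortions
    if (!is.null(distortions)) distortions <- as.data.frame(distortions)
    scale <- if (is.null(config$scale)) 1 else config$scale
    tables <- simulate_bulkseq(
      viability = viability, panel = panel, map = map,
      n_mea = pmax(1, round(config$pools$n_mea * scale)),
      n_wt = pmax(1, round(config$pools$n_wt * scale)),
      coverage = .config_coverage(config),
      distortions = distortions)
  }

  fcfg <- .config_filter(config)
  ecfg <- .config_enrichment(config)

  filt <- lapply(tables, function(reps) {
    if (is.null(panel)) {
      # external tables: trust the caller's panel membership, build a
      # pass-through panel from the union of observed positions
      all <- do.call(rbind, lapply(reps, function(t)
        as.data.frame(t)[c("chrom", "pos")]))
      all <- unique(all[order(all$chrom, all$pos), ])
      p <- snp_panel(all$chrom, all$pos, "A", "C")
      filter_pipeline(reps, p, fcfg)
    } else {
      filter_pipeline(reps, panel, fcfg)
    }
  })

  aligned <- align_tables(filt$mea$table, filt$wt$table)
  prof_mea <- rolling_counts(aligned[[1]], ecfg$window_size)
  prof_wt <- rolling_counts(aligned[[2]], ecfg$window_size)
  track <- enrichment_track(prof_mea, prof_wt)
  smoothed <- smooth_median(track, ecfg$smooth_window)
  peaks <- call_peaks(smoothed, ecfg)

  manifest <- list(
    tool = "bulkscan",
    version = as.character(packageVersion("bulkscan")),
    seed = config$seed,
    config_hash = hash,
    stages = list(
      mea_filter = filt$mea$report,
      wt_filter = filt$wt$report,
      common_snps = nrow(aligned[[1]]),
      windows = nrow(track),
      peaks = nrow(peaks)))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(...) file.path(out_dir, ...)
    write_count_table(filt$mea$table, p("mea_filtered_counts.tsv"),
                      seed = config$seed, config_hash = hash)
    write_count_table(filt$wt$table, p("wt_filtered_counts.tsv"),
                      seed = config$seed, config_hash = hash)
    write_track(prof_mea, p("mea_windows.tsv"), "tsv",
                seed = config$seed, config_hash = hash)
    write_track(prof_wt, p("wt_windows.tsv"), "tsv",
                seed = config$seed, config_hash = hash)
    write_track(smoothed, p("enrichment_smoothed.bed"), "bed")
    write_track(smoothed, p("enrichment_smoothed.tsv"), "tsv",
                seed = config$seed, config_hash = hash)
    write_peaks(peaks, p("peaks.bed"), "bed")
    write_peaks(peaks, p("peaks.tsv"), "tsv",
                seed = config$seed, config_hash = hash)
    jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, dataframe = "rows")
  }

  list(tables = list(mea = filt$mea$table, wt = filt$wt$table),
       profiles = list(mea = prof_mea, wt = prof_wt),
       track = track, smoothed = smoothed, peaks = peaks,
       filter_reports = list(mea = filt$mea$report, wt = filt$wt$report),
       manifest = manifest)
}

#' Closed-form expectations of the standard cross designs
#'
#' The four anchor expectations of the method, by exact enumeration:
#' viable-seed fraction of the selfed F2 without and with one fully
#' penetrant unlinked rescue locus, and the pooled paternal-accession
#' allele fraction of the control pool genome-wide and of the selective
#' pool at a fully required rescue locus.
#'
#' @return Named numeric vector of the four expectations (fractions).
#' @examples
#' design_expectations()
#' @export
design_expectations <- function() {
  none <- viability_model(v0 = 0)
  full <- viability_model(
    v0 = 0,
    rescue_loci = data.frame(chrom = "1", pos_bp = NA_real_, pos_cM = 50,
                             multiplier = Inf))
  at_locus <- locus("1", pos_cM = 50)
  c(
    f2_selfing_no_rescue =
      expected_viable_fraction(cross_design("f2_selfing"), none),
    f2_selfing_full_rescue =
      expected_viable_fraction(cross_design("f2_selfing"), full),
    wt_pool_genome_wide =
      expected_pool_allele_fraction(cross_design("wt_pool"),
                                    viability_model(v0 = 1), at_locus),
    mea_pool_at_rescue_locus =
      expected_pool_allele_fraction(cross_design("mea_pool"), full,
                                    at_locus))
}
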