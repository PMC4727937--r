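#' Default paternal rescue loci
#'
#' Six loci at the physical positions of the main enrichment peaks of a
#' Ler x Cvi bulk-segregant scan (chromosomes 1, 2, 3 and 5), each with
#' the same multiplicative rescue factor. The default multiplier is
#' chosen so that baseline viability `v0 = 0.03` rises to 0.85 when all
#' six paternal rescue alleles are present: `r = (0.85 / 0.03)^(1/6)`.
#'
#' @param multiplier per-locus rescue factor.
#' @return Data frame with columns `chrom`, `pos_bp`, `pos_cM`,
#'   `multiplier`.
#' @export
default_rescue_loci <- function(multiplier = (0.85 / 0.03)^(1 / 6)) {
  data.frame(
    chrom = c("1", "1", "2", "3", "5", "5"),
    pos_bp = c(13069000, 18754000, 16054000, 20370000, 9865000, 14239000),
    pos_cM = NA_real_,
    multiplier = multiplier)
}

#' Default full-pipeline run configuration
#'
#' The stated experimental world of the simulator: three replicates per
#' pool with survivor counts (600, 400, 400) for the selective pool and
#' (825, 800, 775) for the control pool, a 20,000-SNP panel over five
#' chromosomes, Poisson coverage with mean 22 reads per SNP, and the six
#' default rescue loci spanning viability 3% (no rescue alleles) to 85%
#' (all six).
#'
#' @param seed RNG seed recorded in every output.
#' @param scale single factor applied to the survivor counts for scaled-
#'   down desk runs (default 1 = full scale).
#' @return A nested list understood by [run_pipeline()].
#' @export
default_run_config <- function(seed = 1, scale = 1) {
  list(
    seed = seed,
    scale = scale,
    panel = list(n_snps = 20000, frac_ambiguous = 0.01,
                 frac_mismatch = 0.01),
    coverage = list(distribution = "poisson", mean_coverage = 22,
                    dispersion = 10, error_rate = 0.002),
    pools = list(n_mea = c(600, 400, 400), n_wt = c(825, 800, 775)),
    viability = list(v0 = 0.03, cap = 1, wildtype_viability = 1,
                     rescue_loci = default_rescue_loci()),
    distortions = NULL,
    filter = list(poisson_percentile = 0.99, tail_quantile = 0.01),
    enrichment = list(window_size = 50, smooth_window = 100,
                      peak_threshold = 0.10,
                      min_peak_separation_bp = 2e6,
                      min_prominence = 0.05))
}

#' Null-model run configuration
#'
#' Same pipeline as [default_run_config()] but with no rescue loci and a
#' uniform viability of 0.5 for maternally mutant seeds, so that no
#' position in the genome is under selection.
#'
#' @inheritParams default_run_config
#' @return A run configuration list.
#' @export
null_run_config <- function(seed = 1, scale = 1) {
  cfg <- default_run_config(seed = seed, scale = scale)
  cfg$viability$v0 <- 0.5
  cfg$viability$rescue_loci <- NULL
  cfg
}

#' Read / write a run configuration (JSON)
#'
#' @param path file path.
#' @param config a configuration list.
#' @return `read_run_config` returns the configuration list;
#'   `write_run_config` returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (!is.null(cfg$viability$rescue_loci) &&
      length(cfg$viability$rescue_loci) == 0)
    cfg$viability$rescue_loci <- NULL
  cfg
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

# Materialise model objects from a configuration list.
.config_viability <- function(cfg) {
  rl <- cfg$viability$rescue_loci
  if (!is.null(rl)) rl <- as.data.frame(rl)
  viability_model(v0 = cfg$viability$v0, rescue_loci = rl,
                  cap = cfg$viability$cap,
                  wildtype_viability = cfg$viability$wildtype_viability)
}

.config_coverage <- function(cfg) {
  coverage_model(distribution = cfg$coverage$distribution,
                 mean_coverage = cfg$coverage$mean_coverage,
                 dispersion = cfg$coverage$dispersion,
                 error_rate = cfg$coverage$error_rate)
}

.config_filter <- function(cfg) {
  filter_config(poisson_percentile = cfg$filter$poisson_percentile,
                tail_quantile = cfg$filter$tail_quantile)
}

.config_enrichment <- function(cfg) {
  enrichment_config(window_size = cfg$enrichment$window_size,
                    smooth_window = cfg$enrichment$smooth_window,
                    peak_threshold = cfg$enrichment$peak_threshold,
                    min_peak_separation_bp =
                      cfg$enrichment$min_peak_separation_bp,
                    min_prominence =
                      if (is.null(cfg$enrichment$min_prominence))
                        cfg$enrichment$peak_threshold / 2
                      else cfg$enrichment$min_prominence)
}
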