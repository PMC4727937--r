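#' Informative SNP panel
#'
#' Ordered biallelic positions that discriminate the two parental
#' accessions, with optional quality flags mimicking positions that are
#' ambiguous in the reference or disagree with published SNP lists.
#'
#' @param chrom,pos chromosome and 1-based position, strictly increasing
#'   within chromosomes.
#' @param allele_A,allele_B the two accession alleles (must differ per row).
#' @param flag_ambiguous,flag_mismatch logical quality flags.
#' @return A data frame of class `snp_panel`.
#' @export
snp_panel <- function(chrom, pos, allele_A, allele_B,
                      flag_ambiguous = FALSE, flag_mismatch = FALSE) {
  n <- length(pos)
  panel <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                      allele_A = as.character(allele_A),
                      allele_B = as.character(allele_B),
                      flag_ambiguous = rep_len(flag_ambiguous, n),
                      flag_mismatch = rep_len(flag_mismatch, n))
  if (any(panel$allele_A == panel$allele_B))
    stop("panel alleles must differ at every position")
  key <- paste(panel$chrom, panel$pos)
  if (anyDuplicated(key)) stop("duplicate panel positions")
  for (nm in unique(panel$chrom)) {
    p <- panel$pos[panel$chrom == nm]
    if (is.unsorted(p, strictly = TRUE))
      stop("panel positions must be strictly increasing within chromosome ",
           nm)
  }
  class(panel) <- c("snp_panel", "data.frame")
  panel
}

#' Draw a random informative SNP panel over a genetic map
#'
#' Positions are uniform over each chromosome's physical length, in
#' numbers proportional to it; alleles are random distinct bases. A small
#' fraction of positions can be flagged to exercise the quality filters.
#'
#' @param map a [genetic_map()].
#' @param n_snps total number of panel SNPs.
#' @param frac_ambiguous,frac_mismatch expected fraction of flagged
#'   positions.
#' @return A `snp_panel`.
#' @export
make_snp_panel <- function(map, n_snps = 20000,
                           frac_ambiguous = 0.01, frac_mismatch = 0.01) {
  chroms <- map$chromosomes
  n_per <- round(n_snps * chroms$length_bp / sum(chroms$length_bp))
  n_per[length(n_per)] <- n_snps - sum(n_per[-length(n_per)])
  bases <- c("A", "C", "G", "T")
  out <- lapply(seq_len(nrow(chroms)), function(i) {
    pos <- sort(sample.int(chroms$length_bp[i], n_per[i]))
    a <- sample(bases, n_per[i], replace = TRUE)
    b <- vapply(a, function(x) sample(setdiff(bases, x), 1), character(1))
    data.frame(chrom = chroms$name[i], pos = pos, allele_A = a, allele_B = b)
  })
  out <- do.call(rbind, out)
  snp_panel(out$chrom, out$pos, out$allele_A, out$allele_B,
            flag_ambiguous = runif(nrow(out)) < frac_ambiguous,
            flag_mismatch = runif(nrow(out)) < frac_mismatch)
}

#' Sequencing coverage model for pooled reads
#'
#' @param distribution `"poisson"` or `"negative_binomial"`.
#' @param mean_coverage mean read depth per SNP (lambda).
#' @param dispersion negative-binomial size parameter (ignored for
#'   Poisson).
#' @param error_rate per-read allele miscall probability, in `[0, 0.5)`.
#' @return An object of class `coverage_model`.
#' @export
coverage_model <- function(distribution = c("poisson", "negative_binomial"),
                           mean_coverage = 22, dispersion = 10,
                           error_rate = 0.002) {
  distribution <- match.arg(distribution)
  stopifnot(mean_coverage > 0, error_rate >= 0, error_rate < 0.5)
  if (distribution == "negative_binomial") stopifnot(dispersion > 0)
  structure(list(distribution = distribution, mean_coverage = mean_coverage,
                 dispersion = dispersion, error_rate = error_rate),
            class = "coverage_model")
}

#' Mea-independent segregation distortion at a locus
#'
#' A gametic transmission bias: F1 pollen carries allele B at this locus
#' with probability `bias` instead of 1/2, independently of seed
#' viability.
#'
#' @param chrom,pos_bp,pos_cM locus coordinates (as in [locus()]).
#' @param bias transmission probability of allele B, in `(0, 1)`.
#' @return A one-row data frame.
#' @export
distortion_locus <- function(chrom, pos_bp = NA_real_, pos_cM = NA_real_,
                             bias = 0.5) {
  stopifnot(bias > 0, bias < 1)
  out <- locus(chrom, pos_bp, pos_cM)
  out$bias <- bias
  out
}

#' Simulate a surviving seedling population over a SNP panel
#'
#' Seeds are generated (maternal gamete fixed or simulated according to
#' the design; paternal gametes by the Haldane model, reweighted at
#' distortion loci) and accepted with their survival probability until
#' `n_target_survivors` accumulate. Each survivor carries a full diploid
#' allele vector over the panel positions.
#'
#' @param design a [cross_design()].
#' @param viability a [viability_model()].
#' @param n_target_survivors number of surviving seedlings to collect.
#' @param panel a `snp_panel`.
#' @param map a `genetic_map` covering the panel.
#' @param distortions optional data frame of [distortion_locus()] rows.
#' @param max_attempts bound on generated seeds before declaring the
#'   design unrescuable.
#' @return A list of class `pool_population` with `paternal` (survivors x
#'   SNP 0/1 matrix of B alleles), `maternal` (matrix, or `NULL` meaning
#'   all-A), `maternally_mutant`, `attempts`, and the `panel`.
#' @export
simulate_cross_population <- function(design, viability, n_target_survivors,
                                      panel, map, distortions = NULL,
                                      max_attempts = NULL) {
  stopifnot(inherits(design, "cross_design"),
            inherits(viability, "viability_model"),
            inherits(panel, "snp_panel"),
            n_target_survivors >= 1)
  if (is.null(max_attempts)) max_attempts <- 2000 * n_target_survivors

  # tracked loci = panel SNPs plus rescue and distortion loci
  tracked <- data.frame(chrom = panel$chrom, pos_bp = as.numeric(panel$pos),
                        pos_cM = NA_real_)
  tracked$kind <- "panel"
  rescue <- viability$rescue_loci
  extra <- rescue[, c("chrom", "pos_bp", "pos_cM")]
  extra$kind <- rep("rescue", nrow(rescue))
  if (!is.null(distortions) && nrow(distortions) > 0) {
    d <- distortions[, c("chrom", "pos_bp", "pos_cM")]
    d$kind <- "distort"
    extra <- rbind(extra, d)
  }
  tracked <- rbind(tracked, extra)
  tracked <- .with_cM(tracked, map)
  ord <- order(match(tracked$chrom, map$chromosomes$name), tracked$pos_cM)
  tracked <- tracked[ord, , drop = FALSE]
  rfrac <- .build_rfrac(tracked$chrom, tracked$pos_cM)

  rescue_idx <- which(tracked$kind == "rescue")
  distort_idx <- which(tracked$kind == "distort")
  design_code <- match(design$design_label,
                       c("mea_pool", "wt_pool", "f2_selfing")) - 1L

  res <- sim_survivors_cpp(
    as.integer(n_target_survivors), nrow(tracked), rfrac,
    as.integer(rescue_idx - 1L), as.numeric(rescue$multiplier),
    viability$v0, viability$cap, viability$wildtype_viability,
    as.integer(distort_idx - 1L),
    if (length(distort_idx)) as.numeric(distortions$bias) else numeric(0),
    design_code, as.numeric(max_attempts))

  if (res$n_accepted < n_target_survivors)
    stop("design yields no survivors: only ", res$n_accepted, " of ",
         n_target_survivors, " seeds survived after ", res$attempts,
         " attempts")

  panel_cols <- which(tracked$kind == "panel")
  out <- list(
    paternal = res$paternal[, panel_cols, drop = FALSE],
    maternal = if (design$design_label == "f2_selfing")
      res$maternal[, panel_cols, drop = FALSE] else NULL,
    maternally_mutant = res$maternally_mutant,
    attempts = res$attempts,
    panel = panel)
  class(out) <- "pool_population"
  out
}

#' Simulate pooled sequencing reads over a survivor population
#'
#' Per SNP, total depth is drawn from the coverage model; each read
#' samples one of the `2N` pooled chromosomes uniformly and reports its
#' allele, miscalled with probability `error_rate`.
#'
#' @param survivors a `pool_population` from
#'   [simulate_cross_population()].
#' @param coverage a [coverage_model()].
#' @param pool,replicate metadata labels for the resulting table.
#' @return A [snp_table()] with one row per panel SNP.
#' @export
simulate_pool_reads <- function(survivors, coverage,
                                pool = NULL, replicate = NULL) {
  stopifnot(inherits(survivors, "pool_population"),
            inherits(coverage, "coverage_model"))
  n <- nrow(survivors$paternal)
  if (n == 0) stop("empty survivor list")
  m <- ncol(survivors$paternal)
  b_copies <- colSums(survivors$paternal)
  if (!is.null(survivors$maternal))
    b_copies <- b_copies + colSums(survivors$maternal)
  f <- b_copies / (2 * n)
  eps <- coverage$error_rate
  p_b <- f * (1 - eps) + (1 - f) * eps
  depth <- switch(coverage$distribution,
                  poisson = rpois(m, coverage$mean_coverage),
                  negative_binomial = rnbinom(m, size = coverage$dispersion,
                                              mu = coverage$mean_coverage))
  count_B <- rbinom(m, depth, p_b)
  snp_table(survivors$panel$chrom, survivors$panel$pos,
            depth - count_B, count_B, pool = pool, replicate = replicate)
}

#' Simulate a full multi-replicate bulk-segregant experiment
#'
#' Runs [simulate_cross_population()] and [simulate_pool_reads()] once per
#' replicate of each pool.
#'
#' @param design_mea,design_wt [cross_design()]s for the selective and the
#'   control cross.
#' @param viability a [viability_model()].
#' @param panel a `snp_panel`.
#' @param map a `genetic_map`.
#' @param n_mea,n_wt integer vectors of survivor counts per replicate.
#' @param coverage a [coverage_model()].
#' @param distortions optional distortion loci (applied to both pools).
#' @return A list with `mea` and `wt`, each a list of [snp_table()]s.
#' @export
simulate_bulkseq <- function(design_mea = cross_design("mea_pool"),
                             design_wt = cross_design("wt_pool"),
                             viability, panel, map,
                             n_mea = c(600, 400, 400),
                             n_wt = c(825, 800, 775),
                             coverage = coverage_model(),
                             distortions = NULL) {
  one_pool <- function(design, ns, label) {
    lapply(seq_along(ns), function(i) {
      pop <- simulate_cross_population(design, viability, ns[i], panel, map,
                                       distortions = distortions)
      simulate_pool_reads(pop, coverage, pool = label, replicate = i)
    })
  }
  list(mea = one_pool(design_mea, n_mea, "mea"),
       wt = one_pool(design_wt, n_wt, "WT"))
}
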