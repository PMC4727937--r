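#' Cross designs with imprinted maternal-effect lethality
#'
#' A `cross_design` describes which parent contributes segregating
#' chromosomes and whether seeds are maternally mutant for the lethal
#' maternal-effect locus:
#'
#' * `"mea_pool"`: a homozygous mutant mother (accession A background) is
#'   pollinated by an A/B F1 hybrid. Every seed is maternally mutant; the
#'   maternal contribution is fixed all-A and only paternal gametes
#'   segregate.
#' * `"wt_pool"`: the matching control cross with a wild-type A mother;
#'   no seed is maternally mutant.
#' * `"f2_selfing"`: a selfed F1 that is heterozygous both for the
#'   maternal-effect mutation and (A/B) at all tracked loci; a seed is
#'   maternally mutant with probability 1/2 and both gametes segregate.
#'
#' @param design_label one of `"mea_pool"`, `"wt_pool"`, `"f2_selfing"`.
#' @param maternal_background accession label of the maternal background
#'   (allele "A" everywhere for the pooled designs).
#' @return An object of class `cross_design`.
#' @export
cross_design <- function(design_label = c("mea_pool", "wt_pool", "f2_selfing"),
                         maternal_background = "A") {
  design_label <- match.arg(design_label)
  maternal_genotype <- switch(design_label,
                              mea_pool = "mutant_homozygous",
                              wt_pool = "wildtype",
                              f2_selfing = "heterozygous")
  structure(list(design_label = design_label,
                 maternal_genotype = maternal_genotype,
                 maternal_background = maternal_background,
                 paternal_parent = "F1 A/B heterozygote"),
            class = "cross_design")
}

#' A genomic locus
#'
#' @param chrom chromosome name.
#' @param pos_bp physical position (1-based bp); optional if `pos_cM` given.
#' @param pos_cM genetic position (cM); optional if `pos_bp` given.
#' @return A one-row data frame with columns `chrom`, `pos_bp`, `pos_cM`.
#' @export
locus <- function(chrom, pos_bp = NA_real_, pos_cM = NA_real_) {
  if (is.na(pos_bp) && is.na(pos_cM))
    stop("a locus needs a physical or a genetic position")
  data.frame(chrom = as.character(chrom), pos_bp = pos_bp, pos_cM = pos_cM)
}

#' Multiplicative seed-viability model
#'
#' Survival of a maternally mutant seed is
#' `min(cap, v0 * prod(r_i ^ x_i))` where `x_i` indicates a paternally
#' inherited B allele at rescue locus `i`. An infinite multiplier encodes a
#' fully penetrant rescue locus (survival `cap` whenever the paternal B
#' allele is present, even with `v0 = 0`). Maternally wild-type seeds
#' survive with probability `wildtype_viability`.
#'
#' @param v0 baseline survival probability of a maternally mutant seed with
#'   no rescue alleles, in `[0, 1]`.
#' @param rescue_loci `NULL`, or a data frame with columns `chrom`,
#'   `pos_bp` and/or `pos_cM`, and `multiplier` (each `>= 1`, `Inf`
#'   allowed).
#' @param cap survival probabilities are truncated at this value
#'   (default 1).
#' @param wildtype_viability survival probability of maternally wild-type
#'   seeds (default 1).
#' @return An object of class `viability_model`.
#' @export
viability_model <- function(v0, rescue_loci = NULL, cap = 1,
                            wildtype_viability = 1) {
  stopifnot(v0 >= 0, v0 <= 1, cap > 0, cap <= 1,
            wildtype_viability >= 0, wildtype_viability <= 1)
  if (is.null(rescue_loci))
    rescue_loci <- data.frame(chrom = character(), pos_bp = numeric(),
                              pos_cM = numeric(), multiplier = numeric())
  stopifnot(is.data.frame(rescue_loci),
            all(c("chrom", "multiplier") %in% names(rescue_loci)))
  if (!"pos_bp" %in% names(rescue_loci)) rescue_loci$pos_bp <- NA_real_
  if (!"pos_cM" %in% names(rescue_loci)) rescue_loci$pos_cM <- NA_real_
  if (any(rescue_loci$multiplier < 1))
    stop("rescue multipliers must be >= 1")
  rescue_loci$chrom <- as.character(rescue_loci$chrom)
  structure(list(v0 = v0, rescue_loci = rescue_loci, cap = cap,
                 wildtype_viability = wildtype_viability),
            class = "viability_model")
}

# Fill in genetic positions from the map where only physical ones are given.
.with_cM <- function(loci, map) {
  miss <- is.na(loci$pos_cM)
  if (any(miss)) {
    if (is.null(map)) stop("a genetic map is needed to place loci in cM")
    loci$pos_cM[miss] <- bp_to_cm(map, loci$chrom[miss], loci$pos_bp[miss])
  }
  loci
}

# Inter-locus recombination fractions for loci ordered by chromosome then
# cM; chromosome boundaries get r = 0.5 (independent assortment).
.build_rfrac <- function(chrom, pos_cM) {
  m <- length(chrom)
  if (m < 2) return(numeric(0))
  new_chrom <- chrom[-1] != chrom[-m]
  d <- diff(pos_cM)
  if (any(!new_chrom & d < 0))
    stop("loci must be sorted by genetic position within chromosomes")
  r <- haldane_recomb(pmax(d, 0))
  r[new_chrom] <- 0.5
  r
}

#' Simulate gametes of an A/B heterozygous parent
#'
#' Gametes follow the Haldane model: per chromosome the starting allele is
#' A or B with probability 1/2, and the allele switches between consecutive
#' loci with probability `haldane_recomb(d)`; chromosomes assort
#' independently.
#'
#' @param n number of gametes.
#' @param positions data frame with columns `chrom` and `pos_cM` (or
#'   `pos_bp` plus a `map`), sorted by position within chromosomes.
#' @param map optional `genetic_map` to fill in missing `pos_cM`.
#' @return An `n x nrow(positions)` integer matrix of 0 (allele A) / 1
#'   (allele B).
#' @export
simulate_gametes <- function(n, positions, map = NULL) {
  stopifnot(n >= 1, is.data.frame(positions), nrow(positions) >= 1)
  if (!"pos_cM" %in% names(positions)) positions$pos_cM <- NA_real_
  positions <- .with_cM(positions, map)
  rfrac <- .build_rfrac(as.character(positions$chrom), positions$pos_cM)
  sim_gametes_cpp(as.integer(n), nrow(positions), rfrac)
}

# All 2^L paternal gamete classes over L loci with their transmission
# probabilities under Haldane linkage (loci on distinct chromosomes are
# independent). `loci` must carry chrom and pos_cM; rows are used in the
# given order, which must be sorted by chromosome then cM.
.paternal_classes <- function(loci, max_loci = 20) {
  L <- nrow(loci)
  if (L > max_loci)
    stop("cannot enumerate gamete classes over more than ", max_loci, " loci")
  if (L == 0)
    return(list(patterns = matrix(0L, 1, 0), prob = 1))
  patterns <- as.matrix(expand.grid(rep(list(0:1), L), KEEP.OUT.ATTRS = FALSE))
  colnames(patterns) <- NULL
  prob <- rep(1, nrow(patterns))
  chrom <- as.character(loci$chrom)
  for (nm in unique(chrom)) {
    cols <- which(chrom == nm)
    prob <- prob * 0.5  # starting allele of the chromosome
    if (length(cols) > 1) {
      d <- diff(loci$pos_cM[cols])
      if (any(d < 0)) stop("loci must be ordered by cM within chromosomes")
      r <- haldane_recomb(d)
      for (j in seq_along(r)) {
        same <- patterns[, cols[j + 1]] == patterns[, cols[j]]
        prob <- prob * ifelse(same, 1 - r[j], r[j])
      }
    }
  }
  list(patterns = patterns, prob = prob)
}

# Survival probability of maternally mutant seeds for each gamete pattern.
# `x` is a pattern matrix over the rescue loci (columns aligned with
# `multiplier`).
.survival_mutant <- function(x, multiplier, v0, cap) {
  if (ncol(x) == 0) return(rep(min(v0, cap), nrow(x)))
  finite <- is.finite(multiplier)
  s <- rep(v0, nrow(x))
  if (any(finite))
    s <- s * exp(x[, finite, drop = FALSE] %*% log(multiplier[finite]))[, 1]
  s <- pmin(s, cap)
  if (any(!finite)) {
    full <- rowSums(x[, !finite, drop = FALSE]) > 0
    s[full] <- cap
  }
  s
}

.sorted_loci <- function(loci, map) {
  loci <- .with_cM(loci, map)
  loci[order(loci$chrom, loci$pos_cM), , drop = FALSE]
}

#' Expected fraction of viable seeds, by exact enumeration
#'
#' Enumerates paternal (and, for selfing, maternal) gamete classes with
#' their Haldane transmission probabilities and averages the survival
#' probability of the viability model.
#'
#' @param design a [cross_design()].
#' @param viability a [viability_model()].
#' @param map optional `genetic_map`, needed when rescue loci are given in
#'   bp only or share a chromosome.
#' @return Expected viable-seed fraction in `[0, 1]`.
#' @examples
#' vb <- viability_model(v0 = 0)
#' expected_viable_fraction(cross_design("f2_selfing"), vb)  # 0.5
#' @export
expected_viable_fraction <- function(design, viability, map = NULL) {
  stopifnot(inherits(design, "cross_design"),
            inherits(viability, "viability_model"))
  if (design$design_label == "wt_pool")
    return(viability$wildtype_viability)
  loci <- .sorted_loci(viability$rescue_loci, map)
  cls <- .paternal_classes(loci)
  e_mut <- sum(cls$prob *
                 .survival_mutant(cls$patterns, loci$multiplier,
                                  viability$v0, viability$cap))
  switch(design$design_label,
         mea_pool = e_mut,
         # maternal-effect locus segregates 1:1 in the selfed mother
         f2_selfing = 0.5 * viability$wildtype_viability + 0.5 * e_mut)
}

#' Expected pooled allele fraction at a query position, by enumeration
#'
#' Expected fraction of B (paternal-accession) allele copies among the
#' pooled diploid genomes of surviving offspring at `query`, conditioning
#' survival on the viability model. The query is linked to rescue loci on
#' the same chromosome through the Haldane map.
#'
#' @param design a [cross_design()].
#' @param viability a [viability_model()].
#' @param query a [locus()].
#' @param map optional `genetic_map` (required for bp-only positions).
#' @return Expected B-allele fraction in `[0, 1]`.
#' @examples
#' vb <- viability_model(v0 = 1)
#' q <- locus("1", pos_cM = 10)
#' expected_pool_allele_fraction(cross_design("wt_pool"), vb, q)  # 0.25
#' @export
expected_pool_allele_fraction <- function(design, viability, query,
                                          map = NULL) {
  stopifnot(inherits(design, "cross_design"),
            inherits(viability, "viability_model"),
            is.data.frame(query), nrow(query) == 1)
  rescue <- viability$rescue_loci
  loci <- rbind(rescue[, c("chrom", "pos_bp", "pos_cM")],
                query[, intersect(names(query), c("chrom", "pos_bp", "pos_cM"))])
  if (!"pos_bp" %in% names(loci)) loci$pos_bp <- NA_real_
  loci$multiplier <- c(rescue$multiplier, NA_real_)
  loci$is_query <- c(rep(FALSE, nrow(rescue)), TRUE)
  loci <- .sorted_loci(loci, map)
  if (!is.null(map)) {
    len <- map$chromosomes
    q <- loci[loci$is_query, ]
    if (!q$chrom %in% len$name)
      stop("query chromosome '", q$chrom, "' is off the map")
  }
  cls <- .paternal_classes(loci)
  rescue_cols <- which(!loci$is_query)
  q_col <- which(loci$is_query)
  s_mut <- .survival_mutant(cls$patterns[, rescue_cols, drop = FALSE],
                            loci$multiplier[rescue_cols],
                            viability$v0, viability$cap)
  x_q <- cls$patterns[, q_col]

  lbl <- design$design_label
  if (lbl == "wt_pool") {
    w <- cls$prob * viability$wildtype_viability
    maternal_B <- 0
  } else if (lbl == "mea_pool") {
    w <- cls$prob * s_mut
    maternal_B <- 0
  } else { # f2_selfing: maternal gamete segregates independently at query
    w <- cls$prob * (0.5 * viability$wildtype_viability + 0.5 * s_mut)
    maternal_B <- 0.5
  }
  if (sum(w) <= 0)
    stop("design yields no survivors; pooled allele fraction undefined")
  paternal_B <- sum(w * x_q) / sum(w)
  (maternal_B + paternal_B) / 2
}

#' Forward-simulate seeds of a design and summarise survival
#'
#' Monte Carlo companion of [expected_viable_fraction()] and
#' [expected_pool_allele_fraction()]: simulates `n_seeds` seeds at the
#' rescue loci (plus the optional query position), applies the viability
#' model, and reports the realised viable fraction and, if a query is
#' given, the pooled B-allele fraction among survivors.
#'
#' @inheritParams expected_pool_allele_fraction
#' @param n_seeds number of seeds to simulate.
#' @param query optional [locus()].
#' @return A list with `viable_fraction`, `n_viable` and (with a query)
#'   `pool_allele_fraction`.
#' @export
simulate_design <- function(design, viability, n_seeds, query = NULL,
                            map = NULL) {
  stopifnot(inherits(design, "cross_design"),
            inherits(viability, "viability_model"), n_seeds >= 1)
  rescue <- viability$rescue_loci
  loci <- rescue[, c("chrom", "pos_bp", "pos_cM")]
  loci$multiplier <- rescue$multiplier
  loci$is_query <- rep(FALSE, nrow(loci))
  if (!is.null(query)) {
    q <- locus(query$chrom, query$pos_bp, query$pos_cM)
    q$multiplier <- NA_real_
    q$is_query <- TRUE
    loci <- rbind(loci, q)
  }
  loci <- .sorted_loci(loci, map)
  m <- max(nrow(loci), 1L)
  rfrac <- if (nrow(loci) > 0)
    .build_rfrac(loci$chrom, loci$pos_cM) else numeric(0)
  pat <- if (nrow(loci) > 0)
    sim_gametes_cpp(n_seeds, m, rfrac) else matrix(0L, n_seeds, 0)

  lbl <- design$design_label
  mut <- switch(lbl,
                mea_pool = rep(TRUE, n_seeds),
                wt_pool = rep(FALSE, n_seeds),
                f2_selfing = runif(n_seeds) < 0.5)
  rescue_cols <- which(!loci$is_query)
  s <- rep(viability$wildtype_viability, n_seeds)
  s[mut] <- .survival_mutant(pat[mut, rescue_cols, drop = FALSE],
                             loci$multiplier[rescue_cols],
                             viability$v0, viability$cap)
  alive <- runif(n_seeds) < s
  out <- list(viable_fraction = mean(alive), n_viable = sum(alive))
  if (!is.null(query)) {
    q_col <- which(loci$is_query)
    pat_q <- pat[alive, q_col]
    mat_q <- if (lbl == "f2_selfing")
      as.integer(runif(sum(alive)) < 0.5) else 0L
    out$pool_allele_fraction <- mean((pat_q + mat_q) / 2)
  }
  out
}
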