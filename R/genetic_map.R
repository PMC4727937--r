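#' Genetic/physical map
#'
#' A `genetic_map` ties genetic (cM) and physical (bp) coordinates together
#' per chromosome. Conversion between the two scales is piecewise-linear
#' interpolation between anchor points; with the default two anchors per
#' chromosome (origin and chromosome end) the map is simply linear.
#'
#' @param chromosomes data frame with columns `name`, `length_cM`,
#'   `length_bp` (one row per chromosome).
#' @param anchors optional named list (by chromosome name) of data frames
#'   with columns `cM` and `bp`, each strictly increasing and spanning
#'   `[0, length]` on both scales. Defaults to the two endpoints.
#' @return An object of class `genetic_map`.
#' @examples
#' map <- genetic_map(data.frame(name = "1", length_cM = 100, length_bp = 2e7))
#' cm_to_bp(map, "1", 50)
#' @export
genetic_map <- function(chromosomes, anchors = NULL) {
  stopifnot(is.data.frame(chromosomes),
            all(c("name", "length_cM", "length_bp") %in% names(chromosomes)))
  chromosomes$name <- as.character(chromosomes$name)
  if (anyDuplicated(chromosomes$name))
    stop("duplicate chromosome names")
  if (any(chromosomes$length_cM <= 0) || any(chromosomes$length_bp <= 0))
    stop("chromosome lengths must be positive")
  if (is.null(anchors)) {
    anchors <- lapply(seq_len(nrow(chromosomes)), function(i)
      data.frame(cM = c(0, chromosomes$length_cM[i]),
                 bp = c(0, chromosomes$length_bp[i])))
    names(anchors) <- chromosomes$name
  }
  if (!setequal(names(anchors), chromosomes$name))
    stop("anchors must be given for exactly the chromosomes of the map")
  for (nm in chromosomes$name) {
    a <- anchors[[nm]]
    stopifnot(all(c("cM", "bp") %in% names(a)))
    if (any(diff(a$cM) <= 0) || any(diff(a$bp) <= 0))
      stop("anchors must be strictly increasing in both coordinates (chromosome ",
           nm, ")")
    len <- chromosomes[chromosomes$name == nm, ]
    if (min(a$cM) < 0 || max(a$cM) > len$length_cM ||
        min(a$bp) < 0 || max(a$bp) > len$length_bp)
      stop("anchors outside chromosome bounds (chromosome ", nm, ")")
  }
  structure(list(chromosomes = chromosomes, anchors = anchors),
            class = "genetic_map")
}

#' Default five-chromosome Arabidopsis-like map
#'
#' Linear map with the TAIR10 physical chromosome lengths and genetic
#' lengths typical of Ler x Cvi recombinant inbred maps.
#'
#' @return A `genetic_map` with chromosomes "1".."5".
#' @export
arabidopsis_map <- function() {
  genetic_map(data.frame(
    name = c("1", "2", "3", "4", "5"),
    length_cM = c(135, 98, 100, 104, 123),
    length_bp = c(30427671, 19698289, 23459830, 18585056, 26975502)))
}

.map_anchor <- function(map, chrom) {
  chrom <- as.character(chrom)
  a <- map$anchors[[chrom]]
  if (is.null(a)) stop("chromosome '", chrom, "' not on the map")
  a
}

#' Convert coordinates between genetic and physical scales
#'
#' @param map a `genetic_map`.
#' @param chrom chromosome name (scalar or vector recycled against `pos`).
#' @param pos_cM,pos_bp positions to convert.
#' @return Numeric vector of converted positions.
#' @export
cm_to_bp <- function(map, chrom, pos_cM) {
  .map_convert(map, chrom, pos_cM, from = "cM", to = "bp")
}

#' @rdname cm_to_bp
#' @export
bp_to_cm <- function(map, chrom, pos_bp) {
  .map_convert(map, chrom, pos_bp, from = "bp", to = "cM")
}

.map_convert <- function(map, chrom, pos, from, to) {
  stopifnot(inherits(map, "genetic_map"))
  chrom <- rep_len(as.character(chrom), length(pos))
  out <- numeric(length(pos))
  for (nm in unique(chrom)) {
    a <- .map_anchor(map, nm)
    idx <- chrom == nm
    p <- pos[idx]
    if (any(p < min(a[[from]]) | p > max(a[[from]])))
      stop("position off the map on chromosome ", nm)
    out[idx] <- approx(a[[from]], a[[to]], xout = p, ties = "ordered")$y
  }
  out
}

#' Haldane map function
#'
#' Recombination fraction between two loci at genetic distance `d` cM under
#' a Poisson crossover process with no interference:
#' `r = (1 - exp(-2 d / 100)) / 2`.
#'
#' @param distance_cM nonnegative genetic distance(s) in centimorgan.
#' @return Recombination fraction(s) in `[0, 0.5)`.
#' @examples
#' haldane_recomb(50)  # 0.5 * (1 - exp(-1))
#' @export
haldane_recomb <- function(distance_cM) {
  if (any(is.na(distance_cM)) || any(distance_cM < 0))
    stop("genetic distance must be nonnegative")
  0.5 * (1 - exp(-2 * distance_cM / 100))
}
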