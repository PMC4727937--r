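#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' @param n_plump number of viable (plump) seeds.
#' @param n_aborted number of aborted seeds.
#' @param confidence confidence level in `(0, 1)` (default 0.95).
#' @return Named numeric vector `proportion`, `lower`, `upper`.
#' @examples
#' binomial_ci(52, 48)
#' @export
binomial_ci <- function(n_plump, n_aborted, confidence = 0.95) {
  stopifnot(n_plump >= 0, n_aborted >= 0, confidence > 0, confidence < 1)
  n <- n_plump + n_aborted
  if (n == 0) stop("cannot form an interval from zero seeds")
  x <- n_plump
  alpha <- 1 - confidence
  lower <- if (x == 0) 0 else qbeta(alpha / 2, x, n - x + 1)
  upper <- if (x == n) 1 else qbeta(1 - alpha / 2, x + 1, n - x)
  c(proportion = x / n, lower = lower, upper = upper)
}

#' One-sided binomial rescue test with Bonferroni correction
#'
#' Exact one-sided binomial test of a line's plump-seed count against a
#' null proportion equal to the control's observed plump fraction
#' (treated as fixed), alternative "greater"; the p-value is multiplied
#' by `n_comparisons` and capped at 1.
#'
#' @param n_plump,n_aborted the line's seed counts.
#' @param control_plump,control_aborted the control's seed counts.
#' @param n_comparisons Bonferroni factor (number of lines tested).
#' @return Named numeric vector `p_raw`, `p_adjusted`.
#' @export
rescue_test <- function(n_plump, n_aborted, control_plump, control_aborted,
                        n_comparisons = 1) {
  stopifnot(n_comparisons >= 1)
  n <- n_plump + n_aborted
  n_ctl <- control_plump + control_aborted
  if (n_ctl < 1) stop("control must have at least one seed")
  if (n < 1) stop("line must have at least one seed")
  p0 <- control_plump / n_ctl
  if (p0 >= 1) {
    # cannot exceed a control already at 100%: degenerate, p = 1
    return(c(p_raw = 1, p_adjusted = 1))
  }
  p_raw <- pbinom(n_plump - 1, n, p0, lower.tail = FALSE)
  c(p_raw = p_raw, p_adjusted = min(1, p_raw * n_comparisons))
}

#' Cube-root normalisation of proportions
#'
#' @param proportions numeric vector of values in `[0, 1]`.
#' @return `proportions^(1/3)`, order-preserving.
#' @export
cube_root_transform <- function(proportions) {
  if (any(is.na(proportions)) || any(proportions < 0))
    stop("proportions must be nonnegative")
  proportions^(1 / 3)
}

#' Seed-count summary table with tests against a control line
#'
#' Computes per line the plump proportion, its Clopper-Pearson interval,
#' and (when a control label is given) the Bonferroni-corrected one-sided
#' rescue test, with star annotation (`*` adjusted p < 0.01, `**` < 0.001).
#'
#' @param counts data frame with columns `label`, `plump`, `aborted`.
#' @param control_label label of the reference line; its row is excluded
#'   from testing and from the Bonferroni count.
#' @param confidence confidence level for the intervals.
#' @return The input with columns `proportion`, `lower`, `upper`,
#'   `p_raw`, `p_adjusted`, `stars` appended.
#' @export
seed_stats <- function(counts, control_label = NULL, confidence = 0.95) {
  stopifnot(all(c("label", "plump", "aborted") %in% names(counts)))
  ci <- t(mapply(binomial_ci, counts$plump, counts$aborted,
                 MoreArgs = list(confidence = confidence)))
  out <- cbind(counts, as.data.frame(ci))
  out$p_raw <- NA_real_; out$p_adjusted <- NA_real_
  out$stars <- ""
  if (!is.null(control_label)) {
    ctl <- which(counts$label == control_label)
    if (length(ctl) != 1) stop("control label must match exactly one row")
    lines <- setdiff(seq_len(nrow(counts)), ctl)
    m <- length(lines)
    for (i in lines) {
      p <- rescue_test(counts$plump[i], counts$aborted[i],
                       counts$plump[ctl], counts$aborted[ctl],
                       n_comparisons = m)
      out$p_raw[i] <- p["p_raw"]
      out$p_adjusted[i] <- p["p_adjusted"]
      out$stars[i] <- if (p["p_adjusted"] < 0.001) "**"
        else if (p["p_adjusted"] < 0.01) "*" else ""
    }
  }
  out
}
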