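# Independent brute-force oracles; deliberately naive and separate from
# the implementation paths they check.

# smallest integer k with Poisson(lambda) CDF >= p, by direct pmf summation
bf_poisson_quantile <- function(p, lambda) {
  k <- 0
  acc <- dpois(0, lambda)
  while (acc < p) {
    k <- k + 1
    acc <- acc + dpois(k, lambda)
  }
  k
}

# type-7 quantile by the textbook formula, independent of stats::quantile
bf_quantile_type7 <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  x[lo] + (h - lo) * (x[min(lo + 1, n)] - x[lo])
}

# O(n*w) centred sliding median with symmetrically shrinking edges
bf_running_median <- function(x, w) {
  if (w %% 2 == 0) w <- w + 1
  h <- (w - 1) / 2
  n <- length(x)
  vapply(seq_len(n), function(i) {
    k <- min(h, i - 1, n - i)
    median(x[(i - k):(i + k)])
  }, numeric(1))
}

# naive windowed sums over one chromosome
bf_window_sums <- function(x, w) {
  n <- length(x)
  if (n < w) return(numeric(0))
  vapply(seq_len(n - w + 1), function(i) sum(x[i:(i + w - 1)]), numeric(1))
}

# Clopper-Pearson interval by scanning p over a grid and inverting the
# exact binomial tails
bf_clopper_pearson <- function(x, n, conf = 0.95, step = 1e-4) {
  a <- (1 - conf) / 2
  grid <- seq(0, 1, by = step)
  upper_tail <- vapply(grid, function(p) pbinom(x - 1, n, p,
                                                lower.tail = FALSE),
                       numeric(1))
  lower_tail <- vapply(grid, function(p) pbinom(x, n, p), numeric(1))
  lo <- if (x == 0) 0 else max(grid[upper_tail <= a])
  hi <- if (x == n) 1 else min(grid[lower_tail <= a])
  c(lower = lo, upper = hi)
}

# one-sided exact binomial tail by direct pmf summation
bf_binom_tail_greater <- function(x, n, p0) sum(dbinom(x:n, n, p0))

# small random count table, sorted, unique positions
random_snp_table <- function(n = 200, chroms = c("1", "2"),
                             max_cov = 60, pool = NULL, replicate = NULL) {
  chrom <- sort(sample(chroms, n, replace = TRUE))
  tab <- do.call(rbind, lapply(unique(chrom), function(nm) {
    k <- sum(chrom == nm)
    data.frame(chrom = nm, pos = sort(sample.int(1e6, k)))
  }))
  cov <- sample.int(max_cov, nrow(tab), replace = TRUE)
  a <- rbinom(nrow(tab), cov, 0.7)
  snp_table(tab$chrom, tab$pos, a, cov - a, pool = pool,
            replicate = replicate)
}

toy_map <- function() {
  genetic_map(data.frame(name = c("1", "2"),
                         length_cM = c(100, 80),
                         length_bp = c(2e7, 1.6e7)))
}
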