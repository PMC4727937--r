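test_that("rolling_counts matches hand-added windows on a toy table", {
  tab <- snp_table("1", c(10, 20, 30, 40, 50),
                   c(1, 2, 3, 4, 5), c(5, 4, 3, 2, 1))
  prof <- rolling_counts(tab, 3)
  expect_equal(nrow(prof), 3)
  expect_equal(prof$count_A, c(6, 9, 12))   # 1+2+3, 2+3+4, 3+4+5
  expect_equal(prof$count_B, c(12, 9, 6))
  expect_equal(prof$prop_B, c(12, 9, 6) / 18)
  expect_equal(prof$center, c(20, 30, 40))  # median member position
  # conservation: window sums equal brute-force member sums
  expect_equal(prof$count_A, bf_window_sums(tab$count_A, 3))
  # pooled-count ratio, not mean of per-SNP ratios (visible only with
  # unequal per-SNP coverage)
  tab2 <- snp_table("1", c(10, 20, 30), c(9, 1, 1), c(1, 1, 8))
  prof2 <- rolling_counts(tab2, 3)
  expect_equal(prof2$prop_B, 10 / 21)
  expect_false(isTRUE(all.equal(prof2$prop_B,
    mean(tab2$count_B / snp_coverage(tab2)))))
})

test_that("rolling_counts window 1 is the per-SNP identity", {
  set.seed(12)
  tab <- random_snp_table(50)
  prof <- rolling_counts(tab, 1)
  expect_equal(prof$count_A, as.numeric(tab$count_A))
  expect_equal(prof$prop_B, tab$count_B / snp_coverage(tab))
  expect_equal(prof$center, as.numeric(tab$pos))
})

test_that("chromosomes shorter than the window yield no windows", {
  tab <- snp_table(rep(c("1", "2"), c(10, 60)),
                   c(1:10, 1:60), 1, 1)
  prof <- rolling_counts(tab, 50)
  expect_true(all(prof$chrom == "2"))
  expect_equal(nrow(prof), 11)
  expect_error(rolling_counts(tab, 0), "window_size")
})

test_that("enrichment_track applies the relative-excess formula", {
  mk <- function(prop) {
    p <- data.frame(chrom = "1", center = seq_along(prop) * 100,
                    start = seq_along(prop) * 100 - 50,
                    end = seq_along(prop) * 100 + 50,
                    count_A = 100 * (1 - prop), count_B = 100 * prop,
                    prop_B = prop)
    class(p) <- c("window_profile", "data.frame")
    p
  }
  # the stated extremes: 0.50 vs 0.25 -> +100%; equality -> 0; 0.30 vs 0.25
  tr <- enrichment_track(mk(c(0.50, 0.25, 0.30)), mk(c(0.25, 0.25, 0.25)))
  expect_equal(tr$enrichment, c(1.0, 0.0, 0.2))
  # zero control windows are excluded with a message
  expect_message(
    tr0 <- enrichment_track(mk(c(0.5, 0.5)), mk(c(0.25, 0))),
    "zero control")
  expect_equal(nrow(tr0), 1)
  expect_error(enrichment_track(mk(c(0.5, 0.5)), mk(0.25)), "not aligned")
})

test_that("smooth_median equals the brute-force sliding median", {
  set.seed(13)
  mk_track <- function(v, chrom = "1") {
    t <- data.frame(chrom = chrom, center = seq_along(v) * 1000,
                    start = seq_along(v) * 1000 - 500,
                    end = seq_along(v) * 1000 + 500, enrichment = v)
    class(t) <- c("enrichment_track", "data.frame")
    t
  }
  # constant track unchanged; single spike removed
  expect_equal(smooth_median(mk_track(rep(0.3, 20)), 5)$enrichment,
               rep(0.3, 20))
  spike <- rep(0, 15); spike[8] <- 1
  expect_equal(smooth_median(mk_track(spike), 5)$enrichment, rep(0, 15))
  # random tracks vs oracle, odd and even (adjusted) spans
  for (w in c(3, 7, 10, 21)) {
    v <- rnorm(500)
    expect_equal(smooth_median(mk_track(v), w)$enrichment,
                 bf_running_median(v, w))
  }
  # multi-chromosome tracks smooth per chromosome
  v1 <- rnorm(60); v2 <- rnorm(9)
  two <- rbind(mk_track(v1, "1"), mk_track(v2, "2"))
  class(two) <- c("enrichment_track", "data.frame")
  sm <- smooth_median(two, 7)
  expect_equal(sm$enrichment, c(bf_running_median(v1, 7),
                                bf_running_median(v2, 7)))
})

test_that("call_peaks finds apexes, merges near maxima, honours threshold", {
  mk_track <- function(v, centers = seq_along(v) * 1e5) {
    t <- data.frame(chrom = "1", center = centers, start = centers - 100,
                    end = centers + 100, enrichment = v)
    class(t) <- c("enrichment_track", "data.frame")
    t
  }
  cfg <- enrichment_config(peak_threshold = 0.1,
                           min_peak_separation_bp = 2e6,
                           min_prominence = 0)
  # everywhere below threshold: no peaks
  expect_equal(nrow(call_peaks(mk_track(rep(0.05, 30)), cfg)), 0)
  # one triangular bump: exactly one peak at its apex
  bump <- c(seq(0, 0.4, length.out = 10), seq(0.35, 0, length.out = 9))
  pk <- call_peaks(mk_track(bump), cfg)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$pos, 10e5)
  expect_equal(pk$enrichment, 0.4)
  # two bumps 1 Mb apart with 2 Mb separation: higher apex wins
  v <- rep(0, 40)
  v[10] <- 0.3; v[20] <- 0.5          # centers 1.0 Mb and 2.0 Mb apart
  pk2 <- call_peaks(mk_track(v), cfg)
  expect_equal(nrow(pk2), 1)
  expect_equal(pk2$pos, 20e5)
  # far enough apart: both kept
  v2 <- rep(0, 60); v2[10] <- 0.3; v2[40] <- 0.5
  expect_equal(nrow(call_peaks(mk_track(v2), cfg)), 2)
  # plateau tie-break: smaller position reported
  v3 <- rep(0, 30); v3[14:16] <- 0.2
  expect_equal(call_peaks(mk_track(v3), cfg)$pos, 14e5)
})

test_that("min_prominence suppresses shoulder wiggles but keeps real peaks", {
  base <- c(seq(0, 0.4, length.out = 30), seq(0.4, 0, length.out = 30))
  wiggle <- base
  wiggle[45] <- wiggle[45] + 0.03     # small bump on the shoulder
  centers <- seq_along(wiggle) * 2e5
  t <- data.frame(chrom = "1", center = centers, start = centers - 100,
                  end = centers + 100, enrichment = wiggle)
  class(t) <- c("enrichment_track", "data.frame")
  loose <- call_peaks(t, enrichment_config(min_prominence = 0))
  strict <- call_peaks(t, enrichment_config(min_prominence = 0.05))
  expect_equal(nrow(loose), 2)   # apex + shoulder wiggle
  expect_equal(nrow(strict), 1)  # apex only
  expect_equal(strict$enrichment, 0.4)
})

test_that("windowed profile proportions track planted enrichment", {
  # selective pool at 50% near a planted locus against a 25% control
  set.seed(14)
  map <- toy_map()
  panel <- make_snp_panel(map, 1500, frac_ambiguous = 0, frac_mismatch = 0)
  full <- viability_model(v0 = 0, rescue_loci = data.frame(
    chrom = "1", pos_bp = 1e7, pos_cM = NA_real_, multiplier = Inf))
  pop_m <- simulate_cross_population(cross_design("mea_pool"), full, 400,
                                     panel, map)
  pop_w <- simulate_cross_population(cross_design("wt_pool"),
                                     viability_model(1), 400, panel, map)
  cov <- coverage_model(mean_coverage = 30, error_rate = 0)
  t_m <- simulate_pool_reads(pop_m, cov, pool = "mea")
  t_w <- simulate_pool_reads(pop_w, cov, pool = "WT")
  aligned <- align_tables(drop_monoallelic(t_m), drop_monoallelic(t_w))
  tr <- smooth_median(enrichment_track(rolling_counts(aligned[[1]], 50),
                                       rolling_counts(aligned[[2]], 50)), 20)
  at_locus <- tr$enrichment[tr$chrom == "1" &
                              abs(tr$center - 1e7) < 5e5]
  expect_gt(mean(at_locus), 0.5)   # ~ (0.5 - 0.25)/0.25 = 1, noisy
})
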