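test_that("haldane_recomb matches the closed form and its limits", {
  expect_identical(haldane_recomb(0), 0)
  expect_equal(haldane_recomb(10000), 0.5, tolerance = 1e-12)
  expect_equal(haldane_recomb(50), 0.5 * (1 - exp(-1)), tolerance = 1e-12)
  d <- seq(0, 300, by = 7)
  r <- haldane_recomb(d)
  expect_true(all(diff(r) > 0))       # strictly increasing
  expect_true(all(r >= 0 & r < 0.5))
  expect_error(haldane_recomb(-1), "nonnegative")
})

test_that("genetic map interpolation is monotone, invertible and bounded", {
  map <- genetic_map(
    data.frame(name = "1", length_cM = 100, length_bp = 2e7),
    anchors = list(`1` = data.frame(cM = c(0, 30, 100),
                                    bp = c(0, 1e7, 2e7))))
  bp <- cm_to_bp(map, "1", c(0, 15, 30, 65, 100))
  expect_equal(bp, c(0, 5e6, 1e7, 1.5e7, 2e7))
  expect_equal(bp_to_cm(map, "1", bp), c(0, 15, 30, 65, 100))
  expect_error(cm_to_bp(map, "1", 101), "off the map")
  expect_error(cm_to_bp(map, "7", 10), "not on the map")
  expect_error(genetic_map(
    data.frame(name = "1", length_cM = 100, length_bp = 2e7),
    anchors = list(`1` = data.frame(cM = c(0, 50, 40), bp = c(0, 1e7, 2e7)))),
    "strictly increasing")
})

test_that("simulate_gametes reproduces Mendelian and Haldane behaviour", {
  set.seed(42)
  n <- 1e5
  # single heterozygous locus: 1:1 segregation
  g1 <- simulate_gametes(n, data.frame(chrom = "1", pos_cM = 10))
  expect_lt(abs(mean(g1) - 0.5), 3 * sqrt(0.25 / n))
  # complete linkage at d = 0
  g2 <- simulate_gametes(n / 10, data.frame(chrom = "1", pos_cM = c(20, 20)))
  expect_identical(sum(g2[, 1] != g2[, 2]), 0L)
  # recombinant fraction at 50 cM equals the Haldane closed form
  g3 <- simulate_gametes(n, data.frame(chrom = "1", pos_cM = c(10, 60)))
  rec <- mean(g3[, 1] != g3[, 2])
  r <- haldane_recomb(50)
  expect_lt(abs(rec - r), 3 * sqrt(r * (1 - r) / n))
  # loci on different chromosomes assort independently
  g4 <- simulate_gametes(n, data.frame(chrom = c("1", "2"), pos_cM = c(0, 0)))
  rec4 <- mean(g4[, 1] != g4[, 2])
  expect_lt(abs(rec4 - 0.5), 3 * sqrt(0.25 / n))
  expect_error(
    simulate_gametes(10, data.frame(chrom = "1", pos_cM = c(30, 10))),
    "sorted")
})

test_that("expected_viable_fraction matches the Mendelian anchors", {
  none <- viability_model(v0 = 0)
  full <- viability_model(v0 = 0, rescue_loci = data.frame(
    chrom = "1", pos_cM = 50, multiplier = Inf))
  # heterozygous maternal-effect lethality alone: half the seeds abort
  expect_identical(expected_viable_fraction(cross_design("f2_selfing"), none),
                   0.5)
  # one unlinked fully penetrant paternal rescue locus: 75%
  expect_identical(expected_viable_fraction(cross_design("f2_selfing"), full),
                   0.75)
  # mutant mother x F1: half the pollen carries the required allele
  expect_identical(expected_viable_fraction(cross_design("mea_pool"), full),
                   0.5)
  # hand-computed finite-multiplier case: v0=0.2, one locus r=2
  # mea_pool: 0.5*0.2 + 0.5*0.4 = 0.3; f2: 0.5 + 0.5*0.3 = 0.65
  vb <- viability_model(v0 = 0.2, rescue_loci = data.frame(
    chrom = "1", pos_cM = 50, multiplier = 2))
  expect_equal(expected_viable_fraction(cross_design("mea_pool"), vb), 0.3)
  expect_equal(expected_viable_fraction(cross_design("f2_selfing"), vb), 0.65)
  expect_identical(
    expected_viable_fraction(cross_design("wt_pool"), viability_model(1)), 1)
})

test_that("expected_viable_fraction is monotone in v0 and multipliers", {
  for (d in c("mea_pool", "f2_selfing")) {
    des <- cross_design(d)
    prev <- -1
    for (v0 in c(0, 0.05, 0.2, 0.5)) {
      cur <- expected_viable_fraction(des, viability_model(v0 = v0,
        rescue_loci = data.frame(chrom = "1", pos_cM = 50, multiplier = 2)))
      expect_gte(cur, prev)
      prev <- cur
    }
    prev <- -1
    for (r in c(1, 1.5, 2, 5, 20)) {
      cur <- expected_viable_fraction(des, viability_model(v0 = 0.1,
        rescue_loci = data.frame(chrom = "1", pos_cM = 50, multiplier = r)))
      expect_gte(cur, prev)
      prev <- cur
    }
  }
})

test_that("expected_pool_allele_fraction hits the design anchors", {
  full <- viability_model(v0 = 0, rescue_loci = data.frame(
    chrom = "1", pos_cM = 50, multiplier = Inf))
  q_at <- locus("1", pos_cM = 50)
  # control pool: no selection, a quarter of pooled copies are paternal B
  expect_equal(expected_pool_allele_fraction(
    cross_design("wt_pool"), viability_model(1), q_at), 0.25)
  # selective pool at a fully required locus: every survivor has paternal B
  expect_equal(expected_pool_allele_fraction(
    cross_design("mea_pool"), full, q_at), 0.5)
  # unlinked (other chromosome): back to 0.25
  expect_equal(expected_pool_allele_fraction(
    cross_design("mea_pool"), full, locus("2", pos_cM = 10)), 0.25)
})

test_that("linkage decay follows (1 - r)/2 around a fully required locus", {
  full <- viability_model(v0 = 0, rescue_loci = data.frame(
    chrom = "1", pos_cM = 0, multiplier = Inf))
  mea <- cross_design("mea_pool")
  for (d in c(0, 5, 20, 50, 120)) {
    got <- expected_pool_allele_fraction(mea, full, locus("1", pos_cM = d))
    expect_equal(got, (1 - haldane_recomb(d)) / 2, tolerance = 1e-12)
  }
})

test_that("enumeration agrees with forward simulation", {
  set.seed(7)
  map <- toy_map()
  # two linked + one unlinked locus, finite multipliers
  vb <- viability_model(v0 = 0.05, rescue_loci = data.frame(
    chrom = c("1", "1", "2"), pos_cM = c(20, 55, 40),
    multiplier = c(3, 2.2, 4)))
  q <- locus("1", pos_cM = 35)
  n <- 1e5
  for (d in c("mea_pool", "f2_selfing")) {
    des <- cross_design(d)
    exp_v <- expected_viable_fraction(des, vb, map)
    exp_f <- expected_pool_allele_fraction(des, vb, q, map)
    sim <- simulate_design(des, vb, n, query = q, map = map)
    expect_lt(abs(sim$viable_fraction - exp_v),
              3 * sqrt(exp_v * (1 - exp_v) / n))
    se_f <- sqrt(exp_f * (1 - exp_f) / sim$n_viable)
    expect_lt(abs(sim$pool_allele_fraction - exp_f), 3 * se_f + 1e-3)
  }
})

test_that("allele relabelling symmetry: B fractions mirror to 1 - f", {
  set.seed(11)
  n <- 4e4
  pos <- data.frame(chrom = "1", pos_cM = c(10, 40))
  g <- simulate_gametes(n, pos)
  # relabelled gametes are 1 - g; their B fraction mirrors
  expect_equal(colMeans(g) + colMeans(1 - g), c(1, 1))
  # same recombinant fraction either way
  expect_identical(mean(g[, 1] != g[, 2]),
                   mean((1 - g)[, 1] != (1 - g)[, 2]))
})

test_that("enumeration capacity and input errors are explicit", {
  too_many <- viability_model(v0 = 0.1, rescue_loci = data.frame(
    chrom = as.character(1:21), pos_cM = rep(10, 21),
    multiplier = rep(1.5, 21)))
  expect_error(expected_viable_fraction(cross_design("mea_pool"), too_many),
               "enumerate")
  full <- viability_model(v0 = 0, rescue_loci = data.frame(
    chrom = "1", pos_cM = 50, multiplier = Inf))
  expect_error(expected_pool_allele_fraction(
    cross_design("mea_pool"), full, locus("9", pos_cM = 1),
    map = toy_map()), "off the map")
})
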