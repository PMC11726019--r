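test_that("breakend clustering groups junctions by gap and spans members", {
  j <- make_junctions(pos1 = seq(30e6, 48e6, by = 2e6),
                      pos2 = seq(40e6, 58e6, by = 2e6))
  reg <- cluster_regions(j, gap_bp = 1e7, chrom_length = 2e8)
  expect_equal(nrow(reg), 2L)  # one cluster + whole chromosome
  expect_equal(reg$start[1], 30e6)
  expect_equal(reg$end[1], 58e6)
  expect_true(reg$whole_chrom[2])

  far <- make_junctions(pos1 = c(10e6, 11e6, 150e6, 151e6),
                        pos2 = c(12e6, 13e6, 152e6, 153e6))
  reg2 <- cluster_regions(far, gap_bp = 1e7, chrom_length = 2e8)
  expect_equal(nrow(reg2), 3L)  # two clusters + whole chromosome

  none <- make_junctions(numeric(0), numeric(0))
  reg3 <- cluster_regions(none, chrom_length = 2e8)
  expect_equal(nrow(reg3), 1L)
  expect_true(reg3$whole_chrom)
})

test_that("interleave counting excludes nesting and follows components", {
  expect_equal(count_interleaved(make_junctions(c(10, 30), c(50, 80))), 2L)
  expect_equal(count_interleaved(make_junctions(c(10, 30), c(100, 60))), 0L)
  expect_equal(
    count_interleaved(make_junctions(c(10, 30, 60), c(40, 70, 90))), 3L)
})

test_that("interleave counts agree with the pairwise component oracle", {
  set.seed(404)
  for (rep in 1:300) {
    n <- sample(2:50, 1)
    a <- sort(sample.int(1e6, 2 * n))
    pos1 <- a[seq(1, 2 * n, by = 2)]
    pos2 <- a[seq(2, 2 * n, by = 2)]
    pick <- sample.int(2 * n, n)
    p1 <- pmin(a[pick], rev(a)[pick])
    p2 <- pmax(a[pick], rev(a)[pick])
    keep <- p1 < p2
    if (sum(keep) < 2) next
    got <- count_interleaved(make_junctions(p1[keep], p2[keep]))
    expect_equal(got, oracle_interleaved(p1[keep], p2[keep]))
  }
})

test_that("fragment joins test is exact for small counts, chi-square above", {
  expect_equal(fragment_joins_test(c(10, 10, 10, 10)), 1.0)
  expect_lt(fragment_joins_test(c(40, 0, 0, 0)), 1e-15)
  # exact path against full 4^n enumeration
  for (counts in list(c(2, 1, 1, 0), c(4, 0, 0, 0), c(3, 3, 1, 1),
                      c(1, 1, 1, 1))) {
    expect_equal(fragment_joins_test(counts), oracle_multinom_p(counts),
                 tolerance = 1e-10)
  }
  expect_error(fragment_joins_test(c(0, 0, 0, 0)), "at least one")
})

test_that("joins test reads orientation classes off a junction set", {
  j <- make_junctions(c(10, 30, 50, 70), c(20, 40, 60, 80),
                      strand1 = c("+", "-", "+", "-"),
                      strand2 = c("-", "+", "+", "-"))
  expect_equal(fragment_joins_test(j), oracle_multinom_p(c(1, 1, 1, 1)),
               tolerance = 1e-10)
})

test_that("breakpoint exponentiality test rejects clustered positions", {
  expect_gt(breakpoint_exponential_test(seq(5e5, 9.5e6, length.out = 10),
                                        1, 1e7), 0.9)
  expect_lt(breakpoint_exponential_test(seq(1, 1e5, length.out = 20),
                                        1, 1e7), 1e-10)
  expect_error(breakpoint_exponential_test(c(1, 2, 3, 4), 1, 1e7),
               "distinct")
  expect_error(breakpoint_exponential_test(1:10, 5, 5), "positive")
})

test_that("chromosomal enrichment test matches exact binomial summation", {
  expect_equal(chromosomal_enrichment_test(50, 0.08e9, 60, 1e9),
               oracle_binom_tail(50, 60, 0.08), tolerance = 1e-12)
  expect_lt(chromosomal_enrichment_test(50, 0.08e9, 60, 1e9), 1e-30)
  p_prop <- chromosomal_enrichment_test(5, 0.08e9, 60, 1e9)
  expect_equal(p_prop, oracle_binom_tail(5, 60, 0.08), tolerance = 1e-12)
  expect_gt(p_prop, 0.05)  # proportional share is not enrichment
  # every breakend on a tiny chromosome: smallest attainable tail
  expect_equal(chromosomal_enrichment_test(20, 1e6, 20, 1e9),
               (1e6 / 1e9)^20, tolerance = 1e-12)
  expect_error(chromosomal_enrichment_test(5, 1e6, 0, 1e9), "at least one")
})

test_that("criteria combinations reproduce the published rule set", {
  p <- detector_params()
  c1 <- evaluate_criteria(6, 0, 10, 7, p_joins = 0.5, p_enrich = 0.5,
                          p_exp = 0.5, params = p)
  expect_true("i" %in% c1$criteria_passed)
  expect_identical(c1$verdict, "positive")

  low <- evaluate_criteria(6, 0, 10, 5, p_joins = 0.5, p_enrich = 0.01,
                           p_exp = 0.5, params = p)
  expect_identical(low$criteria_passed, "v")
  expect_identical(low$verdict, "low_density")

  none <- evaluate_criteria(5, 0, 5, 7, p_joins = 0.5, p_enrich = 0.5,
                            p_exp = 0.5, params = p)
  expect_length(none$criteria_passed, 0L)
  expect_identical(none$verdict, "negative")

  # missing tests count as failing
  na_case <- evaluate_criteria(6, 0, 10, 7, p_joins = NA, p_enrich = NA,
                               p_exp = NA, params = p)
  expect_identical(na_case$verdict, "negative")
})

test_that("criteria engine agrees with the truth-table oracle", {
  set.seed(405)
  p <- detector_params()
  for (rep in 1:2000) {
    intra <- sample(c(0:8, 39:41, 20), 1)
    inter <- sample(0:6, 1)
    total <- intra + inter + sample(c(0, 50, 90:110), 1)
    osc <- sample(0:9, 1)
    pj <- sample(c(NA, runif(1), 0.04, 0.05, 0.06), 1)
    pe <- sample(c(NA, runif(1), 0.04, 0.05, 0.06), 1)
    px <- sample(c(NA, runif(1), 0.04, 0.05, 0.06), 1)
    got <- evaluate_criteria(intra, inter, total, osc, pj, pe, px, p)
    want <- oracle_criteria(intra, inter, total, osc, pj, pe, px)
    expect_identical(got$criteria_passed, want$passed)
    expect_identical(got$verdict, want$verdict)
  }
})

test_that("amplified segments are flagged above five times baseline", {
  seg <- make_segments(c(2, 2, 11, 2, 10, 2))
  f <- flag_amplified_segments(seg)
  expect_equal(f$baseline, 2)
  expect_equal(f$flagged, c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE))
  flat <- flag_amplified_segments(make_segments(rep(2, 5)))
  expect_false(any(flat$flagged))
  # baseline is length-weighted: one long CN-4 segment outweighs many short
  wide <- make_segments(c(4, 2, 2, 2), len = c(9e7, 1e6, 1e6, 1e6))
  expect_equal(flag_amplified_segments(wide)$baseline, 4)
})

test_that("the WGS caller is deterministic and labels simulations correctly", {
  cfg <- shatter_config(seed = 99)
  tr <- simulate_chromothripsis(cfg)
  set.seed(1); w <- render_wgs(tr, cfg)
  cl1 <- call_wgs(w$segments, w$junctions,
                  chrom_lengths = c("11" = cfg$chrom_length))
  cl2 <- call_wgs(w$segments, w$junctions,
                  chrom_lengths = c("11" = cfg$chrom_length))
  expect_identical(cl1$report, cl2$report)
  expect_false(cl1$calls[["11"]]$verdict == "negative")

  ctrl <- simulate_control(shatter_config(seed = 100))
  set.seed(2); wc <- render_wgs(ctrl)
  ncl <- call_wgs(wc$segments, wc$junctions)
  expect_identical(ncl$calls[["11"]]$verdict, "negative")
})
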