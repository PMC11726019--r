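qualifying_segments <- function(n, cf = 0.9) {
  make_segments(rep(c(2, 1), length.out = n), cf = cf,
                log_ratio = rep(c(0, -0.6), length.out = n))
}

test_that("five qualifying oscillating segments are suggestive, four are not", {
  pos <- call_panel(qualifying_segments(5))
  expect_identical(pos$calls[["1"]]$verdict, "suggestive_positive")
  expect_equal(pos$calls[["1"]]$best_run$run_length, 5L)

  neg <- call_panel(qualifying_segments(4))
  expect_identical(neg$calls[["1"]]$verdict, "negative")
  expect_true("run_too_short" %in% neg$calls[["1"]]$reasons)
})

test_that("low segment cellular fraction blocks the call", {
  low <- call_panel(qualifying_segments(5, cf = 0.3))
  expect_identical(low$calls[["1"]]$verdict, "negative")
  expect_true("low_ccf" %in% low$calls[["1"]]$reasons)
})

test_that("non-uniform sizes and discordant tracks block the call", {
  seg <- make_segments(rep(c(2, 1), length.out = 5),
                       len = c(1e7, 1e7, 5e5, 1e7, 1e7),
                       log_ratio = rep(c(0, -0.6), length.out = 5))
  res <- call_panel(seg)
  expect_identical(res$calls[["1"]]$verdict, "negative")
  expect_true("nonuniform_sizes" %in% res$calls[["1"]]$reasons)

  disc <- make_segments(rep(c(2, 1), length.out = 5),
                        log_ratio = c(0, 0.6, 0, -0.6, 0))
  res2 <- call_panel(disc)
  expect_identical(res2$calls[["1"]]$verdict, "negative")
  expect_true("discordant_tracks" %in% res2$calls[["1"]]$reasons)
})

test_that("a qualifying window inside a longer non-uniform run still calls", {
  # seven-segment run whose first segment is tiny; the last five segments
  # are uniform, so the published five-consecutive-segments rule applies
  seg <- make_segments(rep(c(2, 1), length.out = 7),
                       len = c(2e5, 1e7, 1e7, 1e7, 1e7, 1e7, 1e7),
                       log_ratio = rep(c(0, -0.6), length.out = 7))
  res <- call_panel(seg)
  expect_identical(res$calls[["1"]]$verdict, "suggestive_positive")
  expect_gte(res$calls[["1"]]$best_run$run_length, 5L)
})

test_that("amplification spikes are bridged before rule evaluation", {
  # ecDNA-like CN-40 spike interrupting an otherwise qualifying oscillation
  seg <- make_segments(c(2, 1, 2, 40, 1, 2, 1),
                       log_ratio = c(0, -0.6, 0, 3.5, -0.6, 0, -0.6))
  res <- call_panel(seg)
  expect_identical(res$calls[["1"]]$verdict, "suggestive_positive")
  expect_equal(res$calls[["1"]]$best_run$run_length, 6L)
})

test_that("relaxing any single threshold never revokes a positive", {
  set.seed(301)
  base <- detector_params()
  for (rep in 1:50) {
    n <- sample(4:9, 1)
    seg <- make_segments(rep(c(2, 1), length.out = n),
                         len = round(runif(n, 1e6, 2e7)),
                         cf = runif(n, 0.3, 1),
                         log_ratio = rep(c(0, -0.6), length.out = n))
    v0 <- call_panel(seg, base)$calls[["1"]]$verdict
    if (v0 != "suggestive_positive") next
    relaxed <- list(
      detector_params(min_panel_run = base$min_panel_run - 1L),
      detector_params(min_segment_ccf = base$min_segment_ccf / 2),
      detector_params(uniformity_max_ratio = base$uniformity_max_ratio * 2)
    )
    for (p in relaxed) {
      expect_identical(call_panel(seg, p)$calls[["1"]]$verdict,
                       "suggestive_positive")
    }
  }
})

test_that("concordance against truth labels produces exact rates", {
  calls <- data.frame(
    chrom = as.character(1:10),
    verdict = c(rep("suggestive_positive", 3), rep("negative", 7)),
    stringsAsFactors = FALSE)
  truth <- setNames(c(rep(TRUE, 4), rep(FALSE, 6)), as.character(1:10))
  cc <- concordance_vs_truth(calls, truth)
  expect_equal(cc$sensitivity, 0.75)
  expect_equal(cc$specificity, 1)
  expect_equal(unname(cc$counts["TP"]), 3L)
  expect_equal(nrow(cc$confusion), 10L)

  perfect <- data.frame(chrom = as.character(1:10),
                        verdict = c(rep("suggestive_positive", 4),
                                    rep("negative", 6)))
  pc <- concordance_vs_truth(perfect, truth)
  expect_equal(pc$sensitivity, 1)
  expect_equal(pc$specificity, 1)

  none <- setNames(rep(FALSE, 10), as.character(1:10))
  expect_true(is.na(concordance_vs_truth(perfect, none)$sensitivity))
  expect_error(concordance_vs_truth(calls, truth[1:3]), "missing")
})
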