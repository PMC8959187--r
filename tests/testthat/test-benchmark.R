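mk_call <- function(sample, chrom, start, end, type,
                    quality = 100, n_bins = 5, mean_dosage = 0.5) {
  tibble::tibble(sample = sample, chrom = chrom, start = start, end = end,
                 type = type, n_bins = n_bins, mean_dosage = mean_dosage,
                 quality = quality)
}

test_that("any-overlap matching respects sample, type and half-open coordinates", {
  truth <- tibble::tibble(sample = "A", chrom = "chr1",
                          start = 150, end = 300, type = "DEL")
  m <- match_calls(mk_call("A", "chr1", 100, 200, "DEL"), truth)
  expect_equal(m$tp, 1); expect_equal(m$fn, 0)

  ## abutting half-open intervals do not overlap
  m2 <- match_calls(mk_call("A", "chr1", 100, 150, "DEL"), truth)
  expect_equal(m2$tp, 0); expect_equal(m2$fp, 1); expect_equal(m2$fn, 1)

  ## wrong sample or wrong type is no match
  expect_equal(match_calls(mk_call("B", "chr1", 100, 200, "DEL"), truth)$tp, 0)
  expect_equal(match_calls(mk_call("A", "chr1", 100, 200, "DUP"), truth)$tp, 0)
  expect_equal(match_calls(mk_call("A", "chr1", 100, 200, "DUP"), truth,
                           same_type_required = FALSE)$tp, 1)

  ## one call spanning two truth CNVs: both detected, one true call
  truth2 <- tibble::tibble(sample = "A", chrom = "chr1",
                           start = c(100, 500), end = c(200, 600),
                           type = "DEL")
  m3 <- match_calls(mk_call("A", "chr1", 50, 700, "DEL"), truth2)
  expect_equal(m3$n_detected, 2)
  expect_equal(m3$tp, 1)
  expect_equal(m3$fn, 0)
})

test_that("precision, recall and f follow their definitions", {
  truth <- tibble::tibble(sample = "A", chrom = "chr1",
                          start = 100, end = 200, type = "DEL")
  calls <- dplyr::bind_rows(mk_call("A", "chr1", 150, 250, "DEL"),
                            mk_call("A", "chr1", 5000, 6000, "DEL"))
  pr <- precision_recall(match_calls(calls, truth))
  expect_equal(pr$precision, 0.5)
  expect_equal(pr$recall, 1)
  expect_equal(pr$f, 2 / 3)

  ## zero calls: precision missing, recall 0, f 0
  none <- precision_recall(match_calls(calls[0, ], truth))
  expect_true(is.na(none$precision))
  expect_equal(none$recall, 0)
  expect_equal(none$f, 0)

  ## harmonic mean at a realistic operating point
  expect_equal(2 * 0.788 * 0.976 / (0.788 + 0.976), 0.872, tolerance = 5e-4)

  expect_error(precision_recall(match_calls(calls, truth[0, ])), "truth")
})

test_that("boundary error averages both endpoint offsets", {
  truth <- tibble::tibble(sample = "A", chrom = "chr1",
                          start = 1e6, end = 3e6, type = "DEL")
  exact <- match_calls(mk_call("A", "chr1", 1e6, 3e6, "DEL"), truth)
  expect_equal(boundary_error(exact), 0)

  ## shifted one 200 kb bin at each end
  shifted <- match_calls(mk_call("A", "chr1", 1.2e6, 3.2e6, "DEL"), truth)
  expect_equal(boundary_error(shifted), 2e5)

  unmatched <- match_calls(mk_call("A", "chr1", 9e6, 9.5e6, "DEL"), truth)
  expect_true(is.na(boundary_error(unmatched)))
})

test_that("size bands partition the truth set", {
  truth <- tibble::tibble(sample = "A", chrom = "chr1",
                          start = c(0, 0, 0, 0),
                          end = c(5e5, 1e6, 4.99e6, 5.01e6), type = "DEL")
  st <- stratify_sizes(truth)
  expect_equal(as.character(st$size_band),
               c("<1Mb", "<1Mb", "1-5Mb", ">5Mb"))
  expect_false(anyNA(st$size_band))
})

test_that("the PR frontier keeps the best precision per recall", {
  pts <- tibble::tibble(
    recall = c(0.2, 0.5, 0.5, 0.8, 0.9),
    precision = c(0.9, 0.95, 0.7, 0.6, NA))
  fr <- pr_frontier(pts)
  ## the dominated (0.2, 0.9) and duplicate-recall (0.5, 0.7) points drop out
  expect_equal(fr$recall, c(0.5, 0.8))
  expect_equal(fr$precision, c(0.95, 0.6))
  ## monotone: precision non-increasing in recall
  expect_true(all(diff(fr$precision) <= 0))

  single <- pr_frontier(tibble::tibble(recall = 0.4, precision = 0.8))
  expect_equal(nrow(single), 1)

  ## property: on random point clouds the frontier is monotone and
  ## dominates every point
  set.seed(33)
  for (i in 1:10) {
    cloud <- tibble::tibble(recall = runif(40), precision = runif(40))
    fr2 <- pr_frontier(cloud)
    expect_true(all(diff(fr2$recall) > 0))
    expect_true(all(diff(fr2$precision) < 0))
    for (j in seq_len(nrow(cloud))) {
      expect_true(any(fr2$recall >= cloud$recall[j] &
                        fr2$precision >= cloud$precision[j]))
    }
  }
})

test_that("rebinning aggregates adjacent bins and conserves counts", {
  counts <- const_counts(3, 10, value = 7, bin_size = 1000)
  rb <- rebin_counts(counts, 4)
  expect_equal(nrow(rb), 3)  # 4 + 4 + 2 bins
  expect_equal(rb$start, c(0, 4000, 8000))
  expect_equal(rb$end, c(4000, 8000, 10000))
  expect_equal(sum(rb$S01), sum(counts$S01))
  expect_equal(rb$S02, c(28, 28, 14))
  expect_identical(rebin_counts(counts, 1), counts)
})

test_that("a sweep over thresholds traces the expected operating points", {
  set.seed(34)
  cfg <- simulation_config(
    n_samples = 30,
    layout = tibble::tibble(chrom = c("chr1", "chr2"), length = c(4e7, 4e7)))
  cfg$cnvs <- plant_cnvs(cfg, n_del = 3, n_dup = 3, size_range_bins = c(6, 12))
  sim <- simulate_cohort(cfg, seed = 35)
  sw <- sweep_cnv_calls(sim$counts, sim$truth)
  expect_s3_class(sw, "cnv_sweep")
  expect_gt(nrow(sw$points), 0)
  expect_gt(nrow(tidy(sw)), 0)
  g <- glance(sw)
  expect_gt(g$best_f, 0)
  expect_lte(g$best_f, 1)
  ## frontier f never exceeds the best point f
  expect_equal(g$best_f, max(sw$points$f))
  ## the frontier contains the full-sensitivity (cutoff 0) operating point
  ## or dominates it
  base <- sw$points[sw$points$min_quality == 0, ][1, ]
  expect_true(any(tidy(sw)$recall >= base$recall &
                    tidy(sw)$precision >= base$precision))
})
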