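binning_1mb <- make_binning(c(chr1 = 1e6), bin_size = 2e5)

test_that("reads increment the single bin containing their leftmost base", {
  aln <- tibble::tibble(chrom = "chr1",
                        pos = c(200001, 250000, 399999))  # all in bin 2
  counts <- bin_read_counts(aln, binning_1mb)
  expect_equal(counts, c(0L, 3L, 0L, 0L, 0L))

  ## a read spanning the bin-2/bin-3 boundary counts once, in bin 2
  spanning <- tibble::tibble(chrom = "chr1", pos = 399996)  # 10 bp alignment
  expect_equal(bin_read_counts(spanning, binning_1mb),
               c(0L, 1L, 0L, 0L, 0L))
})

test_that("duplicate, low-MAPQ and flagged reads are excluded", {
  aln <- tibble::tibble(
    chrom = "chr1",
    pos = c(1, 1, 1, 1, 1),
    mapq = c(60, 60, 10, 60, 60),
    duplicate = c(FALSE, TRUE, FALSE, FALSE, FALSE),
    secondary = c(FALSE, FALSE, FALSE, TRUE, FALSE),
    unmapped = c(FALSE, FALSE, FALSE, FALSE, TRUE),
    supplementary = FALSE
  )
  expect_equal(sum(bin_read_counts(aln, binning_1mb)), 1L)
  ## duplicates kept on request
  expect_equal(sum(bin_read_counts(aln, binning_1mb,
                                   exclude_duplicates = FALSE)), 2L)
  ## conservation: total counts == reads passing filters
  set.seed(5)
  rand <- tibble::tibble(chrom = "chr1", pos = sample(1e6, 500, TRUE),
                         mapq = sample(c(0, 30, 60), 500, TRUE))
  expect_equal(sum(bin_read_counts(rand, binning_1mb, min_mapq = 20)),
               sum(rand$mapq >= 20))
})

test_that("alignments on unknown chromosomes warn and are skipped", {
  aln <- tibble::tibble(chrom = c("chr1", "chrUn"), pos = c(1, 1))
  expect_warning(counts <- bin_read_counts(aln, binning_1mb), "chrUn")
  expect_equal(sum(counts), 1L)
  expect_error(bin_read_counts(aln, binning_1mb, on_missing_chrom = "error"),
               "chrUn")
})

test_that("BAM counting agrees with the alignment-table route", {
  recs <- tibble::tibble(
    chrom = c("chr1", "chr1", "chr1", "chr1"),
    pos = c(100, 250001, 250050, 900001),
    mapq = c(60, 60, 5, 60),
    flag = c(0L, 0L, 0L, 1024L)  # last one duplicate-flagged
  )
  dir <- withr::local_tempdir()
  bam <- toy_bam(recs, c(chr1 = 1e6), dir)
  counts <- bin_read_counts(bam, binning_1mb)
  expect_equal(counts, c(1L, 1L, 0L, 0L, 0L))

  tbl <- coverage_matrix(list(sampleA = bam), binning_1mb)
  expect_s3_class(tbl, "bin_counts")
  expect_equal(tbl$sampleA, counts)
  expect_equal(sample_names(tbl), "sampleA")
})

test_that("off-target accounting matches the panel regime", {
  ## three million reads, half off-target
  set.seed(9)
  n <- 30000  # 1:10000 scale model of the panel yield
  pos <- sample(1e6, n, replace = TRUE)
  targets <- tibble::tibble(chrom = "chr1", start = 0, end = 5e5)
  aln <- tibble::tibble(chrom = "chr1", pos = pos)
  st <- off_target_stats(list(s1 = aln), targets, genome_size = 1e6)
  expect_equal(st$total_reads, n)
  expect_equal(st$off_target_reads, sum(pos - 1 >= 5e5))
  expect_equal(st$off_target_fraction, st$off_target_reads / n)
  expect_equal(st$off_target_fraction, 0.5, tolerance = 0.02)
  expect_equal(st$mean_off_target_depth,
               st$off_target_reads * 100 / 5e5)

  ## every read on-target -> fraction 0; no targets -> fraction 1
  on <- tibble::tibble(chrom = "chr1", pos = seq(1, 1000))
  expect_equal(off_target_stats(list(s = on), targets, 1e6)$off_target_fraction, 0)
  expect_equal(off_target_stats(list(s = on), NULL, 1e6)$off_target_fraction, 1)
})

test_that("off-target fraction is invariant to target permutation and overlap", {
  set.seed(10)
  aln <- tibble::tibble(chrom = sample(c("chr1", "chr2"), 2000, TRUE),
                        pos = sample(1e6, 2000, TRUE))
  targets <- tibble::tibble(
    chrom = c("chr1", "chr1", "chr2"),
    start = c(1e5, 3e5, 0), end = c(2e5, 4e5, 1e5))
  base <- off_target_stats(list(s = aln), targets, 2e6)
  shuffled <- off_target_stats(list(s = aln), targets[c(3, 1, 2), ], 2e6)
  overlapping <- off_target_stats(
    list(s = aln),
    dplyr::bind_rows(targets, tibble::tibble(chrom = "chr1", start = 1.5e5,
                                             end = 3.5e5)), 2e6)
  expect_equal(shuffled$off_target_reads, base$off_target_reads)
  ## the extra interval bridges the two chr1 targets
  expect_equal(
    overlapping$off_target_reads,
    sum(!(aln$chrom == "chr1" & aln$pos - 1 >= 1e5 & aln$pos - 1 < 4e5) &
          !(aln$chrom == "chr2" & aln$pos - 1 < 1e5)))
})

test_that("bin-size recommendation walks the ladder", {
  ## panel regime: ~3e6 reads, ~50% off-target on a 3 Gb genome -> 200 kb
  expect_equal(recommend_bin_size(1.5e6, 3e9), 2e5)
  ## exome regime: ~15e6 off-target reads -> 20 kb
  expect_equal(recommend_bin_size(15e6, 3e9), 2e4)
  ## 76e6 reads at 20.3% off-target
  expect_equal(76e6 * 0.203, 15428000)
  expect_equal(recommend_bin_size(15428000, 3e9), 2e4)
  expect_error(recommend_bin_size(0, 3e9), "off-target")
  expect_warning(out <- recommend_bin_size(10, 3e9), "largest")
  expect_equal(out, 2e6)
})
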