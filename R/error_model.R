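#' Poisson floor on the dosage error
#'
#' The relative standard deviation of a Poisson count with expectation
#' `expected_reads` is `1/sqrt(expected_reads)`. This is the theoretical
#' minimum random error that the normalised read depth of a cell can have:
#' whatever the empirical error model says, the dosage of a bin observed
#' through N reads cannot be known more precisely than counting noise
#' allows.
#'
#' @param expected_reads Expected read count per cell (positive).
#' @return Relative standard deviation(s), same shape as the input.
#' @examples
#' poisson_floor(100)  # 0.1
#' @export
poisson_floor <- function(expected_reads) {
  if (any(!is.finite(expected_reads)) || any(expected_reads <= 0)) {
    abort("`expected_reads` must be positive and finite.")
  }
  1 / sqrt(expected_reads)
}

#' Estimate the per-cell dosage error
#'
#' The error of the relative dosage in sample s, bin b is modelled
#' multiplicatively:
#'
#'   sigma\[s,b\] = max( sd_bin\[b\] * sd_sample\[s\] / mean_sd,  floor\[s,b\] )
#'
#' where `sd_bin` is the standard deviation of dosage in that bin across
#' samples (how noisy the locus is), `sd_sample` the standard deviation of
#' the sample across bins (how noisy the sample is), and `mean_sd` the mean
#' of `sd_sample` over the cohort — so a sample of average noisiness gets
#' sigma equal to the bin's own sd. The Poisson floor
#' `1/sqrt(expected reads)` replaces any estimate below it, with expected
#' reads taken from the raw counts: the sample's mean count over active
#' bins times the bin's relative depth.
#'
#' Standard deviations are computed on the linear dosage scale, where the
#' deletion/duplication targets 0.5 and 1.5 live.
#'
#' @param dosage A `bin_dosage` tibble ([normalize_dosage()], optionally
#'   [svd_denoise()]d). Its attributes supply the expected-read model.
#' @return A `bin_sigma` tibble of the same wide shape, with attributes
#'   `sd_bin`, `sd_sample`, `mean_sd` and `floor` (the per-cell Poisson
#'   floor matrix, samples x bins).
#' @export
estimate_errors <- function(dosage) {
  d <- bin_matrix(dosage)
  if (nrow(d) < 3) {
    abort("error estimation needs at least 3 samples; use a larger cohort.")
  }
  sample_mean_count <- attr(dosage, "sample_mean_count")
  bin_rel <- attr(dosage, "bin_rel_depth")
  if (is.null(sample_mean_count) || is.null(bin_rel)) {
    abort("`dosage` must come from normalize_dosage() (attributes missing).")
  }

  sd_bin <- apply(d, 2, sd)
  sd_sample <- apply(d, 1, sd)
  mean_sd <- mean(sd_sample)
  model <- if (mean_sd > 0) outer(sd_sample, sd_bin) / mean_sd else 0 * d

  expected <- outer(sample_mean_count, bin_rel)
  floor_m <- 1 / sqrt(pmax(expected, .Machine$double.eps))
  sigma <- pmax(model, floor_m)

  out <- bin_table(sigma, dosage)
  structure(out,
            sd_bin = unname(sd_bin),
            sd_sample = sd_sample,
            mean_sd = mean_sd,
            floor = floor_m,
            class = c("bin_sigma", class(out)))
}
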