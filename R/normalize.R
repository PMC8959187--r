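#' Select analysable bins
#'
#' A bin is active when its mean raw count across samples reaches
#' `min_mean_count` (boundary inclusive). Inactive bins — centromeres,
#' unmappable sequence, bins starved of reads — carry no dosage signal and
#' are excluded from normalisation, error estimation and calling; a CNV call
#' may span them but they contribute no evidence.
#'
#' @param counts A `bin_counts` tibble (see [coverage_matrix()] /
#'   [read_counts_tsv()]).
#' @param min_mean_count Minimum mean raw count (default 1).
#' @return A logical vector, one element per bin row of `counts`.
#' @export
select_active_bins <- function(counts, min_mean_count = 1) {
  m <- bin_matrix(counts)
  active <- colMeans(m) >= min_mean_count
  if (!any(active)) abort("no active bins: every bin is below `min_mean_count`.")
  unname(active)
}

#' Normalise read counts to relative dosage
#'
#' Two-step normalisation: each sample's counts are first divided by that
#' sample's mean count over active bins (removing library-size differences),
#' then each bin's column is divided by its across-sample mean of the
#' step-one values (removing locus-specific capture/mappability bias). The
#' result is the relative dosage `d`, scaled so that 1.0 is diploid-normal,
#' 0.5 a heterozygous deletion and 1.5 a heterozygous duplication; each
#' bin's across-sample mean is exactly 1.
#'
#' @param counts A `bin_counts` tibble with at least two samples.
#' @param active Logical mask from [select_active_bins()]; computed with
#'   default settings when `NULL`.
#' @param min_mean_count Used when `active` is `NULL`.
#' @return A `bin_dosage` tibble over the active bins only (same wide
#'   layout), with attributes `active` (the mask over the original rows),
#'   `sample_mean_count` (per-sample mean raw count over active bins) and
#'   `bin_rel_depth` (per-bin relative depth, the step-two divisor).
#' @export
normalize_dosage <- function(counts, active = NULL, min_mean_count = 1) {
  sm <- sample_names(counts)
  if (length(sm) < 2) abort("normalisation needs at least 2 samples.")
  if (is.null(active)) active <- select_active_bins(counts, min_mean_count)
  m <- bin_matrix(counts)[, active, drop = FALSE]

  sample_mean <- rowMeans(m)
  if (any(sample_mean <= 0)) {
    abort(paste0("sample(s) with zero reads over active bins: ",
                 paste(names(sample_mean)[sample_mean <= 0], collapse = ", ")))
  }
  step1 <- m / sample_mean
  bin_rel <- colMeans(step1)
  d <- sweep(step1, 2, bin_rel, "/")

  out <- bin_table(d, counts[active, ])
  structure(out,
            active = active,
            sample_mean_count = sample_mean,
            bin_rel_depth = unname(bin_rel),
            class = c("bin_dosage", class(out)))
}

#' Remove shared biases from log dosage by truncated SVD
#'
#' Systematic biases common to multiple samples — batch, chemistry, sample
#' handling — show up as high-variance low-rank structure in the log-dosage
#' matrix. The singular value decomposition `log d = U S V'` is computed,
#' the rank-`n_discard` reconstruction from the largest singular values is
#' subtracted, and the residual is exponentiated back to the dosage scale.
#' `n_discard = 0` is the identity.
#'
#' Genuine CNVs survive because they are private to one sample and a small
#' genomic span, contributing little to the leading singular vectors.
#'
#' @param dosage A `bin_dosage` tibble from [normalize_dosage()].
#' @param n_discard Number of leading singular vectors to discard
#'   (default 5).
#' @param dosage_floor Dosage values below this are raised to it before the
#'   log (default 0.01), keeping zero-count cells finite while preserving a
#'   strong deletion signal.
#' @return A `bin_dosage` tibble of the same shape, with attributes carried
#'   over and `n_discarded_vectors` recorded.
#' @export
svd_denoise <- function(dosage, n_discard = 5, dosage_floor = 0.01) {
  if (n_discard == 0) {
    attr(dosage, "n_discarded_vectors") <- 0L
    return(dosage)
  }
  m <- bin_matrix(dosage)
  if (n_discard < 0 || n_discard >= min(dim(m))) {
    abort("`n_discard` must be in [0, min(samples, active bins) - 1].")
  }
  L <- log(pmax(m, dosage_floor))
  sv <- svd(L, nu = n_discard, nv = n_discard)
  low_rank <- sv$u %*% (sv$d[seq_len(n_discard)] * t(sv$v))
  resid <- exp(L - low_rank)

  out <- bin_table(resid, dosage)
  structure(out,
            active = attr(dosage, "active"),
            sample_mean_count = attr(dosage, "sample_mean_count"),
            bin_rel_depth = attr(dosage, "bin_rel_depth"),
            n_discarded_vectors = as.integer(n_discard),
            class = c("bin_dosage", class(out)))
}
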