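## Emission probabilities and the 3-state HMM.
##
## States are indexed 1 = DEL, 2 = NORM, 3 = DUP throughout.

CNV_STATES <- c("DEL", "NORM", "DUP")

#' Cumulative normal probability, clamped for log safety
#'
#' Standard-normal CDF with the result clamped to `[1e-300, 1 - 1e-16]` so
#' that its logarithm is always finite. Accuracy of the underlying erf-based
#' evaluation is far better than the 1e-6 the emission model needs.
#'
#' @param z Numeric vector of z-scores.
#' @return Probabilities in `[1e-300, 1 - 1e-16]`.
#' @export
normal_cdf <- function(z) {
  pmin(pmax(pnorm(z), 1e-300), 1 - 1e-16)
}

#' Per-bin emission probabilities for the three copy-number states
#'
#' Given dosage `d` and its error `sigma`, the evidence for each state is a
#' one-sided tail probability of the normal distribution centred on the
#' state's expected dosage:
#' deletion `P(d <= 0.5)`, duplication `P(d >= 1.5)`, and normal dosage
#' `P(d <= 1)` or `P(d >= 1)` (whichever side `d` falls on). In the default
#' non-mosaic mode this means a bin only favours a CNV state once its dosage
#' crosses the midpoint between 1 and 0.5 (or 1.5) — full heterozygous
#' events, not mosaics. Mosaic mode instead scores deviation from 1 in
#' either direction (`P(d <= 1)` toward deletion, `P(d >= 1)` toward
#' duplication), admitting intermediate dosages.
#'
#' The three probabilities are tail areas, not a partition; they are used as
#' unnormalised emission weights (Viterbi is invariant to per-bin scaling).
#'
#' @param d Dosage values (vector or matrix).
#' @param sigma Matching error estimates, all positive.
#' @param mosaic Logical, default `FALSE`.
#' @return A list with elements `p_del`, `p_norm`, `p_dup`, each the shape
#'   of `d`.
#' @export
cnv_emissions <- function(d, sigma, mosaic = FALSE) {
  le <- cnv_log_emissions(d, sigma, mosaic = mosaic)
  list(p_del = pmax(exp(le$log_del), 1e-300),
       p_norm = pmax(exp(le$log_norm), 1e-300),
       p_dup = pmax(exp(le$log_dup), 1e-300))
}

#' @rdname cnv_emissions
#' @details `cnv_log_emissions()` returns the same tail probabilities on
#'   the natural-log scale, evaluated directly in log space
#'   (`pnorm(log.p = TRUE)`). This is what the HMM consumes: far in the
#'   tails (small `sigma`), the probabilities themselves underflow to the
#'   clamp and lose their ordering, while the log values stay finite and
#'   strictly ordered — which is what makes the non-mosaic midpoint gate
#'   exact in the small-`sigma` limit.
#' @export
cnv_log_emissions <- function(d, sigma, mosaic = FALSE) {
  if (any(sigma <= 0)) abort("`sigma` must be positive.")
  log_norm <- pnorm(-abs(d - 1) / sigma, log.p = TRUE)
  if (mosaic) {
    log_del <- pnorm((1 - d) / sigma, log.p = TRUE)
    log_dup <- pnorm((d - 1) / sigma, log.p = TRUE)
  } else {
    log_del <- pnorm((0.5 - d) / sigma, log.p = TRUE)
    log_dup <- pnorm((d - 1.5) / sigma, log.p = TRUE)
  }
  log_up <- log1p(-1e-16)
  list(log_del = pmin(log_del, log_up),
       log_norm = pmin(log_norm, log_up),
       log_dup = pmin(log_dup, log_up))
}

#' Most probable copy-number state path (Viterbi)
#'
#' Decodes the maximum-a-posteriori state sequence of a three-state HMM
#' (deletion, normal, duplication) over one chromosome's bins. The chain
#' has stay probability `1 - 2t` and switch probability `t` to each other
#' state, and initial distribution `(t, 1 - 2t, t)` — the same `t` acts as
#' the prior against opening a CNV. Computation is in log space; ties are
#' broken toward NORM, then DEL.
#'
#' @param log_emission Matrix with one row per bin and columns
#'   `(DEL, NORM, DUP)` of log emission weights.
#' @param trans_prob Transition probability `t`, in (0, 0.5).
#' @return Integer vector of states (1 = DEL, 2 = NORM, 3 = DUP).
#' @export
viterbi_path <- function(log_emission, trans_prob) {
  if (!is.matrix(log_emission) || ncol(log_emission) != 3) {
    abort("`log_emission` must be an n x 3 matrix.")
  }
  n <- nrow(log_emission)
  if (n == 0) abort("empty emission sequence.")
  if (trans_prob <= 0 || trans_prob >= 0.5) {
    abort("`trans_prob` must be in (0, 0.5).")
  }
  log_t <- log(trans_prob)
  log_stay <- log1p(-2 * trans_prob)
  ## log transition matrix: [from, to]
  ltrans <- matrix(log_t, 3, 3)
  diag(ltrans) <- log_stay
  ## tie-break preference order: NORM, DEL, DUP
  pref <- c(2L, 1L, 3L)

  score <- c(log_t, log_stay, log_t) + log_emission[1, ]
  back <- matrix(0L, n, 3)
  if (n > 1) {
    for (i in 2:n) {
      new_score <- numeric(3)
      for (to in 1:3) {
        cand <- score + ltrans[, to]
        best <- pref[which.max(cand[pref])]
        back[i, to] <- best
        new_score[to] <- cand[best] + log_emission[i, to]
      }
      score <- new_score
    }
  }
  path <- integer(n)
  path[n] <- pref[which.max(score[pref])]
  if (n > 1) {
    for (i in n:2) path[i - 1] <- back[i, path[i]]
  }
  path
}

#' Segment a state path into CNV calls
#'
#' Maximal runs of the DEL (or DUP) state over a chromosome's active bins
#' become one call each. Call coordinates are bin-aligned: the start of the
#' run's first bin to the end of its last. Inactive bins lying between two
#' active bins of a run are spanned by the call but contribute nothing to
#' `n_bins` or the evidence (the path is defined on active bins only, so
#' this falls out of the construction).
#'
#' @param path Integer state path over the chromosome's active bins.
#' @param bins Tibble of those bins' `chrom`, `start`, `end` (same order).
#' @param d Dosage over the same bins.
#' @param log_lr Per-bin log-likelihood ratio `log p_state - log p_norm`
#'   for the state the path assigns (used for the quality score).
#' @param sample_id Sample identifier for the output rows.
#' @return A calls tibble: `sample`, `chrom`, `start`, `end`, `type`,
#'   `n_bins`, `mean_dosage`, `quality`.
#' @export
segment_calls <- function(path, bins, d, log_lr, sample_id) {
  stopifnot(length(path) == nrow(bins), length(d) == length(path),
            length(log_lr) == length(path))
  runs <- rle(path)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  keep <- runs$values != 2L
  empty <- tibble::tibble(sample = character(), chrom = character(),
                          start = numeric(), end = numeric(),
                          type = character(), n_bins = integer(),
                          mean_dosage = numeric(), quality = numeric())
  if (!any(keep)) return(empty)
  purrr::map_dfr(which(keep), function(r) {
    i <- starts[r]:ends[r]
    tibble::tibble(
      sample = sample_id,
      chrom = bins$chrom[i[1]],
      start = bins$start[i[1]],
      end = bins$end[i[length(i)]],
      type = CNV_STATES[runs$values[r]],
      n_bins = length(i),
      mean_dosage = mean(d[i]),
      quality = max(0, 10 / log(10) * sum(log_lr[i]))
    )
  })
}

#' Call CNVs across a cohort
#'
#' Runs the full read-depth calling pipeline on a per-bin count table:
#' active-bin selection, two-step dosage normalisation
#' ([normalize_dosage()]), SVD denoising ([svd_denoise()]), multiplicative
#' error estimation with a Poisson floor ([estimate_errors()]), per-bin
#' emission probabilities ([cnv_emissions()]), Viterbi decoding of the
#' three-state HMM per sample per chromosome ([viterbi_path()]), and
#' segmentation into scored calls ([segment_calls()]). Deterministic given
#' inputs and parameters.
#'
#' The quality of a call is a phred-scaled sum of per-bin log-likelihood
#' ratios of the called state against normal dosage, floored at 0; it grows
#' with both per-bin evidence and the number of supporting bins, and is the
#' quantity to threshold when trading precision against recall.
#'
#' @param counts A `bin_counts` tibble (>= 3 samples).
#' @param n_discard Leading singular vectors to discard (default 5; 0
#'   disables denoising).
#' @param trans_prob HMM transition probability (default 1e-5, the
#'   geometric midpoint of the useful 1e-10..0.1 range).
#' @param mosaic Call mosaic CNVs (default `FALSE`; see [cnv_emissions()]).
#' @param min_quality Drop calls below this quality (default 0: keep all).
#' @param min_mean_count Active-bin threshold (default 1).
#' @param dosage_floor Floor before the log in the SVD step (default 0.01).
#' @return An object of class `cnv_fit`: a list with `calls` (tibble),
#'   `dosage` and `sigma` (wide bin tibbles over active bins), `active`
#'   (mask), `binning` key of the input, and `params`. Use [tidy()] for the
#'   calls, [glance()] for a one-row summary, [augment()] for the per-cell
#'   dosage/error table, and [autoplot()] to draw a region.
#' @export
call_cnvs <- function(counts, n_discard = 5, trans_prob = 1e-5,
                      mosaic = FALSE, min_quality = 0,
                      min_mean_count = 1, dosage_floor = 0.01) {
  sm <- sample_names(counts)
  if (length(sm) < 3) abort("CNV calling needs at least 3 samples.")
  active <- select_active_bins(counts, min_mean_count)
  dosage <- normalize_dosage(counts, active = active)
  dosage <- svd_denoise(dosage, n_discard = n_discard,
                        dosage_floor = dosage_floor)
  sigma <- estimate_errors(dosage)

  d <- bin_matrix(dosage)
  s <- bin_matrix(sigma)
  em <- cnv_log_emissions(d, s, mosaic = mosaic)
  chroms <- dosage$chrom
  bin_key <- dosage[, c("chrom", "start", "end")]

  calls <- purrr::map_dfr(sm, function(id) {
    le_del <- em$log_del[id, ]
    le_norm <- em$log_norm[id, ]
    le_dup <- em$log_dup[id, ]
    purrr::map_dfr(unique(chroms), function(ch) {
      j <- which(chroms == ch)
      le <- cbind(le_del[j], le_norm[j], le_dup[j])
      path <- viterbi_path(le, trans_prob)
      log_lr <- le[cbind(seq_along(j), path)] - le[, 2]
      segment_calls(path, bin_key[j, ], d[id, j], log_lr, id)
    })
  })
  calls <- calls[calls$quality >= min_quality, , drop = FALSE]
  calls <- calls[order(match(calls$sample, sm), calls$chrom, calls$start), ]

  structure(list(
    calls = tibble::as_tibble(calls),
    dosage = dosage,
    sigma = sigma,
    active = active,
    counts = counts,
    params = list(n_discard = n_discard, trans_prob = trans_prob,
                  mosaic = mosaic, min_quality = min_quality,
                  min_mean_count = min_mean_count,
                  dosage_floor = dosage_floor)
  ), class = "cnv_fit")
}

#' @export
print.cnv_fit <- function(x, ...) {
  p <- x$params
  cat(sprintf(paste0(
    "<cnv_fit> %d sample(s), %d active / %d bins\n",
    "  svd vectors discarded: %d; transition probability: %g; mode: %s\n",
    "  %d call(s): %d DEL, %d DUP (min quality %g)\n"),
    length(sample_names(x$counts)), sum(x$active), length(x$active),
    p$n_discard, p$trans_prob, if (p$mosaic) "mosaic" else "non-mosaic",
    nrow(x$calls), sum(x$calls$type == "DEL"), sum(x$calls$type == "DUP"),
    p$min_quality))
  invisible(x)
}

#' Tidiers for fitted CNV call sets
#'
#' `tidy()` returns the calls, one row per CNV; `glance()` a one-row cohort
#' summary; `augment()` the long per-sample-per-bin table of dosage and
#' error underlying the calls.
#'
#' @param x A `cnv_fit` from [call_cnvs()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy cnv_fit
#' @export
tidy.cnv_fit <- function(x, ...) x$calls

#' @rdname tidy.cnv_fit
#' @method glance cnv_fit
#' @export
glance.cnv_fit <- function(x, ...) {
  tibble::tibble(
    n_samples = length(sample_names(x$counts)),
    n_bins = length(x$active),
    n_active_bins = sum(x$active),
    n_discard = x$params$n_discard,
    trans_prob = x$params$trans_prob,
    mosaic = x$params$mosaic,
    n_calls = nrow(x$calls),
    n_del = sum(x$calls$type == "DEL"),
    n_dup = sum(x$calls$type == "DUP"),
    median_quality = if (nrow(x$calls)) stats::median(x$calls$quality) else NA_real_
  )
}

#' @rdname tidy.cnv_fit
#' @method augment cnv_fit
#' @export
augment.cnv_fit <- function(x, ...) {
  d_long <- tidyr::pivot_longer(x$dosage, -c("chrom", "start", "end"),
                                names_to = "sample", values_to = "dosage")
  s_long <- tidyr::pivot_longer(x$sigma, -c("chrom", "start", "end"),
                                names_to = "sample", values_to = "sigma")
  dplyr::inner_join(d_long, s_long,
                    by = c("chrom", "start", "end", "sample"))
}
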