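## Benchmarking harness: any-overlap matching of calls against a truth set,
## precision/recall/f, boundary-location error, quality-threshold and
## parameter sweeps with best-precision-per-recall frontier selection.

#' Match CNV calls against a truth set
#'
#' A truth CNV is *detected* iff some call of the same sample (and, by
#' default, the same type) overlaps it by at least 1 bp; a call is *true*
#' iff it overlaps some truth CNV under the same rule. Coordinates are
#' 0-based half-open, so abutting intervals do not overlap. One call may
#' detect two truth CNVs (and remains a single true call); both relations
#' are recorded explicitly, so the number of true calls need not equal the
#' number of detected truths.
#'
#' @param calls Calls tibble (`sample`, `chrom`, `start`, `end`, `type`, ...).
#' @param truth Truth tibble with the same columns (plus anything else).
#' @param same_type_required Require type agreement for a match
#'   (default `TRUE`: a DUP call cannot validate a DEL truth).
#' @return A `cnv_match` list: `calls` and `truth` with a logical
#'   `matched` column added, `pairs` (matched pairs with `start_offset`
#'   and `end_offset` in bp), and counts `tp` (true calls), `fp`, `fn`,
#'   `n_detected`.
#' @export
match_calls <- function(calls, truth, same_type_required = TRUE) {
  calls <- tibble::as_tibble(calls)
  truth <- tibble::as_tibble(truth)
  calls$.call_id <- seq_len(nrow(calls))
  truth$.truth_id <- seq_len(nrow(truth))

  by <- if (same_type_required) c("sample", "chrom", "type") else c("sample", "chrom")
  pairs <- dplyr::inner_join(
    calls[, c(".call_id", by, "start", "end")],
    truth[, c(".truth_id", by, "start", "end")],
    by = by, suffix = c("_call", "_truth"),
    relationship = "many-to-many"
  )
  pairs <- dplyr::filter(pairs, .data$start_call < .data$end_truth,
                         .data$start_truth < .data$end_call)
  pairs <- dplyr::mutate(pairs,
                         start_offset = abs(.data$start_call - .data$start_truth),
                         end_offset = abs(.data$end_call - .data$end_truth))

  calls$matched <- calls$.call_id %in% pairs$.call_id
  truth$matched <- truth$.truth_id %in% pairs$.truth_id
  structure(list(
    calls = calls[, setdiff(names(calls), ".call_id")],
    truth = truth[, setdiff(names(truth), ".truth_id")],
    pairs = tibble::as_tibble(pairs),
    tp = sum(calls$matched),
    fp = sum(!calls$matched),
    fn = sum(!truth$matched),
    n_detected = sum(truth$matched)
  ), class = "cnv_match")
}

#' @export
print.cnv_match <- function(x, ...) {
  cat(sprintf("<cnv_match> %d call(s) vs %d truth CNV(s): TP %d, FP %d, FN %d\n",
              nrow(x$calls), nrow(x$truth), x$tp, x$fp, x$fn))
  invisible(x)
}

#' Precision, recall and the f statistic
#'
#' Recall is the fraction of truth CNVs detected; precision the fraction of
#' calls that are true; f their harmonic mean (0 whenever precision or
#' recall is 0 or undefined). With zero calls, precision is reported as
#' missing (`NA`), not 1: an empty call set earns no precision credit.
#'
#' @param match A `cnv_match` from [match_calls()].
#' @return A one-row tibble: `recall`, `precision`, `f`, `tp`, `fp`, `fn`,
#'   `n_calls`, `n_truth`, `n_detected`.
#' @export
precision_recall <- function(match) {
  stopifnot(inherits(match, "cnv_match"))
  n_truth <- nrow(match$truth)
  if (n_truth == 0) abort("empty truth set: recall is undefined.")
  n_calls <- nrow(match$calls)
  recall <- match$n_detected / n_truth
  precision <- if (n_calls > 0) match$tp / n_calls else NA_real_
  f <- if (!is.na(precision) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  tibble::tibble(recall = recall, precision = precision, f = f,
                 tp = match$tp, fp = match$fp, fn = match$fn,
                 n_calls = n_calls, n_truth = n_truth,
                 n_detected = match$n_detected)
}

#' Mean absolute boundary-location error
#'
#' For each matched (call, truth) pair, the absolute start and end offsets
#' in bp; the statistic is the mean over both endpoints of all pairs. With
#' bin-aligned calling, this error scales with the analysis bin size.
#'
#' @param match A `cnv_match`.
#' @return Mean absolute boundary error in bp, or `NA` with no matches.
#' @export
boundary_error <- function(match) {
  stopifnot(inherits(match, "cnv_match"))
  if (nrow(match$pairs) == 0) return(NA_real_)
  mean(c(match$pairs$start_offset, match$pairs$end_offset))
}

#' Stratify truth CNVs by size
#'
#' The bands used in size-stratified reporting: `<1 Mb`, `1-5 Mb`, `>5 Mb`
#' (left-open, right-closed at 1 Mb and 5 Mb); they partition the truth set.
#'
#' @param truth Truth tibble with `start`, `end`.
#' @return The tibble with a `size_band` factor column added.
#' @export
stratify_sizes <- function(truth) {
  size <- truth$end - truth$start
  truth$size_band <- cut(size, c(0, 1e6, 5e6, Inf),
                         labels = c("<1Mb", "1-5Mb", ">5Mb"), right = TRUE)
  truth
}

#' Best precision per recall (the PR frontier)
#'
#' From a table of operating points, keeps for each achieved recall the
#' maximum precision and drops dominated points, giving a frontier along
#' which precision is non-increasing as recall increases. Points with
#' missing precision (zero calls) are dropped.
#'
#' @param points Tibble with at least `recall` and `precision`.
#' @return The frontier subset, ordered by increasing recall.
#' @export
pr_frontier <- function(points) {
  pts <- dplyr::filter(points, !is.na(.data$precision))
  if (nrow(pts) == 0) return(pts)
  pts <- dplyr::arrange(pts, dplyr::desc(.data$recall),
                        dplyr::desc(.data$precision))
  keep <- pts$precision > dplyr::lag(cummax(pts$precision), default = -Inf)
  dplyr::arrange(pts[keep, ], .data$recall)
}

#' Sweep calling parameters and quality thresholds
#'
#' Reproduces the benchmarking protocol used to compare read-depth CNV
#' callers: run the caller over a parameter grid, try every possible
#' quality cut-off for each run, score precision and recall of each
#' operating point against the truth set, and select the best precision
#' achieved for each possible recall.
#'
#' @param counts A `bin_counts` tibble.
#' @param truth Truth tibble.
#' @param grid Data frame of parameter combinations; recognised columns
#'   are `n_discard`, `trans_prob`, `mosaic` and `rebin_factor` (integer
#'   coarsening of the bin grid; 1 = as supplied). Defaults fill in
#'   missing columns.
#' @param same_type_required Passed to [match_calls()].
#' @return A `cnv_sweep` list: `points` (every operating point with
#'   parameter provenance), `frontier` ([pr_frontier()] of the points),
#'   and `summary` (max f on the frontier and the highest recall with
#'   precision >= 50%). `tidy()` returns the frontier, `glance()` the
#'   summary, `autoplot()` a precision-recall plot.
#' @export
sweep_cnv_calls <- function(counts, truth, grid = NULL,
                            same_type_required = TRUE) {
  if (is.null(grid)) grid <- tibble::tibble(n_discard = 5)
  grid <- tibble::as_tibble(grid)
  if (!"n_discard" %in% names(grid)) grid$n_discard <- 5
  if (!"trans_prob" %in% names(grid)) grid$trans_prob <- 1e-5
  if (!"mosaic" %in% names(grid)) grid$mosaic <- FALSE
  if (!"rebin_factor" %in% names(grid)) grid$rebin_factor <- 1L

  points <- purrr::map_dfr(seq_len(nrow(grid)), function(g) {
    cc <- if (grid$rebin_factor[g] > 1) {
      rebin_counts(counts, grid$rebin_factor[g])
    } else counts
    fit <- call_cnvs(cc, n_discard = grid$n_discard[g],
                     trans_prob = grid$trans_prob[g],
                     mosaic = grid$mosaic[g], min_quality = 0)
    calls <- fit$calls
    cutoffs <- sort(unique(c(0, calls$quality)))
    purrr::map_dfr(cutoffs, function(q) {
      m <- match_calls(calls[calls$quality >= q, , drop = FALSE], truth,
                       same_type_required = same_type_required)
      dplyr::mutate(precision_recall(m),
                    min_quality = q,
                    n_discard = grid$n_discard[g],
                    trans_prob = grid$trans_prob[g],
                    mosaic = grid$mosaic[g],
                    rebin_factor = grid$rebin_factor[g])
    })
  })
  frontier <- pr_frontier(points)
  at50 <- dplyr::filter(frontier, .data$precision >= 0.5)
  summary <- tibble::tibble(
    best_f = if (nrow(frontier)) max(frontier$f) else 0,
    max_recall_precision50 = if (nrow(at50)) max(at50$recall) else 0
  )
  structure(list(points = points, frontier = frontier, summary = summary),
            class = "cnv_sweep")
}

#' @export
print.cnv_sweep <- function(x, ...) {
  cat(sprintf("<cnv_sweep> %d operating point(s), frontier of %d; best f %.3f\n",
              nrow(x$points), nrow(x$frontier), x$summary$best_f))
  invisible(x)
}

#' @rdname sweep_cnv_calls
#' @param x A `cnv_sweep`.
#' @param ... Unused.
#' @method tidy cnv_sweep
#' @export
tidy.cnv_sweep <- function(x, ...) x$frontier

#' @rdname sweep_cnv_calls
#' @method glance cnv_sweep
#' @export
glance.cnv_sweep <- function(x, ...) x$summary

#' Coarsen a count table by an integer factor
#'
#' Aggregates runs of `factor` adjacent bins within each chromosome into
#' one bin (the trailing remainder bins form a final shorter bin), giving
#' the count table that a `factor`-times larger bin size would have
#' produced.
#'
#' @param counts A `bin_counts` tibble on a uniform bin grid.
#' @param factor Positive integer.
#' @return A `bin_counts` tibble.
#' @export
rebin_counts <- function(counts, factor) {
  stopifnot(factor >= 1, factor == round(factor))
  if (factor == 1) return(counts)
  sm <- sample_names(counts)
  grouped <- counts |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(.grp = (dplyr::row_number() - 1) %/% factor) |>
    dplyr::group_by(.data$chrom, .data$.grp) |>
    dplyr::summarise(start = min(.data$start), end = max(.data$end),
                     dplyr::across(dplyr::all_of(sm), sum),
                     .groups = "drop") |>
    dplyr::arrange(.data$chrom, .data$start) |>
    dplyr::select(-".grp")
  as_bin_counts(grouped[, c("chrom", "start", "end", sm)])
}
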