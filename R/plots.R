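#' Plot the dosage track of a sample over a region
#'
#' Draws each active bin's relative dosage with an error bar of plus/minus
#' one estimated sigma, with guide lines at 0.5, 1.0 and 1.5 (heterozygous
#' deletion, normal, heterozygous duplication) and the fitted calls for the
#' sample shaded. This is the standard diagnostic view of a called CNV:
#' bins inside a heterozygous deletion sit near 0.5, flanking bins near 1.
#'
#' @param fit A `cnv_fit` from [call_cnvs()].
#' @param sample Sample identifier.
#' @param region Region string (see [parse_region()]) or `NULL` for the
#'   whole genome.
#' @return A ggplot object.
#' @export
plot_dosage <- function(fit, sample, region = NULL) {
  stopifnot(inherits(fit, "cnv_fit"))
  if (!sample %in% sample_names(fit$dosage)) {
    abort(paste0("unknown sample: ", sample))
  }
  df <- tibble::tibble(
    chrom = fit$dosage$chrom,
    start = fit$dosage$start,
    end = fit$dosage$end,
    dosage = fit$dosage[[sample]],
    sigma = fit$sigma[[sample]]
  )
  calls <- fit$calls[fit$calls$sample == sample, ]
  if (!is.null(region)) {
    r <- parse_region(region)
    df <- df[df$chrom == r$chrom & df$end > r$start & df$start < r$end, ]
    calls <- calls[calls$chrom == r$chrom & calls$end > r$start &
                     calls$start < r$end, ]
  }
  df$mid <- (df$start + df$end) / 2
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$mid, y = .data$dosage)) +
    ggplot2::geom_hline(yintercept = c(0.5, 1, 1.5), linetype = "dotted",
                        colour = "grey50") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$dosage - .data$sigma,
                                        ymax = .data$dosage + .data$sigma),
                           width = 0, colour = "grey40") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (bp)", y = "relative dosage",
                  title = paste0(sample,
                                 if (!is.null(region)) paste0(" ", region))) +
    ggplot2::theme_bw()
  if (nrow(calls) > 0) {
    p <- p + ggplot2::geom_rect(
      data = calls, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$start, xmax = .data$end,
                   ymin = -Inf, ymax = Inf, fill = .data$type),
      alpha = 0.15) +
      ggplot2::scale_fill_manual(values = c(DEL = "firebrick",
                                            DUP = "dodgerblue3"))
  }
  p
}

#' @rdname plot_dosage
#' @param object A `cnv_fit`.
#' @param ... Passed to [plot_dosage()].
#' @method autoplot cnv_fit
#' @export
autoplot.cnv_fit <- function(object, ...) plot_dosage(object, ...)

#' Precision-recall plot for a parameter sweep
#'
#' All operating points in grey, the best-precision-per-recall frontier as
#' a line, with the best f statistic annotated.
#'
#' @param object A `cnv_sweep` from [sweep_cnv_calls()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cnv_sweep
#' @export
autoplot.cnv_sweep <- function(object, ...) {
  pts <- dplyr::filter(object$points, !is.na(.data$precision))
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$recall, y = .data$precision)) +
    ggplot2::geom_point(colour = "grey60", size = 1) +
    ggplot2::geom_step(data = object$frontier, direction = "vh",
                       colour = "firebrick") +
    ggplot2::geom_point(data = object$frontier, colour = "firebrick") +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "recall", y = "precision",
                  subtitle = sprintf("best f = %.3f", object$summary$best_f)) +
    ggplot2::theme_bw()
}

#' @rdname autoplot.cnv_sweep
#' @export
plot_pr_frontier <- function(object, ...) autoplot.cnv_sweep(object, ...)
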