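## Read counting and on/off-target accounting.
##
## Alignments come in either as a BAM path (read through Rsamtools) or as a
## tibble of alignment records with columns `chrom`, `pos` (1-based leftmost
## aligned base, as in SAM) and optionally `mapq`, `duplicate`, `secondary`,
## `supplementary`, `unmapped`. The tibble route keeps the counting logic
## testable without any binary fixtures.

normalize_alignments <- function(alignments) {
  if (is.character(alignments) && length(alignments) == 1) {
    return(read_bam_alignments(alignments))
  }
  aln <- tibble::as_tibble(alignments)
  if (!all(c("chrom", "pos") %in% names(aln))) {
    abort("alignment records need columns `chrom` and `pos`.")
  }
  for (col in c("duplicate", "secondary", "supplementary", "unmapped")) {
    if (!col %in% names(aln)) aln[[col]] <- FALSE
  }
  if (!"mapq" %in% names(aln)) aln$mapq <- 60L
  aln
}

read_bam_alignments <- function(path) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    abort("reading BAM files requires the Rsamtools package.")
  }
  flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE)
  p <- Rsamtools::ScanBamParam(flag = flags,
                               what = c("rname", "pos", "mapq", "flag"))
  res <- Rsamtools::scanBam(path, param = p)[[1]]
  tibble::tibble(
    chrom = as.character(res$rname),
    pos = res$pos,
    mapq = ifelse(is.na(res$mapq), 0L, res$mapq),
    duplicate = bitwAnd(res$flag, 1024L) > 0L,
    secondary = FALSE, supplementary = FALSE, unmapped = FALSE
  )
}

filter_alignments <- function(aln, min_mapq, exclude_duplicates) {
  keep <- !aln$unmapped & !aln$secondary & !aln$supplementary &
    aln$mapq >= min_mapq
  if (exclude_duplicates) keep <- keep & !aln$duplicate
  aln[keep, , drop = FALSE]
}

#' Count reads per genomic bin
#'
#' Each passing read increments exactly one bin: the bin containing its
#' leftmost aligned base, so a read spanning a bin boundary is counted once.
#' Unmapped, secondary, supplementary and (by default) duplicate-flagged
#' reads are excluded, as are reads below the mapping-quality cutoff.
#'
#' @param alignments A BAM path or a tibble of alignment records (columns
#'   `chrom`, `pos` 1-based leftmost base; optional `mapq`, `duplicate`,
#'   `secondary`, `supplementary`, `unmapped`).
#' @param binning A [make_binning()] frame.
#' @param min_mapq Minimum mapping quality (default 20).
#' @param exclude_duplicates Drop duplicate-flagged reads (default `TRUE`).
#' @param on_missing_chrom `"warn"` (skip reads on chromosomes absent from
#'   the binning, with a warning) or `"error"`.
#' @return An integer vector of counts, one per bin of `binning`.
#' @export
bin_read_counts <- function(alignments, binning, min_mapq = 20,
                            exclude_duplicates = TRUE,
                            on_missing_chrom = c("warn", "error")) {
  on_missing_chrom <- match.arg(on_missing_chrom)
  aln <- filter_alignments(normalize_alignments(alignments),
                           min_mapq, exclude_duplicates)
  known <- aln$chrom %in% unique(binning$chrom)
  if (!all(known)) {
    msg <- paste0("alignments on chromosome(s) absent from the binning: ",
                  paste(unique(aln$chrom[!known]), collapse = ", "))
    if (on_missing_chrom == "error") abort(msg)
    warn(paste0(msg, " (skipped)"))
    aln <- aln[known, , drop = FALSE]
  }
  idx <- bin_index_for(binning, aln$chrom, aln$pos - 1)
  counts <- tabulate(idx[!is.na(idx)], nbins = nrow(binning))
  as.integer(counts)
}

#' Build a per-bin count table for a cohort
#'
#' Runs [bin_read_counts()] for each sample and assembles the wide count
#' table used throughout the package: one row per bin (`chrom`, `start`,
#' `end`) and one integer column per sample.
#'
#' @param samples A named list (or named character vector of BAM paths);
#'   names become sample identifiers.
#' @inheritParams bin_read_counts
#' @param ... Passed to [bin_read_counts()].
#' @return A `bin_counts` tibble.
#' @export
coverage_matrix <- function(samples, binning, ...) {
  if (is.null(names(samples)) || any(names(samples) == "")) {
    abort("`samples` must be named; names become sample identifiers.")
  }
  counts <- purrr::map(samples, bin_read_counts, binning = binning, ...)
  out <- dplyr::bind_cols(
    binning[, c("chrom", "start", "end")],
    tibble::as_tibble(counts)
  )
  as_bin_counts(out)
}

as_bin_counts <- function(x) {
  x <- tibble::as_tibble(x)
  stopifnot(all(c("chrom", "start", "end") %in% names(x)))
  class(x) <- unique(c("bin_counts", class(x)))
  x
}

#' Sample columns of a bin-level table
#'
#' The wide tables used by this package key rows by `chrom`, `start`, `end`;
#' every other column is one sample.
#'
#' @param x A bin-level tibble.
#' @return Character vector of sample column names.
#' @export
sample_names <- function(x) {
  setdiff(names(x), c("chrom", "start", "end", "bin", "partial"))
}

## samples x bins matrix from a wide bin table
bin_matrix <- function(x) {
  sm <- sample_names(x)
  m <- t(as.matrix(x[, sm, drop = FALSE]))
  rownames(m) <- sm
  m
}

## wide bin table from a samples x bins matrix plus the bin key of `like`
bin_table <- function(m, like) {
  out <- dplyr::bind_cols(like[, c("chrom", "start", "end")],
                          tibble::as_tibble(t(m)))
  names(out) <- c("chrom", "start", "end", rownames(m))
  tibble::as_tibble(out)
}

#' On/off-target read statistics
#'
#' A read is on-target iff its leftmost aligned base lies inside a (merged)
#' target interval; everything else is off-target. Off-target depth is
#' `off_target_reads * mean_read_length / off-target span`, with the
#' off-target span being the genome size minus the merged target span.
#'
#' @param samples Named list of alignment sources (BAM paths or tibbles, as
#'   in [bin_read_counts()]).
#' @param targets Target regions: a tibble with `chrom`, `start`, `end`
#'   (0-based half-open, BED semantics) or `NULL` for an untargeted assay
#'   (all reads off-target).
#' @param genome_size Total genome length in bp.
#' @param mean_read_length Mean read length in bp used for the depth
#'   estimate (default 100).
#' @param min_mapq,exclude_duplicates Read filters, as in
#'   [bin_read_counts()].
#' @return A tibble with one row per sample: `sample`, `total_reads`,
#'   `off_target_reads`, `off_target_fraction`, `mean_off_target_depth`.
#' @export
off_target_stats <- function(samples, targets, genome_size,
                             mean_read_length = 100,
                             min_mapq = 20, exclude_duplicates = TRUE) {
  if (is.null(names(samples)) || any(names(samples) == "")) {
    abort("`samples` must be named.")
  }
  merged <- merge_intervals(targets)
  target_span <- if (is.null(merged)) 0 else sum(merged$end - merged$start)
  off_span <- genome_size - target_span
  if (off_span <= 0) abort("targets cover the whole genome; no off-target span.")

  purrr::imap_dfr(samples, function(src, id) {
    aln <- filter_alignments(normalize_alignments(src),
                             min_mapq, exclude_duplicates)
    total <- nrow(aln)
    on_target <- if (is.null(merged) || total == 0) {
      rep(FALSE, total)
    } else {
      in_intervals(merged, aln$chrom, aln$pos - 1)
    }
    off <- total - sum(on_target)
    tibble::tibble(
      sample = id,
      total_reads = total,
      off_target_reads = off,
      off_target_fraction = if (total > 0) off / total else 0,
      mean_off_target_depth = off * mean_read_length / off_span
    )
  })
}

## merge possibly-overlapping intervals per chromosome (IRanges::reduce)
merge_intervals <- function(targets) {
  if (is.null(targets) || nrow(tibble::as_tibble(targets)) == 0) return(NULL)
  targets <- tibble::as_tibble(targets)
  parts <- split(targets, targets$chrom)
  out <- purrr::imap_dfr(parts, function(tt, ch) {
    ir <- IRanges::reduce(IRanges::IRanges(start = tt$start + 1, end = tt$end))
    tibble::tibble(chrom = ch, start = IRanges::start(ir) - 1,
                   end = IRanges::end(ir))
  })
  out[order(out$chrom, out$start), ]
}

## membership of 0-based positions in merged half-open intervals
in_intervals <- function(merged, chrom, pos) {
  res <- rep(FALSE, length(pos))
  for (ch in unique(merged$chrom)) {
    sel <- chrom == ch
    if (!any(sel)) next
    mm <- merged[merged$chrom == ch, ]
    ir <- IRanges::IRanges(start = mm$start + 1, end = mm$end)
    res[sel] <- IRanges::overlapsAny(
      IRanges::IRanges(start = pos[sel] + 1, width = 1), ir)
  }
  res
}

bin_size_ladder <- c(200, 400, 1e3, 2e3, 5e3, 1e4, 2e4, 5e4,
                     1e5, 2e5, 5e5, 1e6, 2e6)

#' Recommend a bin size from off-target yield
#'
#' Picks the smallest bin size from a fixed ladder (200 bp to 2 Mb in
#' 1-2-5 steps) such that the expected number of off-target reads per bin,
#' `off_target_reads * bin_size / genome_size`, reaches
#' `target_reads_per_bin`. With about three million reads per sample and half
#' of them off-target on a 3 Gb genome, this yields the 200 kb bin size that
#' suits small-panel data.
#'
#' @param off_target_reads Mean off-target reads per sample (scalar, or a
#'   vector to be averaged).
#' @param genome_size Genome length in bp.
#' @param target_reads_per_bin Desired expected reads per bin (default 100).
#' @return A bin size in bp (one ladder value). If even the largest ladder
#'   value falls short, it is returned with a warning.
#' @examples
#' recommend_bin_size(1.5e6, 3e9)  # 200000
#' @export
recommend_bin_size <- function(off_target_reads, genome_size,
                               target_reads_per_bin = 100) {
  off <- mean(off_target_reads)
  if (!is.finite(off) || off <= 0) {
    abort("no off-target signal: zero off-target reads.")
  }
  ok <- off * bin_size_ladder / genome_size >= target_reads_per_bin
  if (!any(ok)) {
    warn("even the largest bin size falls short of the target reads per bin.")
    return(bin_size_ladder[length(bin_size_ladder)])
  }
  bin_size_ladder[which(ok)[1]]
}
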