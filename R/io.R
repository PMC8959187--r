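#' Read and write per-bin count tables
#'
#' The on-disk dialect is a tab-separated table with header
#' `chrom start end sample1 sample2 ...`, one bin per row, coordinates
#' 0-based half-open.
#'
#' @param path File path.
#' @return `read_counts_tsv()`: a `bin_counts` tibble.
#' @export
read_counts_tsv <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    chrom = readr::col_character(), .default = readr::col_double()),
    progress = FALSE)
  as_bin_counts(x)
}

#' @rdname read_counts_tsv
#' @param counts A `bin_counts` tibble.
#' @export
write_counts_tsv <- function(counts, path) {
  readr::write_tsv(counts, path, progress = FALSE)
  invisible(path)
}

#' Read a BED3 file of target regions
#'
#' @param path Path to a headerless, tab-separated BED file; only the first
#'   three columns are used (0-based half-open).
#' @return A tibble with columns `chrom`, `start`, `end`.
#' @export
read_bed3 <- function(path) {
  x <- readr::read_tsv(path, col_names = FALSE, progress = FALSE,
                       col_types = readr::cols(X1 = readr::col_character(),
                                               .default = readr::col_double()))
  out <- tibble::tibble(chrom = x[[1]], start = x[[2]], end = x[[3]])
  if (any(out$end <= out$start)) abort("BED intervals must have end > start.")
  out
}

#' Write CNV calls as TSV or VCF
#'
#' The TSV has BED-compatible leading columns
#' (`chrom start end sample type n_bins mean_dosage quality`). The VCF 4.2
#' output uses symbolic alleles `<DEL>`/`<DUP>` with `END` and `SVLEN` INFO
#' fields and a per-sample `CN` genotype field (copy number 1 for a
#' deletion, 3 for a duplication, under the default diploid assumption).
#'
#' @param calls A calls tibble as produced by [call_cnvs()]/[tidy()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_calls_tsv <- function(calls, path) {
  cols <- c("chrom", "start", "end", "sample", "type", "n_bins",
            "mean_dosage", "quality")
  readr::write_tsv(calls[, cols], path, progress = FALSE)
  invisible(path)
}

#' @rdname write_calls_tsv
#' @param chrom_sizes Optional chromosome-sizes tibble for `##contig` lines.
#' @export
write_calls_vcf <- function(calls, path, chrom_sizes = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=offcnv",
    "##ALT=<ID=DEL,Description=\"Deletion\">",
    "##ALT=<ID=DUP,Description=\"Duplication\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position of the variant\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Length of the variant\">",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type of structural variant\">",
    "##INFO=<ID=NBINS,Number=1,Type=Integer,Description=\"Supporting analysis bins\">",
    "##INFO=<ID=DOSAGE,Number=1,Type=Float,Description=\"Mean relative dosage\">",
    "##FORMAT=<ID=CN,Number=1,Type=Integer,Description=\"Copy number\">"
  ), con)
  if (!is.null(chrom_sizes)) {
    writeLines(sprintf("##contig=<ID=%s,length=%d>",
                       chrom_sizes$chrom, as.integer(chrom_sizes$length)), con)
  }
  samples <- sort(unique(calls$sample))
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", samples), collapse = "\t"), con)
  if (nrow(calls) > 0) {
    ord <- order(calls$chrom, calls$start)
    calls <- calls[ord, ]
    for (i in seq_len(nrow(calls))) {
      cl <- calls[i, ]
      sv <- as.character(cl$type)
      svlen <- as.integer(cl$end - cl$start) * ifelse(sv == "DEL", -1L, 1L)
      info <- sprintf("END=%d;SVLEN=%d;SVTYPE=%s;NBINS=%d;DOSAGE=%.4f",
                      as.integer(cl$end), svlen, sv, as.integer(cl$n_bins),
                      cl$mean_dosage)
      cn <- if (sv == "DEL") "1" else "3"
      gt <- ifelse(samples == cl$sample, cn, ".")
      writeLines(paste(c(cl$chrom, as.integer(cl$start) + 1L, ".", "N",
                         paste0("<", sv, ">"), sprintf("%.2f", cl$quality),
                         "PASS", info, "CN", gt), collapse = "\t"), con)
    }
  }
  invisible(path)
}

#' Write the off-target coverage report
#'
#' One row per sample with total and off-target read counts, off-target
#' fraction and depth, and the cohort-level recommended bin size.
#'
#' @param stats Output of [off_target_stats()].
#' @param path Output path.
#' @param genome_size Genome length in bp (for the recommendation).
#' @param target_reads_per_bin Passed to [recommend_bin_size()].
#' @return The path, invisibly.
#' @export
write_off_target_report <- function(stats, path, genome_size,
                                    target_reads_per_bin = 100) {
  stats$recommended_bin_size <- recommend_bin_size(
    stats$off_target_reads, genome_size, target_reads_per_bin)
  readr::write_tsv(stats, path, progress = FALSE)
  invisible(path)
}
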