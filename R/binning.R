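#' Tile a genome into fixed-width bins
#'
#' Splits each chromosome into adjacent, non-overlapping windows of
#' `bin_size` base pairs. The final window of a chromosome is retained even
#' when shorter than `bin_size` (it is flagged `partial`). Bins never span
#' chromosome boundaries. All coordinates are 0-based half-open.
#'
#' The binning is the coordinate frame for everything downstream: read
#' counting, dosage normalisation and CNV segmentation all operate per bin.
#'
#' @param chrom_sizes A data frame with columns `chrom` and `length` (bp), or
#'   a named numeric vector of chromosome lengths. Chromosome order is kept.
#' @param bin_size Bin width in base pairs (positive integer).
#'
#' @return A tibble of class `genome_binning` with columns `chrom`, `start`,
#'   `end`, `bin` (1-based index over the whole genome) and `partial`
#'   (`TRUE` for a short terminal bin). Attributes `bin_size` and
#'   `chrom_sizes` record the frame.
#'
#' @examples
#' make_binning(c(chr1 = 1e6), bin_size = 2e5)
#' @export
make_binning <- function(chrom_sizes, bin_size) {
  if (is.numeric(chrom_sizes) && !is.null(names(chrom_sizes))) {
    chrom_sizes <- tibble::tibble(chrom = names(chrom_sizes),
                                  length = unname(chrom_sizes))
  }
  chrom_sizes <- tibble::as_tibble(chrom_sizes)
  if (!all(c("chrom", "length") %in% names(chrom_sizes))) {
    abort("`chrom_sizes` needs columns `chrom` and `length`.")
  }
  if (anyDuplicated(chrom_sizes$chrom)) {
    abort("duplicate chromosome names in `chrom_sizes`.")
  }
  if (!is.numeric(bin_size) || length(bin_size) != 1 || bin_size <= 0) {
    abort("`bin_size` must be a single positive number.")
  }
  if (any(chrom_sizes$length <= 0)) {
    abort("chromosome lengths must be positive.")
  }
  bin_size <- as.integer(round(bin_size))

  bins <- purrr::map2_dfr(chrom_sizes$chrom, chrom_sizes$length, function(ch, len) {
    starts <- seq(0, len - 1, by = bin_size)
    tibble::tibble(chrom = ch, start = starts,
                   end = pmin(starts + bin_size, len))
  })
  bins$bin <- seq_len(nrow(bins))
  bins$partial <- (bins$end - bins$start) < bin_size
  structure(bins,
            bin_size = bin_size,
            chrom_sizes = chrom_sizes,
            class = c("genome_binning", class(bins)))
}

#' @export
print.genome_binning <- function(x, ...) {
  cat(sprintf("<genome_binning> %d bins of %s bp over %d chromosome(s)\n",
              nrow(x), format(attr(x, "bin_size"), big.mark = ","),
              nrow(attr(x, "chrom_sizes"))))
  NextMethod()
}

#' Read a chromosome-sizes table
#'
#' Two-column, headerless, tab-separated: chromosome name and length in bp
#' (the `samtools faidx` / UCSC chrom.sizes convention).
#'
#' @param path Path to the file.
#' @return A tibble with columns `chrom` and `length`.
#' @export
read_chrom_sizes <- function(path) {
  readr::read_tsv(path, col_names = c("chrom", "length"),
                  col_types = readr::cols(chrom = readr::col_character(),
                                          length = readr::col_double()),
                  progress = FALSE)
}

#' Parse and format genomic region strings
#'
#' `parse_region()` understands strings like `"chr8:6,800,000-11,800,000"`
#' (en dash accepted). By default the printed coordinates are interpreted as
#' 0-based half-open boundaries, so the width is `end - start`; with
#' `coords = "inclusive"` they are 1-based inclusive and converted.
#' `format_region()` renders a half-open region 1-based inclusive for display.
#'
#' @param x A character vector of region strings.
#' @param coords `"halfopen"` (default) or `"inclusive"`.
#' @return `parse_region()`: a tibble with columns `chrom`, `start`, `end`
#'   and `width` (0-based half-open). `format_region()`: a character vector.
#' @examples
#' parse_region("chr8:6,800,000-11,800,000")$width  # 5 Mb
#' @export
parse_region <- function(x, coords = c("halfopen", "inclusive")) {
  coords <- match.arg(coords)
  x2 <- gsub(",", "", x)
  x2 <- gsub("–", "-", x2)  # en dash
  m <- regmatches(x2, regexec("^([^:]+):([0-9]+)-([0-9]+)$", x2))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad)) abort(paste0("cannot parse region string: ", x[bad][1]))
  chrom <- vapply(m, `[[`, "", 2L)
  start <- as.numeric(vapply(m, `[[`, "", 3L))
  end <- as.numeric(vapply(m, `[[`, "", 4L))
  if (coords == "inclusive") start <- start - 1
  if (any(end <= start)) abort("region end must exceed region start.")
  tibble::tibble(chrom = chrom, start = start, end = end, width = end - start)
}

#' @rdname parse_region
#' @param chrom,start,end Region coordinates (0-based half-open).
#' @export
format_region <- function(chrom, start, end) {
  sprintf("%s:%s-%s", chrom,
          format(start + 1, big.mark = ",", scientific = FALSE, trim = TRUE),
          format(end, big.mark = ",", scientific = FALSE, trim = TRUE))
}

## bin index for a set of positions on one chromosome frame; positions past
## the chromosome end return NA
bin_index_for <- function(binning, chrom, pos) {
  bin_size <- attr(binning, "bin_size")
  cs <- attr(binning, "chrom_sizes")
  first <- vapply(split(binning$bin, binning$chrom), min, 1L)[chrom]
  len <- setNames(cs$length, cs$chrom)[chrom]
  idx <- first + floor(pos / bin_size)
  idx[is.na(len) | pos < 0 | pos >= len] <- NA_integer_
  as.integer(idx)
}
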