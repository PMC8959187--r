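## Shared fixtures and independent oracles, built in code at test time.

## constant-count cohort on a single chromosome
const_counts <- function(n_samples, n_bins, value = 100, bin_size = 1000,
                         chrom = "chr1") {
  binning <- make_binning(setNames(n_bins * bin_size, chrom), bin_size)
  m <- matrix(value, n_bins, n_samples,
              dimnames = list(NULL, sprintf("S%02d", seq_len(n_samples))))
  dplyr::bind_cols(
    tibble::tibble(chrom = binning$chrom, start = binning$start,
                   end = binning$end),
    tibble::as_tibble(m))
}

## exhaustive Viterbi oracle: enumerate all 3^n state paths and score them
## under the same model (initial (t, 1-2t, t), stay 1-2t, switch t);
## ties resolved toward NORM then DEL at every divergence, matching the
## documented tie-break, by scanning candidates in preference-major order.
viterbi_brute <- function(log_emission, trans_prob) {
  n <- nrow(log_emission)
  log_t <- log(trans_prob)
  log_stay <- log1p(-2 * trans_prob)
  init <- c(log_t, log_stay, log_t)
  pref <- c(2L, 1L, 3L)
  paths <- as.matrix(expand.grid(rep(list(pref), n))[, n:1, drop = FALSE])
  score <- apply(paths, 1, function(p) {
    s <- init[p[1]] + log_emission[1, p[1]]
    if (n > 1) {
      for (i in 2:n) {
        s <- s + (if (p[i] == p[i - 1]) log_stay else log_t) +
          log_emission[i, p[i]]
      }
    }
    s
  })
  best <- which(score >= max(score) - 1e-12)
  ## among tied paths, pick the one ranked first in preference order,
  ## comparing states left to right
  rank_key <- apply(paths[best, , drop = FALSE], 1, function(p)
    paste(match(p, pref), collapse = ""))
  unname(paths[best[order(rank_key)][1], ])
}

## pipeline variant with the error model replaced by the bare Poisson floor
## (ablation comparator only; not part of the package surface)
call_poisson_only <- function(counts, trans_prob = 1e-5) {
  active <- select_active_bins(counts)
  dosage <- svd_denoise(normalize_dosage(counts, active = active))
  sig <- estimate_errors(dosage)
  fl <- attr(sig, "floor")
  sm <- sample_names(dosage)
  d <- t(as.matrix(dosage[, sm]))
  rownames(d) <- sm
  em <- cnv_log_emissions(d, fl)
  chroms <- dosage$chrom
  key <- dosage[, c("chrom", "start", "end")]
  purrr::map_dfr(sm, function(id) {
    purrr::map_dfr(unique(chroms), function(ch) {
      j <- which(chroms == ch)
      le <- cbind(em$log_del[id, j], em$log_norm[id, j], em$log_dup[id, j])
      path <- viterbi_path(le, trans_prob)
      lr <- le[cbind(seq_along(j), path)] - le[, 2]
      segment_calls(path, key[j, ], d[id, j], lr, id)
    })
  })
}

## write a small SAM file and return a BAM path (needs Rsamtools + samtools
## headers only through Rsamtools::asBam)
toy_bam <- function(records, chrom_sizes, dir) {
  sam <- file.path(dir, "toy.sam")
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_sizes),
                   as.integer(chrom_sizes)))
  body <- vapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    paste(sprintf("r%03d", i), r$flag, r$chrom, r$pos, r$mapq, "10M",
          "*", 0, 0, "AAAAAAAAAA", "IIIIIIIIII", sep = "\t")
  }, "")
  writeLines(c(hdr, body[order(records$chrom, records$pos)]), sam)
  Rsamtools::asBam(sam, file.path(dir, "toy"), overwrite = TRUE,
                   indexDestination = TRUE)
}
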