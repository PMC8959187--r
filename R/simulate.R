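## Cohort simulator: binned Poisson counts with the statistical structure of
## off-target capture data — library-size variation, low-rank multiplicative
## biases shared across samples, a small fraction of hypervariable bins, and
## planted deletions/duplications with known truth.

default_layout <- function() {
  tibble::tibble(chrom = paste0("chr", 1:4), length = 6e7)
}

#' Configuration for a simulated sequencing cohort
#'
#' Defaults emulate an off-target small-panel cohort: 200 kb bins at a mean
#' of 100 reads per bin (the regime where a 0.065x off-target depth lands),
#' lognormal library-size variation, a rank-3 multiplicative bias shared
#' across samples (batch/chemistry structure, what SVD denoising removes),
#' and 2 percent hypervariable bins whose dosage noise is about five times
#' the Poisson floor (tandem-repeat-like loci, what the multiplicative
#' error model guards against).
#'
#' @param n_samples Cohort size (default 100).
#' @param layout Chromosome layout tibble (`chrom`, `length`); default four
#'   60 Mb chromosomes.
#' @param bin_size Bin width in bp (default 2e5).
#' @param mean_reads_per_bin Mean expected reads per bin (default 100).
#' @param sample_scale_sd sdlog of the lognormal per-sample library-size
#'   factor (default 0.2).
#' @param bias_rank Number of latent multiplicative bias factors shared
#'   across samples (default 3; 0 disables).
#' @param bias_sd Scale of the bias factors: each factor contributes
#'   `N(0,1)` per sample times `N(0, bias_sd)` per bin on the log scale
#'   (default 0.05).
#' @param hypervariable_fraction Fraction of bins with inflated noise
#'   (default 0.02; 0 disables).
#' @param hypervariable_inflation Noise inflation factor for those bins:
#'   per-cell lognormal noise with
#'   `sdlog = inflation / sqrt(mean_reads_per_bin)`, i.e. dosage noise about
#'   `inflation` times the Poisson floor (default 5).
#' @param cnvs Planted CNV truth: tibble with columns `sample`, `chrom`,
#'   `start`, `end`, `type` (`"DEL"`/`"DUP"`), `dosage` (0.5 and 1.5 for
#'   heterozygous events; intermediate values simulate mosaics). `NULL` for
#'   none.
#' @return A `sim_config` list.
#' @export
simulation_config <- function(n_samples = 100,
                              layout = default_layout(),
                              bin_size = 2e5,
                              mean_reads_per_bin = 100,
                              sample_scale_sd = 0.2,
                              bias_rank = 3,
                              bias_sd = 0.05,
                              hypervariable_fraction = 0.02,
                              hypervariable_inflation = 5,
                              cnvs = NULL) {
  cfg <- list(n_samples = n_samples, layout = tibble::as_tibble(layout),
              bin_size = bin_size, mean_reads_per_bin = mean_reads_per_bin,
              sample_scale_sd = sample_scale_sd, bias_rank = bias_rank,
              bias_sd = bias_sd,
              hypervariable_fraction = hypervariable_fraction,
              hypervariable_inflation = hypervariable_inflation,
              cnvs = cnvs)
  structure(cfg, class = "sim_config")
}

#' Plant a random set of heterozygous CNVs
#'
#' Draws bin-aligned deletions and duplications of `size_range_bins` bins,
#' each in a distinct sample (sampled without replacement), uniformly over
#' the genome, at relative dosage 0.5 (DEL) or 1.5 (DUP).
#'
#' @param config A [simulation_config()].
#' @param n_del,n_dup Number of deletions / duplications (defaults 20/20).
#' @param size_range_bins Inclusive range of event sizes in bins
#'   (default 6 to 25 bins; at 200 kb bins, 1.2 to 5 Mb).
#' @return A truth tibble suitable for `config$cnvs`.
#' @export
plant_cnvs <- function(config, n_del = 20, n_dup = 20,
                       size_range_bins = c(6, 25)) {
  n <- n_del + n_dup
  if (n > config$n_samples) {
    abort("more planted CNVs than samples (one event per sample).")
  }
  layout <- config$layout
  samples <- sample(sprintf("S%03d", seq_len(config$n_samples)), n)
  sizes <- sample(seq(size_range_bins[1], size_range_bins[2]), n,
                  replace = TRUE)
  chrom_i <- sample(nrow(layout), n, replace = TRUE,
                    prob = layout$length / sum(layout$length))
  span <- sizes * config$bin_size
  max_start_bin <- floor(layout$length[chrom_i] / config$bin_size) - sizes
  if (any(max_start_bin < 0)) abort("planted CNV larger than its chromosome.")
  start <- vapply(max_start_bin, function(m) sample(0:m, 1), 1) * config$bin_size
  tibble::tibble(
    sample = samples,
    chrom = layout$chrom[chrom_i],
    start = start,
    end = start + span,
    type = rep(c("DEL", "DUP"), c(n_del, n_dup)),
    dosage = rep(c(0.5, 1.5), c(n_del, n_dup))
  )
}

#' Simulate a binned-coverage cohort with known truth
#'
#' Expected counts are
#' `lambda[s,b] = mean_reads_per_bin * scale[s] * exp(sum_k u_k[s] v_k[b])
#' * dosage[s,b] * noise[s,b]`, with `dosage` the planted relative dosage
#' (1 outside events), and `noise` a per-cell lognormal inflation applied
#' only in hypervariable bins. Observed counts are Poisson(lambda).
#' Reproducible: the same `seed` yields identical output.
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed for all randomness.
#' @return A list with `counts` (a `bin_counts` tibble), `truth` (the
#'   planted-CNV tibble, zero rows if none), `binning`, and
#'   `hypervariable` (logical per bin).
#' @export
simulate_cohort <- function(config, seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  binning <- make_binning(config$layout, config$bin_size)
  nb <- nrow(binning)
  ns <- config$n_samples
  sample_ids <- sprintf("S%03d", seq_len(ns))

  truth <- config$cnvs
  if (!is.null(truth)) {
    truth <- tibble::as_tibble(truth)
    len <- setNames(config$layout$length, config$layout$chrom)
    bad <- !(truth$chrom %in% names(len)) | truth$start < 0 |
      truth$end > len[truth$chrom]
    if (any(bad)) abort("planted CNV outside the chromosome layout.")
  } else {
    truth <- tibble::tibble(sample = character(), chrom = character(),
                            start = numeric(), end = numeric(),
                            type = character(), dosage = numeric())
  }

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)

  scale <- exp(rnorm(ns, 0, config$sample_scale_sd))
  log_bias <- matrix(0, ns, nb)
  if (config$bias_rank > 0) {
    u <- matrix(rnorm(ns * config$bias_rank), ns)
    v <- matrix(rnorm(nb * config$bias_rank, 0, config$bias_sd), nb)
    log_bias <- u %*% t(v)
  }
  hyper <- runif(nb) < config$hypervariable_fraction
  noise <- matrix(1, ns, nb)
  if (any(hyper)) {
    sdlog <- config$hypervariable_inflation / sqrt(config$mean_reads_per_bin)
    noise[, hyper] <- exp(rnorm(ns * sum(hyper), 0, sdlog))
  }

  dosage <- matrix(1, ns, nb, dimnames = list(sample_ids, NULL))
  if (nrow(truth) > 0) {
    for (i in seq_len(nrow(truth))) {
      sel <- binning$chrom == truth$chrom[i] &
        binning$end > truth$start[i] & binning$start < truth$end[i]
      dosage[truth$sample[i], sel] <- truth$dosage[i]
    }
  }

  width_frac <- (binning$end - binning$start) / config$bin_size
  lambda <- config$mean_reads_per_bin * scale * exp(log_bias) * dosage * noise
  lambda <- sweep(lambda, 2, width_frac, "*")
  counts <- matrix(rpois(ns * nb, lambda), ns, nb,
                   dimnames = list(sample_ids, NULL))

  list(counts = as_bin_counts(bin_table(counts, binning)),
       truth = truth,
       binning = binning,
       hypervariable = hyper)
}
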