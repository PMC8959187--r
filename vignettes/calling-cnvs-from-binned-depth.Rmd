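---
title: "Calling CNVs from binned read depth: model, parameters and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling CNVs from binned read depth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(offcnv)
```

## The signal and the model

A capture-based sequencing assay scatters a large fraction of its reads
outside the targeted regions. Pooled into fixed-width genomic bins, those
off-target reads behave to a good approximation like independent Poisson
counts whose expectation is proportional to the local copy number, the
sample's library size, and a locus-specific capture/mappability factor. A
heterozygous deletion halves the expectation over its span; a heterozygous
duplication multiplies it by 1.5. Everything in this package follows from
that multiplicative model.

The pipeline in `call_cnvs()`:

1. **Active bins.** A bin is analysable only if its mean raw count across
   the cohort reaches `min_mean_count` (default 1 read). Bins below that —
   centromeres, assembly gaps, unmappable sequence — carry no usable dosage
   and are dropped; a call may span them but gets no evidence from them.
2. **Relative dosage.** Each sample's counts are divided by the sample's
   mean over active bins (library size), then each bin's column by its
   cross-sample mean (locus factor). The result `d` has bin-wise mean
   exactly 1; 0.5 and 1.5 are the heterozygous deletion and duplication
   levels. Both steps are ratios, so dosage is invariant to rescaling any
   sample's counts.
3. **Denoising.** Batch and chemistry effects correlate across samples and
   across many bins, so they concentrate in the leading singular vectors of
   the log-dosage matrix. `svd_denoise()` subtracts the rank-`n_discard`
   reconstruction (default 5 vectors) and exponentiates the residual. A
   genuine CNV is private to one sample and a short span, so it
   contributes little to the leading vectors — with caveats discussed
   under *Limitations*.
4. **Error model.** `estimate_errors()` assigns each cell
   `sigma = max(sd_bin * sd_sample / mean_sd, 1/sqrt(N))`, where `sd_bin`
   is the dosage sd of the bin across samples, `sd_sample` that of the
   sample across bins, and `mean_sd` the cohort mean of the sample sds —
   so a sample of average noisiness inherits each bin's own sd. The floor
   `1/sqrt(N)` is the relative sd of a Poisson count with expectation `N`
   (the sample's mean count times the bin's relative depth, from the raw
   counts): no amount of modelling can know a dosage more precisely than
   counting noise allows. Standard deviations are taken on the linear
   dosage scale, where the 0.5/1.5 targets live.
5. **Emissions and decoding.** Each bin emits three tail probabilities:
   `P(d <= 0.5)` for deletion, `P(d >= 1.5)` for duplication, and
   `P(d <= 1)` or `P(d >= 1)` for normal dosage, each a normal tail with
   the cell's `sigma`. These are unnormalised weights for a three-state
   hidden Markov model with stay probability `1 - 2t` and switch
   probability `t`, decoded by Viterbi per sample per chromosome (calls
   never span chromosomes). Maximal non-normal runs become calls;
   `quality = (10/ln 10) * sum(ln p_state - ln p_norm)` over the run's
   active bins, floored at 0 — a phred-scaled likelihood ratio that grows
   with per-bin evidence and with run length, and is the natural quantity
   to threshold when trading precision against recall.

The default (non-mosaic) emissions have a useful geometric consequence: as
`sigma` shrinks, the deletion tail exceeds the normal tail exactly when
`d < 0.75`, and the duplication tail when `d > 1.25`. A bin must cross the
midpoint between normal and the full heterozygous level before it counts
as evidence — intermediate dosages, which in practice are overwhelmingly
noise rather than mosaic events, are rejected. `mosaic = TRUE` replaces
the CNV tails with `P(d <= 1)`/`P(d >= 1)`, admitting any significant
deviation from 1 at a substantial false-positive cost.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `bin_size` | data-dependent | bp | window width; `recommend_bin_size()` picks the smallest 1–2–5 ladder value giving ≥ `target_reads_per_bin` (100) expected off-target reads per bin. ~1.5 M off-target reads on 3 Gb → 200 kb. Smaller bins resolve smaller CNVs but raise noise per bin. |
| `min_mean_count` | 1 | reads | active-bin threshold (boundary inclusive) |
| `n_discard` | 5 | singular vectors | shared-bias removal; 0 disables |
| `dosage_floor` | 0.01 | dosage | floor before the log in the SVD step, keeps zero-count cells finite while preserving a strong deletion signal |
| `trans_prob` | 1e-5 | probability | HMM switch probability; the geometric midpoint of the 1e-10–0.1 range that is worth sweeping. Smaller values demand more evidence per call (higher precision, lower recall). |
| `mosaic` | `FALSE` | — | emission mode, see above |
| `min_quality` | 0 | phred | post-hoc call filter; thresholding is exactly equivalent to filtering the unthresholded call set |
| `min_mapq` | 20 | MAPQ | read filter in counting; duplicates excluded by default |

Read counting assigns each passing read to the single bin containing its
leftmost aligned base — unambiguous, and a read spanning a boundary is
never double-counted. Reads are counted, not fragments; with paired ends
this doubles the nominal count and correspondingly tightens the Poisson
floor by √2, which is conservative in the right direction only if mates
are mostly in the same bin (true at 200 kb bins). MAPQ ≥ 20 with
duplicates excluded is ordinary depth-caller hygiene; both are
configurable.

## Numerical choices

* **Log-space emissions.** Tail probabilities at small `sigma` underflow
  double precision (`P(d <= 0.5)` at `d = 0.9`, `sigma = 0.001` is
  ~10^-34000). All HMM arithmetic therefore uses `cnv_log_emissions()`,
  which evaluates log tails directly (`pnorm(log.p = TRUE)`); this keeps
  the midpoint gate exact arbitrarily far into the tails. The
  probability-scale view `cnv_emissions()` clamps to `[1e-300, 1-1e-16]`
  and is for inspection, not decoding.
* **Tie-breaking.** Viterbi ties resolve toward normal, then deletion —
  conservative calling on degenerate inputs.
* **Degenerate inputs.** Fewer than 2 samples cannot be normalised, fewer
  than 3 cannot support the error model (cross-sample sds need a cohort);
  both error early with the reason. A sample with zero reads over active
  bins is named in its error. `n_discard` must be below
  `min(samples, active bins)`. An all-inactive binning errors rather than
  returning an empty dosage.
* **No re-normalisation after SVD.** The residual is used as returned;
  its bin means drift from 1 by a negligible amount at the discard depths
  used, and re-centring would partially undo the denoising.
* **No calibration rescaling.** Grouping simulated cells into 100 sets by
  estimated `sigma`, the within-group empirical sd of dosage tracks the
  estimate within ±20% across the whole range (slightly conservative),
  so no post-hoc rescaling of `sigma` is applied.
* **Determinism.** Calling has no stochastic step; identical inputs and
  parameters give byte-identical outputs. All simulator randomness flows
  through one integer seed.
* **Region strings.** Internally and in BED/TSV output, coordinates are
  0-based half-open. `format_region()` renders 1-based inclusive for
  humans; `parse_region()` accepts printed boundary-style coordinates
  (half-open, so `chr8:6,800,000-11,800,000` is exactly 5 Mb) and
  1-based inclusive via `coords = "inclusive"`.

## The simulator: scope and honesty

`simulate_cohort()` draws Poisson counts around
`mean_reads_per_bin × library factor × exp(rank-k bias) × planted dosage`,
with three noise structures layered on the counting noise:

* a lognormal per-sample library-size factor (`sample_scale_sd = 0.2`);
* a rank-3 multiplicative bias shared across samples (`bias_sd = 0.05`
  per factor on the log scale) — the batch/chemistry structure the SVD
  step exists to remove;
* 2% hypervariable bins with per-cell lognormal noise at about five times
  the Poisson floor — the tandem-repeat-like loci the multiplicative
  error model exists to down-weight. (A deterministic per-bin factor
  cannot create cross-sample variance — it would be normalised away — so
  the inflation is necessarily per-cell.)

Defaults emulate a small-panel off-target cohort: 200 kb bins at ~100
reads per bin, i.e. the ~0.065× off-target depth regime. What the
simulator does **not** emulate: GC-content waves, mappability gradients
along the genome, correlated noise between adjacent bins, paired-end
structure, breakpoints inside bins (planted events are bin-aligned unless
you plant them otherwise), sex chromosomes, and real truth-set
uncertainty. Passing tests therefore demonstrate that the algorithm does
what its model promises under its own assumptions — they do not prove
field performance on real capture data, where the unmodelled structure is
exactly what the SVD and error-model steps must absorb.

The ablation tests make the design's claims falsifiable: with a strong
injected rank-3 bias (bias sd 0.3, large enough to push dosages past the
midpoints) the sweep's best f statistic collapses without SVD; with
hypervariable bins the Poisson-only error model floods the output with
false positives that the multiplicative model suppresses at equal recall;
a planted dosage-0.8 event is found only in mosaic mode; and the best f
rises with cohort size from 7 to 50 samples.

## Limitations

* **Isolated strong events can be partially absorbed by the SVD.** A
  single large CNV is itself low-rank structure (one sample × one span).
  When its singular value competes with the noise spectrum — small
  cohorts, small genomes/bin counts, or very large events — the discarded
  vectors capture part of it, shrinking its apparent dosage toward 1 and,
  in the extreme, deleting the evidence entirely. This is the mechanism
  behind the cohort-size power curve: batches of ~7 samples have little
  power, and full power needs on the order of 50+ samples. It also means
  a called event's `mean_dosage` (post-denoising) is biased toward 1;
  for an unbiased dosage estimate, read the normalised pre-denoising
  dosage over the call span. Whole-chromosome events (aneuploidies) are
  the worst case for absorption.
* **Boundary resolution is the bin size.** Calls are bin-aligned; with
  bin-aligned simulated truth, the mean absolute boundary error stays
  below half a bin, and with real (unaligned) breakpoints it scales
  proportionally with the bin size.
* **Three states only.** Copy numbers 1, 2, 3 — homozygous deletions and
  higher amplifications are called as (strong) DEL/DUP but their copy
  number is not estimated.
* **Sex chromosomes.** X is normalised against the cohort mean like any
  autosome; in a mixed-sex cohort male X sits near dosage ~0.5·(cohort
  mean) and will generate calls unless cohorts are sex-stratified or X is
  interpreted with care.
* **No GC correction.** Shared GC waves are low-rank across samples and
  largely removed by the SVD; sample-private GC effects are not.

## Problem sizes in the test suite

The suite exercises the full pipeline at sizes chosen to make every
property sharply visible while keeping a complete run around half a
minute: cohorts of 7–100 samples over 250–4000 bins, with the headline
simulation at the full study conditions (100 samples × 1200 bins, 40
planted events > 1 Mb). The Viterbi implementation is checked against an
exhaustive path enumeration on sequences up to 8 bins; the error-model
calibration uses 240,000 simulated cells in 100 sigma groups.
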