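# admixscan

Population-genomic dissection of recently admixed populations from phased
SNP data, in R. The package targets the standard analysis arc for a hybrid
population such as an indicine × taurine composite cattle breed: establish
cohort quality (kinship, runs of homozygosity, LD decay), paint local
ancestry against labelled reference panels, test for ancestry-excess
segments, date the admixture pulse from weighted LD decay, and scan for
selection with several complementary statistics that are intersected at
their empirical tails. A built-in simulator generates admixed cohorts with
known truth so that every stage is testable without any external data.

## What it computes

* **Local-ancestry painting** — dynamic-programming haplotype copying
  against reference panels: per-site cost 1 per allele mismatch plus a
  switch penalty λ per template change; the ancestry call is the panel
  label of the copied template, majority-voted over a λ grid
  {1, 1.5, 2, 3, 5}. Genome-wide proportions are tract-length weighted.
* **Ancestry-excess segments** — the cohort painting is cut wherever any
  haplotype's call changes; for each segment and ancestry with haplotype
  frequency *f* against genome-wide proportion *p*, a one-sided Z test
  `Z = (f − p) / sqrt(p(1 − p) / 2N)`; retained segments need f ≥ 0.75,
  length ≥ 1,000 bp and P < 0.01.
* **Admixture dating** — weighted LD: for site pairs at genetic distance
  *d*, the covariance of target genotypes weighted by the product of the
  source panels' allele-frequency contrasts decays as
  `A·exp(−n·d) + c` after a single pulse *n* generations ago. Nonlinear
  least-squares fit (bins ≥ 0.5 cM), uncertainty by
  leave-one-chromosome-out jackknife; a tract-length estimator
  `g = 1 / ((1 − m) · mean tract length in Morgans)` cross-checks it.
* **Selection scans** — windowed nucleotide diversity π (50 kb / 20 kb),
  its log-ratio between populations, Weir–Cockerham FST (ratio of sums),
  Tajima's D (2-kb windows), standardized iHS from integrated EHH, and a
  SweepFinder-style composite likelihood ratio against the genome-wide
  frequency spectrum (50-kb windows). Windows ranking in the top 1% of at
  least two scans become candidate regions.
* **Cohort diagnostics** — KING-robust kinship with degree classes,
  PLINK-rule runs of homozygosity (window-snp 100, window-het 1,
  threshold 0.05, min 100 kb, density 200 kb/SNP), LD half-decay distance.
* **Simulator** — K source populations under the Balding–Nichols model at
  tunable FST, single-pulse admixture g generations ago with mixing
  proportions m, Poisson(g per Morgan) tract breakpoints, copy-with-error
  haplotypes, and planted sweeps / ancestry-excess intervals / autozygous
  segments as detector positive controls.

## Worked example

```r
library(admixscan)

cfg <- sim_config(K = 2, F = 0.2, n_ref = 20, n_adm = 15,
                  L_bp = 20e6, n_sites = 4000, m = c(0.6, 0.4),
                  g = 30, eps = 0.001, seed = 7)
panels <- make_panels(cfg)
truth  <- simulate_cohort(cfg, panels)
truth
#> truth_set: 15 diploids, 4000 sites x 1 chr, K=2, g=30, realized m = 0.598/0.402

painting <- paint_cohort(truth$target, panels)
round(global_proportions(painting), 3)
#>  anc1  anc2
#> 0.598 0.402
```

The painted proportions match the realized tract-weighted truth of the
simulated cohort (0.598/0.402) to three decimals. Dating a pulse
simulated at g = 38.27 across ten 50-Mb chromosomes recovers it:

```r
cfg10 <- sim_config(K = 2, F = 0.2, n_ref = 30, n_adm = 30, L_bp = 50e6,
                    n_sites = 8000, n_chr = 10, m = c(0.6, 0.4),
                    g = 38.27, eps = 0.001, seed = 1001)
p10    <- make_panels(cfg10)
t10    <- simulate_cohort(cfg10, p10)
curve  <- weighted_ld_curve(t10$target, p10$haps[[1]], p10$haps[[2]])
fit_decay(curve)[c("n_hat", "se")]
#> $n_hat  39.57
#> $se      2.25
```

The truth (38.27) sits inside the jackknife 95% interval
`n_hat ± 1.96·se`.

An end-to-end demonstration (`run_demo(default_config(seed = 1))`) writes
every stage artifact — filtered VCF, window statistics, tracts BED,
excess-segment table, decay-curve fit, scan TSVs, candidate-region BED and
a `summary.json` — and is byte-reproducible for a fixed seed. A thin
command-line wrapper lives at `inst/cli/admixscan.R`
(`demo`, `simulate`, `run-all` subcommands).

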