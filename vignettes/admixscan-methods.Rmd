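---
title: "Models and methods behind admixscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind admixscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

admixscan analyses recently admixed populations — the motivating setting
is a composite cattle breed formed from indicine and taurine source
lineages a few dozen generations ago — from phased biallelic SNP data plus
ancestry-labelled reference panels. This vignette records the models, the
parameter choices and their rationale, the numerical decisions, and what
the bundled simulation-based tests do and do not establish.

## The single-pulse admixture model

All dating and simulation machinery assumes one admixture pulse: K source
populations mixed `g` generations ago in proportions `m`, with random
mating and no further gene flow afterwards. Under this model the ancestry
of a haplotype along the genome is a Markov jump process: recombination
has had `g` meioses to break ancestry blocks, so tract breakpoints form a
Poisson process of rate `g` per Morgan, and the maximal tract of ancestry
`a` has exponential length with mean `1 / ((1 − m_a) g)` Morgans. Two
estimators exploit this:

* **Weighted LD decay.** For sites x, y at genetic distance d, the
  covariance across admixed individuals of their genotypes, weighted by
  the product of source-panel allele-frequency contrasts
  `(p_A − p_B)(x) · (p_A − p_B)(y)`, has expectation proportional to
  `exp(−g d)`. We aggregate pairs into distance bins (0.05 cM wide, up to
  10 cM) as a weighted regression amplitude `Σ cov·w / Σ w²`, and fit
  `A·exp(−n d) + c` by nonlinear least squares. The affine term `c`
  absorbs long-range background covariance. Bins below 0.5 cM are
  excluded from the fit: at short range, background LD inside the source
  populations dominates the admixture signal. Uncertainty comes from a
  leave-one-chromosome-out jackknife, re-aggregating the per-chromosome
  bin sums and refitting per deletion. Panel allele frequencies enter the
  weights from the panels only, never from the target, so weak panel
  drift biases the amplitude, not the rate. Swapping the two panels
  flips the sign of every weight and leaves the product unchanged.
* **Tract lengths.** Painted (or true) maximal ancestry tracts give
  `g = 1 / ((1 − m_a) · mean length in Morgans)`, excluding
  chromosome-end-censored tracts. This is a consistency cross-check, not
  the primary estimator: painting smooths short tracts, which biases the
  mean upward at small `g·L`.

Genotype (not haplotype) covariance is used for the decay curve so that
unphased targets are supported; phase adds nothing to the expectation.
Pair enumeration is quadratic in sites, so the curve thins each
chromosome to at most `max_sites` (default 2,000) evenly spaced sites —
the decay rate is identified by distance coverage, not site density.

## Local-ancestry painting

Each target haplotype is modelled as a mosaic copy of the reference
haplotypes: a dynamic program over states = all panel haplotypes charges
1 per allele mismatch and λ per template switch, and the Viterbi-style
traceback yields the copied template per site; its panel label is the
ancestry call. Because a single λ trades off switch frequency against
copy fidelity, calls are majority-voted over λ ∈ {1, 1.5, 2, 3, 5}
(ties resolved by the smallest λ), echoing the bagging used by
reference-copying painters. Ties in the DP prefer staying on the current
template, then the lowest template index, making the traceback
deterministic. The DP is exact — tested against exhaustive path
enumeration — and adding reference haplotypes can only lower the optimal
cost. Phase errors are not modelled: input is assumed correctly phased
(simulator phase is exact).

## Segmentation and the ancestry-excess test

The cohort painting is segmented at every position where any haplotype's
call changes, so each segment carries one constant ancestry-count vector.
Segment bounds run from the segment's first site to the next segment's
first site (0-based half-open), extended to the chromosome ends, so
segments tile the genome exactly. Per-haplotype tracts instead use
midpoints between flanking sites, which is the better estimate of the
true breakpoint for length-based dating. For a segment where ancestry `a`
is carried by `x` of `2N` haplotypes, `f = x/2N` is tested one-sided
against the genome-wide proportion `p_a` with
`Z = (f − p_a)/sqrt(p_a(1 − p_a)/2N)`. Retention requires f ≥ 0.75,
length ≥ 1,000 bp and P < 0.01, with no multiple-testing correction —
the screen is deliberately raw, mirroring how such segment filters are
used in practice.

Two caveats are worth recording. First, the Z test treats the `2N`
haplotype ancestries at a locus as independent Bernoulli draws; that is
true under the model, but in a finite genome each haplotype's realized
ancestry fraction scatters around `m`, which overdisperses segment counts
and inflates the nominal 1% tail (the bundled calibration check measures
the fraction at roughly the nominal level only once haplotypes span
several Morgans). Second, segment frequency is the haplotype fraction
carrying the ancestry, and the missense screen below interprets the
published "minor allele frequency > 0.7" wording — which cannot describe
a true minor allele — as alternate-allele frequency.

## Selection statistics

* **π** — per-site `2j(n−j)/(n(n−1))`, summed per window and divided by
  window length in bp; 50-kb windows with 20-kb steps by default. The
  target/reference log-ratio `ln π_t − ln π_r` is NaN where either is 0.
* **Tajima's D** — the standard constants, per nonoverlapping 2-kb
  window; windows without segregating sites are NaN and flagged. With
  missing data, per-site sample sizes adjust and the constants use the
  median available count.
* **FST** — Weir–Cockerham two-population diploid variance components,
  aggregated per window as ratio of sums (the "weighted" convention of
  the common VCF tooling; the alternative per-site mean is noisier at low
  counts). Negative estimates are retained. Monomorphic-in-both sites are
  skipped.
* **iHS** — EHH is integrated (trapezoid over genetic distance) from each
  core until it falls below 0.05, a physical gap exceeds 200 kb, or the
  chromosome ends — truncation and gap defaults follow common selection
  -scan practice since no alternative was specified. Unstandardized
  `iHS = ln(iHH_ancestral / iHH_derived)` is standardized within
  derived-frequency bins of width 0.05. Ancestral alleles come from the
  simulator truth; on real data the reference allele (or an outgroup
  polarization supplied by the user) stands in and is flagged. Because
  the intended per-window summary is not uniquely defined in the
  literature this package emits both the mean |iHS| (primary) and the
  fraction |iHS| > 2 per 50-kb window.
* **CLR** — a composite likelihood ratio comparing each window's site
  frequency classes against the genome-wide background spectrum. The
  sweep model is deliberately minimal: a sweep of width α (bp, log-grid
  spanning ~300 bp to ~300 kb) hitchhikes each sampled lineage at
  distance d with probability `exp(−d/α)`; hitchhiked lineages carry the
  sweeping haplotype's allele (derived with the site's pre-sweep
  probability), escaped lineages resample it, and class probabilities are
  conditioned on polymorphism. α = 0 is exactly the background model, so
  CLR ≥ 0 always. Hitchhike probabilities are discretized to 24 levels;
  empty background classes get add-one smoothing with a warning. This is
  faithful to the composite-likelihood idea at desk scale but makes no
  claim of numeric parity with the reference implementations.
* **Intersection** — every scan is resampled to the coarsest window grid
  by maximal overlap; the empirical rank of a window is the fraction of
  windows with a value at least as large; candidates must rank within the
  top 1% in at least two scans, and adjacent candidates merge into
  regions. Rank-based significance stands in for "P < 0.01" since none
  of these statistics has a usable null model here; for statistics where
  small values mean extreme (Tajima's D), the caller passes sign-flipped
  values. Ranking refuses scans with fewer than 100 windows.

## Cohort diagnostics

KING-robust kinship uses the within-cohort estimator
`φ = (N_Aa,Aa − 2 N_AA,aa) / (N_Aa(i) + N_Aa(j))` with the published
degree thresholds (0.3536 / 0.1768 / 0.0884); pairs with fewer than 100
jointly called sites are NaN. ROH detection follows the PLINK
window-fraction rule with the conventional parameters
(100-SNP windows, ≤1 heterozygote, per-SNP hit fraction ≥ 0.05, minimum
100 kb, ≤200 kb per SNP); gap-splitting inside runs is not applied. The
LD half-decay distance interpolates linearly between distance-bin
midpoints.

Hard site filters replicate the GATK convention: QD < 2, FS > 60,
MQ < 40, MQRankSum < −12.5, ReadPosRankSum < −8, SOR > 3, all strict so
boundary values survive, a missing annotation skips its criterion, and
mean depth outside [1/3×, 3×] of the cohort mean removes the site. The
depth reference is the mean of the original call set and travels with the
filtered table, making the filter idempotent. Site classification against
gene models uses the precedence coding-exon > UTR > intron >
upstream/downstream > intergenic with a 1,000-bp flank (the common
annotator convention); where several transcripts disagree the
higher-precedence class wins, which is one defensible resolution of an
underspecified convention.

## The simulator, and what the tests show

`make_panels()` draws, per site, an ancestral frequency
p ~ Uniform(0.05, 0.95) and per-ancestry frequencies from the
Balding–Nichols Beta distribution at divergence F (exactly p at F = 0);
panel haplotypes are Bernoulli draws in linkage equilibrium.
`simulate_cohort()` lays Poisson(g per Morgan) breakpoints per target
haplotype, draws tract ancestries iid from `m`, and copies a uniformly
chosen panel haplotype of that ancestry within each tract, flipping
alleles with probability `eps` (default 0.001). `plant_features()`
inserts positive controls: ancestry-excess intervals (re-copied from one
ancestry at haplotype fraction f), sweeps (one donor haplotype pasted
into fraction f of haplotypes), and autozygous intervals (haplotype 1
copied onto haplotype 2). Defaults are sized for the desk: K = 4,
20,000 sites on 50 Mb at 1 cM/Mb, 30 reference haplotypes per panel, 30
admixed diploids; the dating checks use ten such chromosomes and the
null-calibration check uses ten chromosomes of 2,000 sites so that
several thousand segments exist.

The simulator intentionally omits several features of real data: there
is no linkage disequilibrium within the source panels (sites are
independent given the frequencies), no drift after the pulse, no phasing
or genotyping error beyond the uniform copy-error rate, no recombination
hotspots (the map is constant unless a bp→cM table is supplied), and the
site-frequency spectrum is frequency-flat rather than neutral-coalescent
— consequently Tajima's D on simulated panels is positive on average,
and the neutral-centering test uses an explicit 1/j-spectrum fixture
instead. Passing tests therefore demonstrate correctness of the
algorithms and calibration of the statistics under the stated model, not
robustness to background LD, phase error or demographic complexity.

Under those conditions the bundled tests verify: per-site painting
accuracy above 0.95 (and proportion recovery within 0.03 of the realized
cohort truth); weighted-LD dating whose jackknife 95% interval brackets
the true generation; oracle equality (1e-10) of Tajima's D, per-site
FST, the painting DP, the ROH window rule and the CLR toy likelihood
against independent brute-force implementations; recovery of planted
sweeps in the top 1% of both |iHS| and CLR with survival of the
two-method intersection; recovery of planted 500-kb autozygosity and
rejection of 80-kb plants; planted ancestry-excess intervals passing the
f ≥ 0.75 / ≥1 kb / P < 0.01 filter; ~1% of null segments below P = 0.01
at 5 Morgans per haplotype; and byte-identical end-to-end reruns under a
fixed seed.

## Numerical and degenerate-input choices

Window grids anchor at position 0 of each chromosome; the final partial
window is kept and flagged. Windows with no usable sites carry value 0
(π) or NaN (D, FST, log-ratio) and a flag rather than being dropped, so
grids stay joinable. The exponential fit initializes from a log-linear
regression of the offset-corrected curve, constrains nothing, and
reports `no_dateable_admixture` when the fitted amplitude is
non-positive; fewer than 10 usable bins is an error. Tract dating
refuses ancestries above m = 0.99 (the estimator divides by 1 − m) and
flags fewer than 30 uncensored tracts. The painting majority vote breaks
ties toward the smallest λ. Empirical ranks use the "fraction ≥ value"
convention so ties share the more extreme rank. All simulation
randomness flows from the single integer seed in `sim_config()`, and the
pipeline writes artifacts with fixed formatting so reruns are
byte-identical.

## Known limitations

Painting confidence is not quantified (no posterior probabilities); the
excess-segment test is anti-conservative on short genomes as described
above; the CLR model is a one-parameter caricature of a sweep; iHS
requires polarized alleles and inherits proxy error otherwise; the
weighted-LD curve assumes the two chosen panels bracket the true sources
— a missing third source biases the amplitude; and the single-pulse
model cannot represent continuous or multi-wave gene flow, for which the
fitted `n` is an effective, not historical, age.
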