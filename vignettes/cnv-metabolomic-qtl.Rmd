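---
title: "CNV dosage and metabolomic signatures: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CNV dosage and metabolomic signatures: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvmetabo)
```

cnvmetabo studies the dosage effect of copy-number variants (CNVs) on
metabolite panels, starting from SNP-array intensity data: the log R ratio
(LRR, normalised total intensity) and the B allele frequency (BAF, allelic
intensity ratio) at each genotyping probe. This vignette describes the
models, the defaults and why they were chosen, and what the package's
synthetic data can and cannot tell you about real cohorts.

## The copy-number model

Copy number along each sample's probe sequence is modelled with a five-state
hidden Markov model over copies {0, 1, 2, 3, 4}: homozygous deletion,
heterozygous deletion, copy-neutral, heterozygous duplication, homozygous
duplication. Emissions follow the standard array model:

* LRR is Gaussian per state, with default means (−3.5, −0.66, 0, 0.40,
  0.68) — the conventional Illumina-style cluster positions, configurable in
  `hmm_params()` — and per-state SDs (1.0, 0.25, 0.20, 0.25, 0.30). The wide
  state-0 SD reflects the near-total loss of signal at homozygous deletions.
* BAF is a mixture of [0,1]-truncated Gaussians placed at the attainable
  allelic ratios of each copy number (copy 2 at {0, 1/2, 1}, copy 3 at
  {0, 1/3, 2/3, 1}, and so on) with binomial-style default weights. Copy 0
  has no allelic signal and is modelled as uniform on [0, 1].

Transitions are distance-aware: over a gap of $d$ bp the chance of leaving
the current state is $p(d) = \mathrm{clip}(1 - e^{-\rho d},\,
p_{\min},\, p_{\max})$, and switching re-draws the state from a stationary
prior that makes CNV states rare (0.989 mass on copy-neutral). This form is
the identity at $d = 0$ and relaxes to the prior at large distances; the
default rate $\rho = 10^{-6}$/bp puts the switching length scale at about a
megabase, matching the package's focus on small-to-intermediate CNVs rather
than rare megabase-scale events. The model is per-sample and unphased; no
population haplotype structure is used, because nothing downstream needs it:
all association quantities derive from per-probe state posteriors.

`forward_backward()` returns exact smoothing posteriors (with scaling, so
chromosomes of any length are numerically safe), and `viterbi_segments()`
reports maximal runs of non-neutral states in the MAP path as CNV segments.
Both agree with exhaustive path enumeration on short chains to $10^{-10}$,
which is how the test suite validates them.

### Expected genotypes (countAll)

The dosage used in association is the posterior-expected copy number at each
probe, $\mathrm{countAll} = \sum_{s=0}^{4} s\,\gamma_s \in [0,4]$ — e.g.
posterior 0.7 on copy 1 and 0.3 on copy 2 gives $1\cdot0.7 + 2\cdot0.3 =
1.3$. This single vector captures deletions, copy-neutral and duplications
additively (a "mirror model"). Deletion-only and duplication-only
expectations (renormalised over states {0,1,2} and {2,3,4}) are also
produced; where a sample has no posterior mass at all on the retained
states, the renormalised expectation is undefined and falls back to 2.
A dosage-based allele frequency is defined as
$f = \sum_i |d_i - 2| / (2n)$, folded to $\min(f, 1-f)$; this is a declared
convention (the mean absolute copy deviation per haploid genome), chosen
because no standard CNV MAF definition exists for continuous dosages.

To disentangle deletion and duplication effects at a locus, samples can be
stratified by countAll (< 1.75 deletion, > 2.5 duplication) and each CNV
group compared with the copy-normal group by a two-sided Mann–Whitney test
(`stratified_validation()`; exact below 25 samples without ties, normal
approximation with tie correction otherwise).

## Intensity normalisation

Two artifacts are removed from LRR before calling, in this order:

1. **GC correction** (`gc_correct()`): per sample, LRR is regressed on probe
   GC fraction and replaced by the residuals (mean preserved). GC runs
   first so the positional trend removed next is not GC-confounded.
2. **Wave correction** (`wave_correct()`): per sample and chromosome, a
   local degree-1 regression of LRR on position with tricube weights and a
   500 kb bandwidth is fitted and subtracted. Degree 1 was chosen for
   robustness at chromosome ends, where the window is one-sided; windows
   with fewer than three probes fall back to the window mean.

A property worth knowing: a CNV spanning a sizeable fraction of the local
window is itself partly absorbed by the fitted trend, attenuating the
corrected LRR contrast of wide events (the test suite measures roughly a
30% attenuation for a 120 kb event under the default 5 kb probe spacing).
This is inherent to window-based wave removal; the HMM still segments such
events reliably because the residual contrast remains several noise SDs.

`compute_lrr_pcs()` takes the first $k$ (default 50) principal components of
the corrected LRR matrix as technical covariates; $k$ is capped at the
matrix rank with a warning for small panels. On small simulated panels with
few probes, high-variance planted CNVs can leak into the leading PCs and
absorb part of the signal — on real arrays with $10^5$–$10^6$ probes a
single locus cannot dominate a component, so this is a small-simulation
artifact to keep in mind when choosing $k$ in demonstrations.

## Association models

All association uses *reverse regression*: the outcome is the CNV dosage
(countAll, or raw corrected LRR for the calling-free validation model) and
the predictors are metabolites, plus covariates (LRR PCs and sex) that are
never dropped. The dosage is treated as continuous and fitted by least
squares — countAll is an expectation in [0, 4], not a discrete genotype, so
the ordinal variant of the joint-phenotype approach does not apply. The
guard for this choice is the classical equivalence: with covariates
residualised out, the reverse and forward univariate regressions have
identical t-statistics, which the tests verify.

* `univariate_assoc()` fits one metabolite at a time and reports beta, SE,
  raw and corrected p, sample size and dosage allele frequency.
* `multivariate_signature()` starts from the joint model with all
  metabolites and repeatedly removes the one with the largest p-value while
  that p-value exceeds `drop_alpha` (default 0.05), refitting fully each
  step. The retained set is the *metabolomic signature*; its joint p-value
  is the F-test of the selected block against the covariate-only model.
  Largest-p removal with full refit is a declared criterion — the selection
  procedure's name alone does not fix one. When $n$ is too small for the
  full joint fit, metabolites are pre-screened to the top $\lfloor n/10
  \rfloor$ by univariate p (with a warning).

### Multiple testing

Metabolite panels are strongly correlated, so Bonferroni-style counting of
$M$ raw tests overcorrects. The effective number of tests is taken from the
eigenvalue variance of the metabolite correlation matrix:
$$M_\mathrm{eff} = 1 + (M-1)\left(1 - \mathrm{Var}(\lambda)/M\right),$$
with the *sample*-variance convention (divisor $M-1$), chosen so the two
limits are exact: an identity correlation gives $M_\mathrm{eff} = M$ and a
perfectly correlated panel gives exactly 1. Adjustment is Sidak-style,
$p_\mathrm{adj} = 1 - (1-p)^{M_\mathrm{eff}}$ (evaluated via `log1p`/`expm1`
so p-values near the double floor survive), isolated in `adjust_p()` so a
plain multiplicative correction can be swapped in if preferred. A global
reporting filter marks records with adjusted $p \le 0.05$ as reportable.

## Two-cohort analysis

`common_probes()` intersects two probe maps on exact genomic position
(chrom, pos) — no liftover, matching how cross-platform concordance is
established in practice. Matched per-cohort records are combined two ways:

* `meta_analyze()`: fixed-effect inverse-variance meta-analysis
  ($w = 1/se^2$), with Cochran's Q reported so heterogeneity is visible and
  a random-effects extension is straightforward. Fixed-effect was chosen as
  the minimal defensible estimator for two cohorts.
* `pooled_assoc()`: a single regression on the stacked samples with a
  cohort indicator added to the covariates, so cohort-level phenotype
  shifts are absorbed rather than biasing the dosage term. Under
  homogeneity the two routes agree, which the tests check.

## Beacon annotation

`match_by_position()` juxtaposes external GWAS summary statistics to probes
purely by genomic coordinate (variant-agnostic: the rsid is carried but
never used for matching), with a window of 0 bp by default — exact-position
matching is the conservative default; a ±4 bp window is available for
overlap conventions that use one. Matching is a linear merge over the
position-sorted inputs and is validated against a quadratic all-pairs
oracle. `build_beacon()` assembles one row per probe with strictly binary
flags (reportable metabolomic signature, LRR signature, CNV presence per
cohort, GWAS overlap, arbitrary extra evidence under a registered schema),
and `rank_matched_loci()` orders matches by p-value with deterministic
(chrom, pos) tie-breaks.

## The synthetic-data generator

`sim_config()` + `simulate_cohort()` generate everything the pipeline
consumes. What it emulates, and the defaults (all configurable, chosen once
as realistic array conditions since no platform noise levels are published
for the emulated chips):

* probe map: exponential inter-probe gaps (mean 5 kb), GC fraction from a
  latent AR(1) along the probe order so neighbouring probes share GC;
* intensities: state-mean LRR plus a linear GC term (coefficient 0.2), a
  2 Mb-period sinusoidal wave with per-sample phase (amplitude 0.05), and
  Gaussian noise (SD 0.18); BAF from per-probe population B-allele
  frequencies with binomial allele counts given the copy state (SD 0.03
  jitter, uniform at copy 0);
* CNV truth: declared regions with a single copy state each and carriers
  drawn at the declared population frequency;
* phenotypes: block-correlated Gaussian background (blocks of 12,
  within-block correlation 0.5 — mimicking lipoprotein-subclass clusters;
  default 228 metabolites) plus planted linear dosage effects
  $\beta \cdot (\text{copy} - 2)$; sex is simulated as a covariate with no
  phenotype effect by default.

Fixed seeds make every output byte-identical; each generator stage derives
its own RNG seed from the master seed, so stages are reproducible
independently of call order. Two cohorts are simulated by two calls with
distinct seeds.

What the generator does **not** emulate: batch/plate structure, probe
cross-hybridisation, ancestry stratification, real linkage disequilibrium,
mixed deletion/duplication alleles at one locus, non-Gaussian metabolite
tails, or NMR spectral artifacts. Passing tests therefore demonstrate the
pipeline's correctness and calibration under a clean generative model — not
robustness to every failure mode of a real cohort.

## Problem sizes and numerical choices

The test suite and examples run at deliberately small scale — panels of
tens of samples by hundreds of probes, calibration at $n = 500$ with 1000
null replicates, signature recovery at $n = 2000$ over 50 seeds — sizes a
laptop handles in seconds to minutes while still giving binomial error bars
tight enough for the stated bounds. Other numerics: forward–backward uses
per-probe scaling (no log-space needed); posterior slices are validated to
sum to 1 before dosage conversion; `effective_tests()` rejects
non-positive-semidefinite inputs beyond an eigenvalue tolerance;
Viterbi tie-breaks (`max.col(..., "first")`) are deterministic, preferring
the lower copy state.

## Known limitations

* Per-sample HMM: no borrowing of strength across samples or haplotype
  phasing, so very short (< 3 probe) events have limited support.
* No chromosome X/Y handling; autosomal analysis only.
* Wave correction attenuates events wide relative to its window (above).
* The dosage MAF and the effective-tests variance convention are declared
  definitions; alternatives exist and are isolated in single functions.
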