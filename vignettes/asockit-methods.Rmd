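---
title: "ASoCkit: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ASoCkit: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

ASoCkit implements three connected analyses for studying putatively
functional regulatory variants in iPSC-derived neural cells: allele-specific
open chromatin (ASoC) calling from ATAC-seq allelic read counts, allelic
scoring of transcription-factor binding motifs, and differential expression
in mixed human-neuron / mouse-astrocyte co-culture RNA-seq.  This vignette
describes the statistical models, the tunable parameters and their defaults,
what the built-in simulators do and do not emulate, and the design decisions
taken where more than one reasonable implementation existed.

## 1. ASoC calling

### Model

A heterozygous biallelic SNP carries one reference and one alternative
allele, so ATAC-seq reads overlapping the site can be assigned to an allele
by their base call.  If chromatin accessibility is allele-independent, each
informative read is a fair coin flip between the alleles.  The caller
therefore:

1. retains per-sample records with het genotype (`0/1`, `1/0`, phased
   equivalents), total depth ≥ `min_dp`, both alleles supported by
   ≥ `min_allele` reads, and — when a `tranche` value is attached —
   tranche > `min_tranche`;
2. pools reference/alternative counts per SNP across all retained
   heterozygous samples;
3. computes the exact two-sided binomial p-value of the pooled reference
   count x out of n reads at null probability 0.5;
4. applies Benjamini–Hochberg step-up adjustment over all qualified SNPs;
5. calls ASoC where q < `fdr` (strictly), optionally annotating each SNP
   with open-chromatin-peak overlap.

### Parameters

| parameter | default | meaning |
|---|---|---|
| `min_dp` | 20 reads | minimum informative depth per record |
| `min_allele` | 2 reads | minimum support for *each* allele per record |
| `min_tranche` | 99.5 % | VQSR sensitivity tier pass-through (strict >) |
| `fdr` | 0.05 | BH threshold, strict `q < fdr` |

Design readings worth making explicit:

* **"Minimum reference or alternative allele count ≥ 2"** is implemented as
  min(ref, alt) ≥ 2 — a het-confirmation filter.  Requiring only *one*
  allele to reach 2 reads would be vacuous at depth ≥ 20 and would admit
  genotyping errors that masquerade as extreme imbalance.  A consequence is
  that a record such as 200 reference / 0 alternative reads is *excluded* by
  the default filters (it looks like a genotyping error, not open
  chromatin); the degenerate fully-skewed case is reachable by setting
  `min_allele = 0` explicitly.
* Filters apply per record (per sample), before pooling — extraction,
  retention, combination, in that order.
* The two-sided p-value follows the minimum-likelihood convention (sum the
  null pmf over all outcomes no more likely than the observed one, ties
  within a 1e-7 relative tolerance), which at p₀ = 0.5 reduces to the
  closed form min(1, 2·P(X ≤ min(x, n−x))).  The closed form is used for
  speed; exhaustive enumeration backs it in the tests.
* Technical replicates are pooled like distinct samples by default;
  `collapse_donors = TRUE` first sums counts within a `donor_id`.
* No reference-mapping-bias correction is applied by the caller; mapping
  bias exists only as a simulator knob (`ref_bias`) so its effect on the
  pipeline can be probed.
* The VQSR tranche is an opaque numeric quality tier from upstream variant
  calling; it is treated as a pass-through filter, never recomputed.
* BH ties are broken by stable input order (the behaviour of
  `stats::p.adjust`), and the call table is sorted by q then p.

### Power

`estimatePower()` estimates, by Monte Carlo, the probability that one truly
imbalanced SNP (per-donor alt-read probability `alt_fraction`) is called
when tested alongside `n_null_background` balanced SNPs.  Each replicate
draws per-donor depths (Poisson by default, negative-binomial via
`depth_dispersion`), applies exactly the per-record filters, pooling, test
and BH threshold of the caller, and records the decision; the estimate's
Monte-Carlo standard error is sqrt(power·(1−power)/n_reps).  The replicate
path is vectorised; a test pins its equivalence to `callASoC()` on
materialised records.  Note the interaction with `min_allele` above: as
`alt_fraction` approaches 1, per-record minor-allele support collapses and
power *drops* — the filters define what the pipeline can see.

## 2. Allelic motif scoring

A JASPAR-style position frequency matrix is normalised to probabilities
with a proportional pseudocount (`(count + 0.01·total) / (total·1.04)` per
position); the pseudocount keeps log-odds finite without reordering bases.
A SNP-flanking window is scored as the maximum, over both strands and over
every placement of the motif that covers the SNP, of
Σᵢ log₂(pᵢ(bᵢ)/qᵢ(bᵢ)) with a uniform background q by default; `N` bases
contribute the background (zero) term.  Only SNP-covering placements are
scored because the question is allelic disruption *at the SNP*, not
genome-wide scanning.  The allelic statistic is
Δ = best(alt) − best(ref); its sign is the predicted disruption direction.
Ties between placements prefer the forward strand, then the smallest
offset.  All coordinates in the R API are 1-based.

## 3. Co-culture differential expression

### The composition problem and the correction factor

In a co-culture of human neurons and mouse astrocytes sequenced as one
library, the fraction of reads from each species varies from sample to
sample with the cellular composition.  Normalising a human transcript by
the *whole* library size confounds its expression with the sample's
neuron:astrocyte ratio.  The per-sample ratio of human to mouse read counts
is therefore carried as a correction factor, realised as **species-specific
effective library sizes**: a human transcript's offset in sample s is
log(human total of s), a mouse transcript's log(mouse total of s).  The
mechanism behind the published ratio statement is not spelled out there;
the species-offset realisation was chosen because it makes the test exactly
invariant to composition shifts, which is the correction's stated purpose.
Both modes are implemented (`offset_mode = "species"` / `"whole"`), and an
acceptance-level test demonstrates that a pure composition shift (tripling
one sample's human counts) changes no human-transcript call under species
offsets while being miscalled wholesale under a single whole-library
offset.  That demonstration supplies the simulation's generative dispersion
to both modes: with dispersions *estimated* from the perturbed data, a
single-sample shift inflates the per-transcript dispersion estimate by more
than it moves the group means (the inflation grows with the square of the
shift), so either mode absorbs it — at a power cost — and the offset
mechanism itself would be invisible.

### Filtering, CPM, PCA

Transcripts must be expressed (nonzero raw count) in at least 75% of
samples; the comparison is `expressed/n ≥ min_fraction` on the exact
fraction, so 7 of 9 samples (77.8%) passes and 6 of 9 (66.7%) fails.
"Expressed" means a nonzero raw count — the simplest reading; a CPM
threshold variant can be had by filtering on `computeCpm()` output.  CPM
uses the species-specific effective sizes by default.  PCA operates on
log₂(CPM+1), transcript-centred; the pseudo-count of 1 is the conventional
choice that keeps zeros at zero.

### The NB model

Per transcript g and sample s, counts follow a negative-binomial
log-linear model

&nbsp;&nbsp;y₍gs₎ ~ NB(μ₍gs₎, φ_g),&nbsp;
log μ₍gs₎ = o₍gs₎ + β₀g + β₁g·x_s,

with x_s the two-level group indicator (second level vs first, levels in
order of first appearance) and o the fixed offsets above;
log2FC = β₁/ln 2.  Fitting is Fisher scoring vectorised across transcripts.
Dispersions are estimated per transcript by maximising the Cox–Reid
adjusted profile likelihood on a 30-point log-spaced grid (10⁻⁶ … 5), then
log-shrunk toward a lowess mean–dispersion trend with weights
`prior_df` : residual df (default 10 : n−2) — the trend borrows strength
across transcripts, the CR adjustment removes the downward bias from the
two estimated mean parameters.  The group effect is tested by the
likelihood-ratio statistic referred to an F(1, residual df + prior df)
distribution rather than χ²₁: the widened tail accounts for dispersion
estimation uncertainty, exactly in the spirit of quasi-likelihood F-tests.
With a *supplied* (known) dispersion the reference reverts to χ²₁.
Significance is strict FDR < 0.05 after BH.  Per gene, the smallest-p
transcript is the gene representative; ties go to the larger mean
expression, then the lexicographically smaller id.

Calibration was checked on simulated nulls (7,000 transcripts, 18 samples):
the fraction of p < 0.05 sits at 0.05 ± 0.01, BH makes no calls, and the
p-distribution passes a Kolmogorov–Smirnov test against uniform.  Exact
numerical parity with any particular published GLM implementation is not a
goal; a test pins log-fold-change agreement (r > 0.98) and p-value rank
agreement with an independent NB GLM fit.

### Degenerate inputs and numerics

All-zero transcripts are excluded with a warning before fitting.  A sample
with a zero species total has no defined ratio and raises an error naming
the sample.  Coefficients are clamped to |β| ≤ 50 (transcripts silent in
one whole group otherwise diverge); p-values are floored at the smallest
positive double so that 0 < p ≤ 1 always holds; identical counts across
samples with equal offsets give log2FC = 0 and p = 1 exactly.

## 4. What the simulators emulate — and what they do not

`simulateAllelicCounts()` draws, per SNP × donor: het status
(Bernoulli `het_prob`), depth (NB with mean `depth_mean` and size
`depth_dispersion`; ∞ = Poisson — the field lacks a canonical per-SNP ATAC
depth law, so the simplest over-dispersed count model was chosen, with
Poisson as a limit), and an alt count that is binomial with
p_eff = a/(a + `ref_bias`·(1−a)), a = `alt_fraction` at imbalanced SNPs and
0.5 otherwise.  `ref_bias` > 1 emulates reference-mapping bias.
`simulatePeaks()` places non-overlapping intervals covering an exact
fraction of SNPs, clipped at inter-SNP midpoints so uncovered SNPs stay
uncovered.  `simulateCocultureCounts()` draws per-sample composition ratios
and library sizes (log-normal), log-normal transcript abundances, NB counts
with a common dispersion, planted ±log2FC effects in the second group, and
independent Bernoulli dropout (which reproduces the "expressed = nonzero"
semantics the 75% filter needs).  Defaults reflect the study design at desk
scale: 9 biological replicates per genotype group, |log2FC| = 1 in 10% of
transcripts, dispersion 0.1, and a few thousand transcripts per species
(the acceptance runs use 4,000 human + 3,000 mouse; real co-culture
libraries quantify an order of magnitude more).

Not emulated — so green tests say nothing about: read-level artefacts
(alignment, duplicates, Tn5 insertion preferences, fragment-length
structure), cross-species read misassignment at the aligner, linkage
between nearby SNPs, correlated dispersion structure, batch effects, or
genuinely zero-inflated expression beyond independent dropout.  Dropout
also makes the NB dispersion estimates absorb the extra zeros, so DE power
under dropout is conservative relative to a pure NB world.

All randomness flows from one explicit seed per simulator call
(`withr::with_seed`), giving byte-identical outputs for identical
configurations — the property the acceptance replicates and the CLI's
file-level determinism rely on.  Output provenance headers deliberately
carry parameters but no timestamp for the same reason.

## 5. Problem sizes used by the shipped checks

The test suite and `scripts/acceptance.R` run at desk scale, chosen as the
smallest sizes at which the checked properties are statistically sharp:
100 replicates × 10,000 SNPs for global-null FDP control of the ASoC
caller; exhaustive binomial-oracle agreement for all x at n ≤ 200;
1,000 random vectors against the brute-force BH definition; power curves at
2,000 Monte-Carlo replicates; DE recovery on the default 4,000 + 3,000
transcript × 18 sample simulation; 1,000 seeded motif-disruption fixtures.

## 6. Known limitations

* Pooling across samples treats reads as exchangeable; donor-level
  overdispersion of allelic fractions (a beta-binomial world) would
  anti-conserve the binomial p-values.  The filters' minor-allele rule and
  the BH layer mitigate but do not remove this; a beta-binomial extension
  is the natural next step.
* The exact JASPAR matrix versions for any particular factor are the
  user's choice and input; the package ships only a synthetic example
  motif.
* The quasi-F reference is a pragmatic small-sample correction, not a full
  quasi-likelihood treatment; with very few samples per group (2–3) its
  p-values are approximate.
* `estimatePower()` models all donors as heterozygous at the SNP of
  interest; donor-count attrition by genotype must be applied by the
  caller (halve the donors for a typical het frequency, say).
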