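---
title: "From sort-seq counts to clinical evidence: the mavemap pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From sort-seq counts to clinical evidence: the mavemap pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mavemap)
```

# The problem

A multiplexed assay of variant effect (MAVE) measures the function of
thousands of variants of one protein in a single experiment. In the
sort-seq design this package models, a mutagenized clone library is
integrated into a reporter cell line, cells are sorted by fluorescence so
that the "select" pool keeps only the top fraction of reporter-expressing
cells, and both the select pool and an unsorted "non-select" pool are
deep-sequenced in tiles. A variant that preserves protein function is
enriched in the select pool; a variant that destroys function is
depleted. Sequencing an unmutagenized wild-type template alongside
measures base-call error, which otherwise masquerades as low-frequency
variation.

`mavemap` covers the downstream analysis end to end: scoring
(`score_variants()`), calibration of scores into clinical evidence
(`llr_calibrate()`), benchmarking against reference variants
(`prc_curve()`, `r90bp()`), genotype-phenotype analyses for diploid
patients (`cohort_cam()`, `symptom_correlation()`, and friends), and
map-level analyses (`positional_medians()`, `gain_of_function_test()`,
`snv_accessible_substitutions()`, ...). A ground-truthed simulator
(`simulate_experiment()`) generates complete synthetic experiments so
every stage can be validated against known truth without external data.

# The scoring model

For each codon-level change $c$, condition and replicate, counts are
converted to counts per million (cpm). Within each replicate:

1. **Filtering.** A change is kept iff its non-select frequency reaches
   10 cpm (boundary inclusive — the filter is a *minimum threshold*).
   Changes may survive in one replicate only; they are then scored from
   that replicate alone and flagged.
2. **Error subtraction and enrichment.** With wild-type control
   frequencies subtracted on the cpm scale,
   $\phi_c = \frac{\max(\mathrm{cpm}^{sel}_c - \mathrm{cpm}^{wt,sel}_c,\ \delta)}
   {\max(\mathrm{cpm}^{non}_c - \mathrm{cpm}^{wt,non}_c,\ \delta)}$,
   with floor $\delta = 0.1$ cpm keeping the ratio finite and positive
   when subtraction overshoots. Floor events are tallied in the fit log.
3. **Rescaling.** $\log\phi$ values are affinely rescaled so the median
   nonsense change maps to 0 and the median synonymous change maps to 1.
   Scores are therefore unitless: 0 is "null-like", 1 is
   "wild-type-like", and values above 1 indicate reporter
   hyper-activation. The rescaling also makes final scores invariant to
   the logarithm base (natural log by default; the invariance is
   property-tested).
4. **Aggregation.** Codon changes translating to the same amino-acid
   substitution are averaged; the standard error is the sample SD over
   codon scores divided by $\sqrt n$. A substitution measured by a single
   codon change gets a Poisson delta-method error,
   $\sqrt{1/n^{sel} + 1/n^{non}}$ on the natural-log scale divided by the
   rescale denominator.
5. **Error regularization.** Because a sample SD over 2-4 codon scores is
   itself very noisy, each SE is shrunk toward an abundance trend fitted
   across variants by least squares, $\log SE \sim a + b \log
   \mathrm{cpm}^{non}$, with weight $w = m/(m + n - 1)$ on the trend
   ($m = 4$ pseudo-measurements; a singleton takes the trend value
   outright). A known limitation: the trend conditions on non-select
   abundance only, so select-side heteroskedasticity — intermediate
   variants whose select counts are small but not floored — is not
   captured.

Replicates are then averaged (unweighted, matching the convention of
averaging biological replicates rather than inverse-variance weighting)
and errors propagated as $\sqrt{\sum_i se_i^2}/k$.

Each scored substitution carries an SNV-accessibility flag: whether the
amino-acid change is reachable by a single nucleotide change of a
contributing reference codon (`snv_neighbor_substitutions()`), since
SNV-accessible substitutions are the ones most likely to be observed
clinically.

# Clinical calibration

Scores are converted to log likelihood ratios of pathogenicity
($LLR_p$) by a two-class kernel density model over the scores of
clinical reference variants: pathogenic/likely-pathogenic (positive) and
benign/likely-benign (negative) variants with at least one review star.
Both densities use the Epanechnikov kernel with Scott rule-of-thumb
bandwidths, $h = 2.34\,\hat\sigma\,N^{-1/5}$ with
$\hat\sigma = \min(SD, IQR/1.349)$; 2.34 is the canonical Epanechnikov
scaling of the Gaussian reference rule and is configurable, since rules
of thumb differ in their constant. Then

$$LLR_p(s) = \log_{10}\frac{\max(f_P(s), \epsilon)}{\max(f_B(s), \epsilon)}$$

with a density floor $\epsilon = 10^{-12}$ preventing infinite ratios
where one compactly-supported density vanishes inside the valid range.
Scores outside the observed range of reference scores (the union range
over both classes) are *undetermined*: the model refuses to extrapolate.

Evidence strengths use the point-based threshold ladder on
$|LLR_p|$: 0.318 (supporting), 0.636 (moderate), 1.272 (strong), with
everything beyond capped at strong in both directions. A configurable
*benign mask* (defaulting to the PHD1 domain, residues 296-343) withholds
benign-direction labels at positions where the assay is known to be
blind: a reporter integrated in open chromatin cannot detect loss of a
closed-chromatin-specific function, so a wild-type-like score there is
not evidence of benignity. Finally, a *caution* flag marks variants whose
95% confidence interval ($z = 1.96$; the level is configurable)
straddles 0.5, the midpoint between the nonsense and synonymous medians —
scores that cannot be confidently placed on either side of
half-function.

# Benchmarking

`prc_curve()` sweeps every observed score value as a threshold (ties
grouped, no interpolation or monotonization — the smallest-assumption
reading) and reports *balanced precision*: with recall
$r_P = tp/(tp+fn)$ and false-positive rate $r_N = fp/(fp+tn)$, balanced
precision $= r_P/(r_P + r_N)$, the precision expected under a 50/50
class prior. It depends only on the two rates, so it is invariant to the
arbitrary class balance of a curated reference set (property-tested).
`r90bp()` reports the maximum recall at balanced precision at or above
0.90. Orientation is declared per predictor: lower scores are damaging
for a functional map, higher for most computational predictors. When
several predictors are compared, `benchmark_predictors()` restricts to
the intersection of variants scored by all of them.

# Genotype-phenotype analyses

The map scores single alleles; patients are diploid. The combined-allele
map (CAM) score of a genotype is the sum of its two allele scores, with
wild-type alleles scored 1, truncating alleles (nonsense, frameshift,
splice-site) modeled as null (0), and a multi-variant allele scored by
its most damaging variant. A monoallelic missense patient therefore has
CAM = 1 + (variant score). CAM lies in [0, 2] when map scores lie in
[0, 1]; gain-of-function scores can exceed it.

Severity proxies: the number of reported symptoms (Pearson correlation
against CAM by default — "R" in the clinical literature is conventionally
Pearson; Spearman available) and the diagnostic dyad (at least two of
hypoparathyroidism, adrenal insufficiency, chronic mucocutaneous
candidiasis), compared by two-sided Wilcoxon rank-sum. Patients carrying
variants in masked domains can be excluded with `exclude_positions()`.

Population-scale carrier analysis: `carrier_association()` forms the
2x2 carrier-by-diagnosis table, reports the odds ratio with
Haldane-Anscombe +0.5 correction when a cell is empty, a Wald 95% CI on
the log odds ratio and a Fisher exact p, with Benjamini-Hochberg
adjustment across the configured symptom family
(`carrier_association_table()`). `damaging_carrier_sets()` builds the
carrier flags under five non-exclusive definitions of damaging
(classical LoF; LoF or map evidence; LoF or AlphaMissense; LoF or
REVEL > 0.5; any), always restricted to rare variants (MAF < 1e-4). The
map-damaging definition defaults to pathogenic-direction evidence at
supporting strength or stronger, exposed as configuration since no
canonical threshold exists.

# Gain-of-function testing

Roughly half of truly wild-type-like variants land numerically above 1,
so a score above 1 is not evidence of hyper-activation. For each variant
a one-tailed empirical p-value against the synonymous score distribution
is computed with the add-one form $p = (1 + \#\{syn \ge s\})/(N_{syn} +
1)$ — ties count toward exceedance and zero p-values are impossible, so
the test is conservative by construction (validity under the null is
property-tested). Benjamini-Hochberg adjustment is applied across all
tested variants.

# What the simulator emulates — and what it does not

`sim_config()` defaults describe one desk-scale mutagenic region under
the standard library quality-control envelope:

| parameter | default | meaning |
|---|---|---|
| `protein_length` | 182 | codons in one mutagenic region |
| `lambda` | 0.6 | mean Poisson codon substitutions per clone (QC range 0.4-1) |
| `n_clones` | 200,000 | clone pool size; gives >85% of substitutions above 10 cpm |
| `depth` | 1e6 | reads per tile and condition |
| `error_rate` | 1e-4 | per-nucleotide base-call error, measured on the WT template |
| `gate_fraction` | 0.10 | top fluorescence fraction sorted into the select pool |
| `n_replicates` | 2 | biological replicates |
| `cell_noise_sd` | 0.4 | per-cell log-fluorescence SD around the clone mean |

True activities attach to amino-acid outcomes: synonymous exactly 1,
nonsense 0 (optionally tolerated in a C-terminal window), and missense
from a two-component mixture — 40% deleterious Beta(2, 8), the rest
near-wild-type N(1, 0.07) with a 2% gain-of-function tail
Uniform(1.1, 1.5). A clone's fluorescence mean is the *minimum* activity
over its substitutions (a deleterious hit dominates a multi-mutant
clone — exactly the mechanism by which multi-mutant clones confound
marginal counts), mapped linearly to log-fluorescence with Normal
per-cell noise. The gate is the pool-level $1 -$ `gate_fraction`
quantile of the fluorescence mixture, solved numerically; select reads
are multinomial over clones weighted by frequency times gate-passing
probability, non-select reads multinomial on raw frequency. Base-call
error adds Poisson counts with per-read miscall probability
$(\mathrm{error\_rate}/3)^{d}$ for a codon change differing at $d$
nucleotides, to the variant channels and (alone) to the WT control
channels.

Features of real data the simulator does **not** emulate: biological
replicates are independent sequencing and sorting draws from one shared
clone pool, not independent transfections, so simulated replicate
agreement is optimistic compared to a real experiment; tiles are not
modeled individually (one tile per region); PCR jackpotting, index
hopping and position-dependent sequencing error are absent; and true
activities are drawn independently across substitutions, with none of
the positional or biochemical structure of a real protein. Passing
recovery tests on this generator therefore demonstrates that the
*pipeline arithmetic* is faithful under the designed noise model — not
that a real experiment of this size would achieve the same accuracy.

# Numerical choices

* Filter boundary inclusive at 10 cpm ("reaching a minimum threshold").
* Floor $\delta = 0.1$ cpm for post-subtraction frequencies; how negative
  frequencies are handled is otherwise unspecified in the field, and
  flooring keeps every $\phi$ finite and positive; floor events are
  logged.
* Natural log for enrichment; outputs are invariant to the base (scores
  exactly; SEs because the delta-method error is computed on the
  natural-log scale).
* Singleton read counts are clamped to 1 read in the delta-method SE to
  avoid division by zero for floored numerators.
* Degenerate calibration (equal nonsense and synonymous medians) and
  missing anchor classes are hard errors, never silently patched.
* Kernel densities are compactly supported; the $10^{-12}$ density floor
  only matters where one class's support ends inside the valid range,
  and the cap at strong bounds the resulting evidence.
* Undetermined evidence uses the union range of both reference classes,
  not per-class ranges.

# Validation design

The test suite validates each stage against hand-computed examples and
independent oracles: SNV enumeration against brute-force mutation of
every nucleotide; kernel densities against `stats::density`; empirical
p-values against null uniformity; carrier CIs against coverage under
independence; and the full scoring pipeline against the simulator's
ground truth (Pearson r of at least 0.9 between recovered scores and
true activities under the default conditions, and nonsense/synonymous
separation at Wilcoxon p below 1e-10).

Standard errors are validated against a 200-resample count-resampling
bootstrap on a directly-constructed 500-variant Poisson count table
(bimodal activities, 2-4 codon changes per variant sharing abundance up
to 10% jitter, anchor classes included). The direct construction matters:
count resampling is only a valid error oracle where marginal count noise
dominates, whereas a full sort-seq simulation adds clone-composition
noise — which codon changes ride on which multi-mutant clones — that
count resampling cannot regenerate, so the bootstrap there *under*-states
the uncertainty the pipeline must report.

Problem sizes used throughout the suite (a 182-codon region at 1e6 reads
for the default experiment; a 60-codon region at 2e5 reads where the
pipeline is rerun repeatedly; 100-200 Monte-Carlo repetitions for
coverage and permutation checks) were chosen as the smallest scales at
which the distributional checks have useful power.

# Known limitations

* The error-regularization trend conditions on non-select abundance only
  (see above); intermediate-activity variants with small select counts
  have the least reliable SEs — in real maps as here.
* The PHD1-style benign mask is a blunt positional rule; it cannot
  distinguish genuinely benign variants inside the masked domain.
* Calibration quality is bounded by the reference set: with 30 positive
  and 16 negative variants, $LLR_p$ beyond the evidence cap is not
  meaningful, and the undetermined range is wide.
* CAM addition assumes allelic effects combine additively on the score
  scale; dominant-negative mechanisms violate this and are not modeled.
* The cohort analyses ignore age and ascertainment, as any symptom-count
  proxy must.

# A worked example

```{r example, eval = FALSE}
expt <- simulate_experiment(sim_config(seed = 1))
fit <- score_variants(expt)
summary(fit)

refs <- simulate_reference_set(expt$truth, n_pos = 30, n_neg = 16,
                               seed = 2)
model <- llr_calibrate(fit, reference = refs)
evidence <- predict(model, fit, benign_mask = phd1_positions())
head(evidence)

cohort <- simulate_cohort(expt$truth, n_patients = 98, beta1 = -0.5,
                          seed = 3)
cohort <- cohort_cam(cohort, fit$scores)
symptom_correlation(cohort$cam, cohort$n_symptoms)
```
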