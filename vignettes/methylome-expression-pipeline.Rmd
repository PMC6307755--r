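---
title: "Integrative methylation-expression analysis: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrative methylation-expression analysis: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meqtm)
```

## Scope and scientific setting

`meqtm` implements an integrative pipeline for paired DNA-methylation
array and RNA-seq data in small clinical cohorts, modelled on studies of
ileal fibroblasts from Crohn's disease patients, where stenotic (STEN),
inflamed (INF), and non-inflamed (NINF) tissue of origin, plus non-CD
controls, are compared. Cohorts of this kind are small (tens of samples),
contain repeated samples per patient, and measure only a subset of
samples on both assays, and the pipeline's statistical choices are driven
by those constraints.

The stages are:

1. probe filtering and Beta/M transformation;
2. a PCA covariate screen;
3. per-CpG differential methylation (DMPs) with empirical-Bayes
   moderation and patient blocking;
4. region calling (DMRs) by gap clustering with signed Stouffer
   combination and BH control;
5. negative-binomial differential expression (DEGs);
6. the intersection of differentially methylated and expressed genes
   (DMEGs); and
7. the eQTM statistic: the Pearson correlation between a region's mean
   Beta and its gene's log expression over the samples shared between
   assays, with percentile-bootstrap confidence intervals and a
   permutation p-value from CpG-count-matched null regions.

A synthetic-cohort generator with planted ground truth makes every stage
testable without patient data; nothing in this package downloads or
bundles study data.

## The methylation model

Methylation fractions (Beta values, in (0,1)) are modelled on the M scale,
$M = \log_2(\beta / (1 - \beta))$, which is unbounded and closer to
homoscedastic; Beta values are clipped to $[\epsilon, 1-\epsilon]$
(default $\epsilon = 10^{-6}$, chosen so that only exact 0/1 values are
affected) before the transform. Effect sizes for reporting
(`delta_beta`) stay on the Beta scale, where they read as methylation
percentage differences.

Per probe, M is regressed on the group contrast plus covariates
(passage number, age, sex, and medication use -- the four drug indicators
azathioprine, purinethol, adalimumab, infliximab). Two design
degeneracies are handled explicitly:

* covariate columns that are constant in the analyzed subset are dropped
  with a message;
* drug indicators that are collinear with the rest of the design (the
  typical case: controls are unmedicated, so per-drug columns align with
  a CD-vs-control contrast) are collapsed into a single any-medication
  indicator. If the design is still rank deficient the fit aborts and
  names the offending columns rather than silently dropping them.

**Patient blocking.** Repeated samples from one patient violate
independence. We model a single intra-patient residual correlation
$\rho$, shared across probes: a first OLS pass yields residuals; for each
probe, the mean cross-product of residuals over same-patient sample
pairs, scaled by the residual variance and by $n/(n-p)$ to undo the
attenuation introduced by fitting $p$ coefficients, gives a per-probe
moment estimate; these are pooled by a Fisher-z mean across probes, and
the model is refit by generalized least squares under the implied
block-equicorrelation covariance. $\hat\rho$ outside $(-0.3, 0.99)$ is
clipped with a warning -- strongly negative pooled values indicate a
misspecified sheet rather than real anticorrelation.

**Variance moderation.** Residual variances are shrunk toward a common
prior by the standard scaled-inverse-chi-square empirical-Bayes scheme,
with the prior degrees of freedom and scale estimated by method of
moments on the log variances (trigamma inversion by Newton's method).
With fewer than 50 probes the moment fit is unreliable and the ordinary
t-test is used. On unblocked data this reproduces limma's moderated t to
within numerical noise, which the test suite checks as an independent
cross-check; the in-package implementation exists so that blocking,
moderation, and the region statistic form one auditable path.

## Region calling

A region is seeded by CpGs whose per-CpG significance passes
`seed_alpha` (default 0.05). Successive seeds on one chromosome within
`max_gap_bp` (default 1000 bp, matched to the default mean inter-probe
spacing of 500 bp) form a candidate; probes lying between the first and
last seed join as members; candidates with fewer than `min_cpgs = 3`
member CpGs are discarded. The region statistic combines signed per-CpG
z-scores, $z_i = \mathrm{sign}(\Delta M_i)\,\Phi^{-1}(1 - p_i/2)$, as
$Z = \sum_i z_i / \sqrt{n}$, so CpGs moving in opposite directions cancel
instead of reinforcing. Two-sided region p-values are BH-adjusted across
regions and called at 0.05.

Two open choices were resolved as follows:

* **Seed scale.** `seed_on` controls whether `seed_alpha` applies to the
  BH-adjusted per-CpG p (default) or the raw p. Seeding on the raw p
  admits chance same-direction triples whose combined Stouffer statistic
  then survives region-level BH -- in our planted-region simulations this
  inflates the region-level false discovery rate to roughly 0.15, versus
  0 with adjusted-p seeding at unchanged sensitivity (0.98). The default
  therefore seeds on the adjusted p, which also matches FDR-based
  candidate selection in kernel-smoothing region callers. Kernel
  smoothing itself (bandwidth machinery and all) is deliberately out of
  scope: the decision rule implemented here is the stated one -- at
  least 3 CpGs, Stouffer-combined, BH below 0.05.
* **Annotation.** Each region is annotated to the gene whose TSS is
  nearest the region midpoint (distance 0 if the TSS falls inside the
  region); midpoint ties break to the lexicographically smallest gene id
  so annotation is deterministic.

## Differential expression

Genes with CPM below 1 in more than `max_below` samples are removed
(default `floor(n/2)`, i.e. 11-of-21 under the emulated design, read as
"strictly more than": a gene below threshold in exactly `max_below`
samples is retained). Size factors use the median-of-ratios estimator
computed in log space; an optional fixed geometric-mean reference makes
the estimator exactly equivariant to scaling one sample. The
negative-binomial Wald fit (gene-wise dispersion shrunk toward a
mean-dispersion trend, size factors as offsets) is delegated to the
DESeq2 engine behind this package's interface; covariates are
standardized before entering the design. Genes whose coefficient fit does
not converge are flagged, receive a missing p, and are excluded from the
BH adjustment, whose count is reported. No independent filtering and no
fold-change shrinkage are applied: the decision surface is the plain
Wald p / BH schema.

For integration, log expression is defined as
$\log_2(\mathrm{count}/\mathrm{size\ factor} + 1)$; the +1 guards zeros
and the base is configurable. Normalized rather than raw counts are the
default because the correlation target is biological, not depth-driven.

## The eQTM statistic

For each DMR-gene pair in the DMEG intersection:

* the region's **mean Beta** per sample is the unweighted mean over
  member probes;
* the **correlation** `r` is Pearson's, over exactly the samples shared
  between assays (9 in the emulated design); at least 3 shared samples
  and nonzero variance on both sides are required -- degenerate inputs
  raise errors rather than returning silent zeros;
* the **confidence interval** is the percentile bootstrap (default
  B = 10000): resample paired samples with replacement, recompute r,
  take the empirical 2.5%/97.5% quantiles. Degenerate resamples (zero
  variance) are redrawn, with the redraw count reported and a hard stop
  past 10B redraws. Percentile was chosen over BCa as the simplest
  method consistent with a plain "B bootstraps" description; with n = 9
  any bootstrap is approximate, and the permutation p below carries the
  inferential weight. Percentile bounds need not bracket the point
  estimate in pathological resamples; such rows are flagged
  (`ci_excludes_r`), not repaired.
* the **permutation p-value** compares `|r|` against null regions drawn
  uniformly among all runs of exactly the same number of consecutive
  probes in the filtered manifest (the observed region's own run is
  excluded; configurable). Contiguous probe runs, rather than arbitrary
  coordinate windows, match both the CpG count and the local correlation
  structure of real regions. Runs are drawn without replacement when the
  pool is large enough, with replacement otherwise, and
  $p = (1 + \#\{|r_\mathrm{null}| \ge |r_\mathrm{obs}|\})/(B + 1)$, the
  add-one rule keeping p in $[1/(B+1), 1]$. The two-sided (absolute
  value) convention is used because the direction of a
  methylation-expression association is not specified a priori.

Because each pair's null is conditioned on its own CpG count, permutation
p-values are not monotone in |r| across pairs with different region
sizes; this is expected behaviour, not a defect.

The pairwise co-expression screen is plain Pearson correlation among a
gene set with |r| > 0.7 pairs flagged; constant genes are dropped with a
warning.

## Age and sex imputation

For samples missing metadata, age is predicted by a linear
epigenetic-clock combination of CpG Beta values followed by the
piecewise anti-log transform: predictor $s \le 0$ maps to
$(1+a)\,e^s - 1$ and $s > 0$ to $(1+a)\,s + a$, with adult age $a = 20$.
Clock coefficients are user-supplied (TSV of probe and weight) rather
than bundled; tests use small synthetic clocks built in code. Missing
clock probes are mean-imputed, with a hard failure below 50% presence.
Clock CpGs can be excluded from the manifest afterwards so age-related
probes cannot confound the group comparisons.

Sex is inferred twice and cross-checked: from methylation, a sample is
called male when more than half of the chromosome-Y probes show signal
within an informative Beta band (default [0.2, 0.8]; females show only
background at chrY after mixed-sex normalization) -- the band is a
documented operational choice, since no universal detection criterion
exists at this stage of processing; and from expression, when at least 2
chromosome-Y genes exceed 1 CPM.

## The synthetic cohort generator

The generator emulates the structure of the emulated study, and its
defaults are the study conditions:

* **Design.** 18 methylation samples from 10 patients (7 NINF/4, 2
  INF/2, 4 STEN/3, 5 non-CD/3) and 21 expression samples from 14
  patients (6 NINF/6, 4 INF/4, 5 STEN/4, 6 non-CD/4), with 9 samples
  from 6 unique patients on both assays. The marginal counts do not
  fully determine which patients span groups and assays; one consistent
  allocation was chosen and frozen in `cohort_design()`. Ages are drawn
  around the reported cohort means (CD younger than non-CD), medication
  is restricted to CD patients, and passage runs 1-5.
* **Methylation.** Per-probe baselines follow a two-component
  logit-normal mixture with modes near Beta 0.1 and 0.9 (array
  bimodality); per-sample noise is Gaussian on the logit scale (sd 0.3).
  Planted regional effects add `delta_beta` on the Beta scale for the
  target group's samples and clip back into (0,1) -- near-saturated
  probes therefore realize less than the nominal shift, as on a real
  array.
* **Expression.** Counts are negative binomial with
  $\mathrm{Var} = \mu + \alpha\mu^2$ (default $\alpha = 0.1$), gene
  means log-normal, per-sample size factors log-normal (log-sd 0.3),
  and planted fold changes multiplying the target group's mean, matching
  the downstream model family.
* **Coupling.** A planted eQTM rotates the gene's log counts toward the
  region's standardized per-sample mean-Beta signal so that the realized
  correlation equals `target_r` exactly on the log scale (integer
  rounding perturbs it slightly); the rotation preserves the
  log-expression variance, so planted couplings do not inflate
  dispersion estimates. When the region carries no sample-level
  variation, a standard-normal latent is first injected on the logit
  scale. With zero noise and $|r| < 1$ the construction necessarily
  overshoots to $|r| = 1$ -- a documented degenerate corner.
* **Probe spacing.** Exponential inter-probe gaps (mean 500 bp) make
  gap-based clustering meaningful.

What the generator does *not* emulate: probe chemistry (type I/II),
chip/batch effects, detection-p failures, cell-type mixture, and count
overdispersion trends that vary with mean beyond the single-parameter NB.
Passing tests therefore demonstrate correctness of the statistical
machinery under a faithful but idealized data model, not robustness to
array artefacts.

## Verification, problem sizes, and numerical choices

The test suite and `scripts/acceptance.R` verify, among others (sizes
are the package's chosen simulation scales):

* closed-form oracles: Stouffer $z\sqrt{k}$; BH against a brute-force
  $\min_{j \ge i} p_{(j)} m / j$ oracle on 100 random vectors; CPM
  column sums; exact size-factor equivariance;
* an exhaustive permutation oracle on a 6-probe manifest (all 4 runs of
  3 CpGs) against sampling at B = 10000;
* null calibration at 2000 probes/genes, 10 vs 10: DMP and DEG type-I
  error within [0.03, 0.07]; KS uniformity of 200 uncoupled eQTM
  permutation p-values at B = 1000;
* recovery: planted regions ($\Delta\beta = 0.15$, 8 CpGs, 10 vs 10, 20
  seeds) at sensitivity $\ge$ 0.8 and region FDR $\le$ 0.1; planted
  fold changes ($|\mathrm{lfc}| = 1$, mean over 20 genes) within
  $\pm 0.2$; coupling sign recovery ($r = -0.8$, 9 shared samples) in
  $\ge$ 95 of 100 seeds;
* percentile-bootstrap coverage for true r = 0.5 at n = 50 within
  95% $\pm$ 5% over 500 replicates at B = 2000;
* exact round trips of the Beta/M and clock-age transforms.

Numerical details worth knowing: p-values are floored at the smallest
positive double so downstream $-\log_{10}$ scores stay finite; signed
z-scores cap p at $10^{-300}$ before inversion; Stouffer regions of
perfectly cancelling CpGs return $Z = 0$, p = 1; BED exports are 0-based
half-open while all tabular coordinates are 1-based inclusive with a
hyphen (the parser also accepts an en-dash); and every stochastic
function takes an explicit seed, with full-pipeline byte-identical
reruns under a fixed configuration.

## Limitations

The DMP/DMR engine assumes a common intra-patient correlation across
probes and an equicorrelated within-patient structure; it does not fit
per-probe random effects. The DMR caller does not reproduce
kernel-smoothing internals, so region boundaries can differ from
kernel-based callers even when the same regions are found. The eQTM
permutation null conditions on CpG count and manifest geometry but not
on methylation variance strata. The paper-scale results (tens of
thousands of DMPs from patient data) are not reproducible from this
package alone, by design: the package ships the machinery and its
verification, not the cohort.
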