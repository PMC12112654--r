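---
title: "Variance-component models for endophenotype-informed linkage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variance-component models for endophenotype-informed linkage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famerv)
```

## The problem

Large family studies localize genes for complex quantitative traits — here
the motivating case is liver fat content in metabolic dysfunction-associated
steatotic liver disease — by combining three classical tools: heritability
estimation in pedigrees, genetic correlation with intermediate traits
("endophenotypes"), and variance-component QTL linkage followed by targeted
association under the linkage peaks. famerv implements this whole chain on
top of a pedigree kinship matrix, together with a gene-dropping simulator
that generates data with known truth, so every estimator in the chain can be
validated against the parameters that generated the data.

## The polygenic model

For a quantitative trait $y$ measured on $n$ pedigree members, the
univariate polygenic model is

$$ y = X\beta + a + e, \qquad
   a \sim \mathcal N(0,\, 2\Phi\,\sigma^2_g), \quad
   e \sim \mathcal N(0,\, I\,\sigma^2_e), $$

where $\Phi$ is the kinship matrix computed from parent links by the
standard recursion (founders $\phi_{ii}=1/2$; a non-founder $k$ with parents
$f, m$ has $\phi_{kk} = (1+\phi_{fm})/2$ and
$\phi_{kj} = (\phi_{fj}+\phi_{mj})/2$). Heritability is
$h^2 = \sigma^2_g/(\sigma^2_g+\sigma^2_e)$. The model is fitted by maximum
likelihood (ML, not REML, following the SOLAR lineage of family-study
software): fixed effects are profiled out by generalized least squares at
every likelihood evaluation, so the optimizer works on the variance
parameters alone. Because kinship is exactly zero across families, the
likelihood factorizes over family blocks.

Significance of $h^2$ comes from a likelihood-ratio test against
$\sigma^2_g = 0$. The null pins a variance on its boundary, so the statistic
follows the $\tfrac12\chi^2_0 : \tfrac12\chi^2_1$ mixture and
$p = \tfrac12 P(\chi^2_1 \ge \Lambda)$; $\Lambda = 0$ gives $p = 0.5$.

Standard errors come from the observed information, computed by central
finite differences of the profiled log-likelihood at the optimum and
propagated to $h^2$ by the delta method. Estimates on the boundary are
flagged and their SEs should be read as one-sided.

### Covariates

The default design is intercept, mean-centered age, sex (0/1), and the
age-by-sex interaction — the usual adjustment set for metabolic traits.
"Interactions" is interpreted as the single product term; no quadratic age
terms are included. Individuals with a missing trait or covariate are
dropped from the likelihood by case deletion, while their relatives keep the
correct kinship entries because $\Phi$ is computed once from the complete
pedigree and then subset.

### Trait transformations

Non-normal traits are handled before fitting, via a per-trait plan
(`none`, `log`, `inverse_normal`) given in configuration rather than
hard-coded. The rank-based inverse normal transform uses Blom offsets,
$\Phi^{-1}\!\big((r - 3/8)/(n + 1/4)\big)$, with average ranks for ties;
van der Waerden offsets are available as an option. The choice of offset is
a convention — published analyses rarely name one — and it does not affect
ranks, so downstream tests change only marginally.

## Bivariate model, genetic correlation, and the ERV

Two traits are modeled jointly with covariance
$\Sigma_g \otimes 2\Phi + \Sigma_e \otimes I$, where the $2\times2$ blocks
are parameterized by per-trait variances and the correlations $\rho_g$ and
$\rho_e$, each constrained to $[-1, 1]$ so the implied covariance stays
positive semi-definite. With $\rho_g = \rho_e = 0$ the likelihood is exactly
the sum of the two univariate likelihoods — a factorization the test suite
checks to $10^{-6}$.

Candidate endophenotypes are ranked by the endophenotype ranking value

$$ \mathrm{ERV} = \big|\sqrt{h^2_i}\,\sqrt{h^2_e}\,\rho_g\big| \in [0, 1], $$

whose significance is the likelihood-ratio test of $\rho_g = 0$. Zero is
interior to the parameter space, so this is a plain 1-df $\chi^2$ test (no
boundary mixture), and the ERV p-value is identical to the genetic
correlation's by construction.

Selection for bivariate linkage takes the top-ranked endophenotype per trait
class, subject to two filters: a significance floor on the ERV p-value
(default 0.05) and a rank floor (`max_rank`) that drops classes whose best
candidate sits near the bottom of the overall ranking — a class with no
competitive candidate contributes no useful pleiotropic signal even when
nominally significant. Redundant candidates (e.g. an insulin measure that is
a component of an insulin-resistance index) are handled by class membership:
only one winner per class is taken, and an explicit exclusion list is
available. The index-trait $h^2$ used inside each ERV defaults to the
bivariate fit's own estimate; `index_h2` switches to an external (e.g.
univariate) estimate.

## QTL linkage

At a locus with IBD-sharing matrix $\hat\Pi$ the univariate linkage model
adds a QTL variance component,

$$ \Omega = 2\Phi\,\sigma^2_g + \hat\Pi\,\sigma^2_q + I\,\sigma^2_e, $$

and $\mathrm{LOD} = (\ell_{\mathrm{alt}} - \ell_{\mathrm{null}})/\ln 10$,
clamped at zero. The nominal p-value uses the same one-half chi-square rule
as the heritability test: $p = \tfrac12 P(\chi^2_1 \ge 2\ln 10\,
\mathrm{LOD})$. The bivariate linkage model adds
$\Sigma_q \otimes \hat\Pi$ (two QTL variances and a freely estimated QTL
correlation $\rho_q$); its LRT is referred to a
$\tfrac14\chi^2_0 : \tfrac12\chi^2_1 : \tfrac14\chi^2_2$ mixture by default
— the asymptotics with an estimated $\rho_q$ are approximate, so the
weights are configurable — and the resulting p-value is converted back to a
1-df-equivalent LOD so univariate and bivariate scores share a scale. The
p-to-LOD conversion is mixture-independent and exactly inverts the
univariate rule.

Scans evaluate every 5 cM and refine to 1 cM across any contiguous region
whose coarse LOD exceeds 0.5, including the flanking coarse intervals. IBD
matrices at fine positions come from the simulator's descent ground truth;
positions a provider cannot serve are skipped with a warning rather than
interpolated (multipoint IBD estimation from marker genotypes is out of
scope). Peaks at or above LOD 2.87 are called significant and at 1.67
suggestive — these defaults reproduce a published Feingold-style
genome-wide adjustment — and each peak carries its $-1$-LOD support
interval: the maximal contiguous region with LOD $\ge$ peak $- 1$, clipped
at chromosome ends. `genomewide_threshold()` exposes the underlying
Ornstein-Uhlenbeck upcrossing approximation
$\alpha \approx (C + 2\rho G t^{*})\cdot\tfrac12 P(\chi^2_1 \ge t^{*})$
with the genome length, chromosome count and correlation decay rate as
inputs, because the exact parameter values behind any particular published
threshold are rarely printed; with plausible settings ($C=23$, $G=35$ M,
$\rho=0.55$, $\alpha=0.05$) the solved threshold falls near 2.9.

"Improvement in localization" from pairing the index trait with an
endophenotype is operationalized as: the bivariate LOD-equivalent strictly
exceeds both univariate LODs at the position. A bivariate peak that merely
shadows one trait's univariate peak is not an improvement.

## Measured-genotype association

Within the $-1$-LOD window of each significant or suggestive peak, every
SNP enters the variance-component model as a fixed 0/1/2 dosage covariate
and is tested by likelihood ratio against the no-dosage null refitted on
the same individuals (1 df for one trait; for a trait pair the dosage enters
both means and the test has 2 df — the published convention does not state
the df, so this is a documented package decision). The LRT is the default;
a Wald test is available behind a flag. Controlling relatedness through the
kinship matrix is the point of the exercise: the test suite shows that a
naive no-kinship regression on the same family data inflates the type-I
error while the variance-component test stays nominal.

Significance is two-tier: a marginal threshold $p \le 10^{-4}$ and a
region-wise Bonferroni threshold $\alpha/n_{\mathrm{SNPs}}$, reported after
rounding down to one significant figure (3500 SNPs $\to 10^{-5}$, 9500
$\to 5\times10^{-6}$). A p-value exactly on the rounded Bonferroni
threshold tiers as marginal, not region-significant, matching how such
boundary hits are conventionally reported; `bonferroni_strict = FALSE`
switches to inclusive comparison. Minor allele frequencies are simple
allele counts over genotyped individuals, descriptive only.

## The synthetic family study

The simulator is first-class, tested code, and its defaults are the study
conditions every calibration claim refers to:

* **Pedigrees** — 104 families drawn from a template mixture (30%
  singletons, 45% nuclear with 1-4 children, 17% three-generation, 8%
  extended, capped at 58 members) tuned to give median family size 3 and
  mean near 7. Pedigrees are non-inbred by construction, although the data
  structures and the kinship recursion handle inbreeding.
* **Genotypes** — gene dropping: founders carry uniquely labelled alleles;
  each meiosis draws a grandparental origin per chromosome and switches
  between adjacent loci with the Haldane fraction
  $\theta = (1 - e^{-2d/100})/2$ (no interference). Allelic states are
  assigned to founder alleles by per-locus MAF from a spectrum spanning
  0.006-0.5.
* **IBD** — exact, from the descent labels:
  $\hat\pi_{ij} = (\text{IBD allele pairs})/2$. This replaces multipoint
  IBD estimation, which is deliberately out of scope.
* **Phenotypes** — $y = X\beta + a + q + e$ with total variance 1 per
  trait before covariate effects; $h^2$ configurable (the tested range is
  0.25-0.67), bivariate $\rho_g$ up to 0.85, and an optional pleiotropic
  QTL whose dosage effect is scaled to a configured variance fraction. The
  QTL acts through an actual dosage, so both linkage (via IBD) and MGA (via
  the dosage) can recover the same signal — mirroring the two-stage
  localization logic. Age is Uniform(18, 80) and sex Bernoulli(1/2):
  covariate recovery needs variation, not demographic realism.

With the seed fixed the full chain (pedigree, descent, phenotypes) is
bit-reproducible.

What the simulator does *not* emulate: ascertainment of families through
probands, linkage disequilibrium beyond two-locus recombination on the
drop map, genotyping error and missingness mechanisms, non-normal trait
distributions (transforms are exercised on already-normal simulated
traits), and household/shared-environment covariance (the model fits none,
matching the analysis it implements). Passing calibration on synthetic data
therefore demonstrates correctness of the estimators under the stated
model, not robustness to these real-data features.

## Numerical choices

* Likelihood evaluations without a QTL kernel use a family-wise
  eigendecomposition of $2\Phi$ (it commutes with $I$), reducing each
  evaluation to diagonal or $2\times2$-block algebra; with $\hat\Pi$
  present, each family block is Cholesky-factorized per evaluation.
* Optimization is L-BFGS-B on the variance parameters with the trait
  standardized to unit variance internally (estimates are invariant to
  affine rescaling; results are mapped back to the data scale). Variances
  are bounded below by 0 (residual variance by $10^{-9}$) and correlations
  to $[-0.999, 0.999]$; convergence tolerance is `factr = 1e7`
  (about $10^{-9}$ relative).
* Multi-start is deterministic: heritability fractions 0.45/0.15/0.75.
  Linkage fits warm-start from their nested null's estimates with a small
  QTL variance; if the warm-started optimum falls below the null — a
  nesting violation that can only be optimizer failure — the fit is
  retried from the full start set. LOD scores are clamped at zero.
* Degenerate inputs are handled explicitly: a pedigree with no
  within-family kin covariance pins $\sigma^2_g$ at its boundary with a
  warning (heritability is unidentifiable); a locus IBD matrix equal to
  $2\Phi$ triggers a confounding warning and an uninformative LOD;
  monomorphic variants return $p = 1$ with a flag.

## Problem sizes used in validation

The shipped test suite validates the estimators at these scales, chosen as
the smallest runs that make the Monte-Carlo bands meaningful: heritability
recovery at $h^2 \in \{0.25, 0.5, 0.67\}$ with 200 phenotype replicates on
a fixed 104-family pedigree (acceptance band: 2 Monte-Carlo SEs, with the
reported SEs checked against the replicate spread); genetic-correlation
recovery at $\rho_g = 0.85$ with 100 replicates; null calibration of the
linkage LOD with 1000 replicates on a 60-family sibship design (the
$P(\mathrm{LOD} \ge 0.588) \approx 5\%$ check and a Kolmogorov-Smirnov
test of the positive part of the LRT against $\chi^2_1$), heritability-LRT
type-I error with 400 replicates, and MGA type-I error with 300 replicates
against a naive no-kinship regression on the same data. Oracle checks use
an exhaustive likelihood grid (replicated three-member pedigrees),
$10^5$ Monte-Carlo gene drops for kinship, and allele-by-allele brute force
for IBD on small families. The end-to-end pipeline test runs a reduced map
(two chromosomes, 25 cM at 5 cM steps, 30 families) twice to verify
bit-identical manifests.

## Known limitations

* No household or dominance components; no ascertainment correction.
* Bivariate fits use complete cases on the trait pair.
* The bivariate linkage null mixture is an approximation when $\rho_q$ is
  estimated; the printed-scale conversion between p and LOD-equivalent is
  exact regardless.
* Relationship classification assumes each pair's joint ancestry is
  loop-free apart from the connections themselves; pairs involving inbred
  ancestry fall back to the kinship-derived degree with label "other".
* MAF is a descriptive allele count, not a pedigree-aware ML estimate.
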