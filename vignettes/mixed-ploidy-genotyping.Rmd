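---
title: "Mixed-ploidy genotyping from read counts: models, conventions and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixed-ploidy genotyping from read counts: models, conventions and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radosage)
```

This vignette is the package's own account of the statistical machinery:
what is modelled, which conventions were fixed where several were
defensible, and what the simulation-based checks do and do not establish
about real data.

## Ploidy from allelic ratios

At a heterozygous biallelic site in an individual with $k$ haploid
chromosome sets, the expected fraction of reads carrying the focal allele
is $p \in \{1/k, \dots, (k-1)/k\}$. Real read-count ratios are
overdispersed relative to the binomial — library preparation and PCR
introduce locus-specific biases — so the count $x_l$ out of $n_l$ reads is
modelled as beta-binomial with expectation $p$ and intraclass correlation
$\rho$ ($\alpha = p(1-\rho)/\rho$, $\beta = (1-p)(1-\rho)/\rho$); $\rho$
controls how far the per-locus mean wanders around $p$. Ratios are
*censored* to the inclusive window $[0.1, 0.9]$, and each density is
renormalized over that support, because apparent heterozygotes with
extreme ratios are usually mistyped homozygotes. The per-individual
log-likelihood is a mixture over the grid,

$$L = \sum_l \log \Big( \sum_p m_p\, \beta b(x_l, n_l, p, \rho) \Big),$$

maximized over the weights $m$ and the single shared $\rho$, and candidate
ploidies are compared by $\mathrm{AIC} = 2k_{\text{par}} - 2L$ with
$k_{\text{par}} = (|\text{grid}|-1) + 1$.

Conventions fixed here, with reasons:

* **Censor bounds inclusive.** A ratio of exactly 0.1 (e.g. 3/30) is
  retained. Inclusive bounds are the simpler contract; at realistic
  coverages the boundary atom is negligible either way.
* **Focal allele = second-listed observed allele.** With the symmetric
  grid $\{1/k,\dots,(k-1)/k\}$ the choice of focal allele only relabels
  mixture components, so no folding at 0.5 is applied.
* **Heterozygosity screen.** A site enters if exactly two alleles carry at
  least one read; three or more observed alleles exclude the site from
  ratio collection (the mixture is defined for biallelic configurations).
  The censoring window then removes likely mistyped homozygotes.
* **One $\rho$ per individual**, shared across mixture components;
  per-component overdispersion is not identifiable at the typical number
  of usable sites and is not supported.
* **Optimization.** Weights are parameterized by softmax (first logit
  fixed), $\rho$ by logit; five starts at $\rho_0 \in \{0.005, 0.02, 0.05,
  0.1, 0.2\}$ with uniform weights, Nelder–Mead (Brent for the diploid's
  single parameter), relative tolerance $10^{-8}$. The $\rho$ confidence
  interval comes from the observed information at the optimum through the
  logit transform.
* **Minimum evidence.** Classification needs 50 usable ratio observations;
  below that the sample is reported `undetermined` rather than guessed —
  samples with few variable sites are exactly the ones where AIC
  comparisons mislead.
* **Ties toward lower ploidy** (within $10^{-9}$ of the minimum AIC): the
  lower-dimensional model is the conservative claim.

The censored beta-binomial itself is evaluated by a multiplicative pmf
recurrence accumulated in log space (one `lbeta` call per $(n, p)$), which
keeps the mixture likelihood cheap enough for multi-start fitting over
thousands of sites; the hot loop is compiled (Rcpp). The exported
`censored_betabinom_logpmf()` is an independent pure-R path
(`lchoose` + `lbeta` + log-sum-exp) and the two are cross-checked in the
tests, alongside a numeric-integration oracle.

## Dosage genotyping

For a sample of known ploidy $n$, the dosage models are the integer
partitions of $n$ (zero-padded, descending): `2:0`, `1:1` for diploids;
`4:0:0:0` … `1:1:1:1` for tetraploids. Counts are sorted descending with
their mean phred qualities, truncated to the $n$ most frequent alleles,
and scored as $L = L_1 \cdot L_2$: a multinomial term over the alleles the
model expects (category probabilities $m_s/n$) times an error term
$p^{x}$, $p = 10^{-q/10}$, for reads the model does not expect. All math
is in natural-log space via `lgamma`.

Choices the underlying formulation leaves open, fixed as follows:

* **BIC convention.** $\mathrm{BIC} = k_{\text{model}} \ln N - 2\log L$
  with $N$ = total reads at the locus and $k_{\text{model}}$ = number of
  distinct alleles in the model. This penalizes allele-rich models, which
  is the relevant complexity axis here.
* **Tie-breaks.** Equal BIC → fewer distinct alleles, then the larger
  leading dosage: conservative against overcalling heterozygosity. Count
  ties during sorting break by allele label order, so calls are
  deterministic.
* **Coverage window inclusive**: $[5n, 200]$ — 10–200 for diploids,
  20–200 for tetraploids; 200 is kept, 201 is not.
* **Per-allele quality** is the arithmetic mean phred of the supporting
  reads, converted once ($p = 10^{-q/10}$), not an average of per-read
  error probabilities.
* If the minimum-BIC model expects more distinct alleles than were
  observed at all, copy numbers cannot be attached to labels and the call
  is returned `ambiguous` (in practice such models lose to simpler ones).

## The filtering cascade

Sample- and locus-level filters run in a fixed, recorded order: variant
type (SNVs and single-base deletions only) and the raw-read floor
(strictly fewer than one million reads excludes a sample) act upstream of
genotyping; per-locus coverage windows act inside the genotyper; then
locus presence (≥ 80% of samples, inclusive) → sample missingness
(> 50% missing, strict, computed on the well-covered locus set) → locus
presence re-applied to the reduced sample set → monomorphic-locus removal.
The presence filter is re-applied because removing high-missingness
samples changes both locus presence and which loci remain polymorphic;
every stage emits a `filter_report`, each filter is idempotent, and
dropped + kept = input throughout.

## Population summaries

**Frequencies.** Genotypes become within-individual allele frequencies,
copy number over ploidy, at biallelic loci (the counted allele is the
second in sort order); values are exact rationals of the ploidy.

**F~ST~.** Two estimators are exposed. The default (`method = "nei"`) is
the ratio of averages $1 - \overline{H_S}/\overline{H_T}$ with $H_T$ from
the pooled mean frequency. It is the textbook definition, but with few
groups it is *structurally* biased toward zero as an estimator of a
divergence parameter $F$: with two demes of Balding–Nichols divergence
$F$, $E[H_S] \approx 2q(1-q)(1-F)$ while the pooled-frequency
$E[H_T] \approx 2q(1-q)(1-F/2)$, so the ratio converges to
$(F/2)/(1-F/2) \approx 0.053$ at $F = 0.1$, not $F$. The
sample-size-corrected two-group estimator (`method = "hudson"`;
$\sum_l N_l / \sum_l D_l$ with the $p(1-p)/(n-1)$ correction) is
approximately unbiased for $F$ and is what the package's own
Balding–Nichols recovery checks use. Per-locus values are reported raw
(small negatives possible; `NaN` where $H_T = 0$); an outlier screen can
be taken as values above the 99th percentile of the per-locus
distribution.

**PCA** is a column-centered SVD on the (imputed) frequency matrix;
scores are deterministic up to sign, fixed by making the
largest-magnitude loading of each component positive. **Imputation**
offers per-locus means and an iterative low-rank alternative (rank-2 by
default) that alternates truncated-SVD reconstruction with re-imputation
until the largest change falls below $10^{-6}$ (≤ 100 iterations),
clamped to the unit interval. Mean imputation shrinks structure; the
low-rank method preserves cluster geometry better and is validated by
self-masking in the tests.

**Cline regression.** Admixture proportions $Q$ are variance-stabilized
as $\arcsin\sqrt{Q}$ (the standard form) and fitted with
`lmer(y ~ latitude + (1 | population))` by REML; the population random
intercept absorbs drift of whole populations away from the trend. The
slope p-value is a Wald test against the normal reference — approximate,
but adequate at the design sizes used here (confirmed by the null
false-positive check below). STRUCTURE itself is not run; its Q-output is
consumed, and its input is exported with every individual on four rows
(diploids fill two rows, the rest carry −9) so mixed-ploidy data sets can
be analysed jointly.

## The simulator, and what passing tests mean

`simulate_individual()` / `simulate_cohort()` generate the inputs every
check runs on: per-locus population frequencies uniform on (0.05, 0.95),
Hardy–Weinberg-like binomial dosage sampling at the given ploidy, coverage
from a negative binomial with mean 60 and dispersion 5 (truncated to
≥ 1, mirroring RAD coverage skew), focal-allele counts beta-binomial with
$\rho = 0.02$, and per-read miscalls at rate 0.005 assigned to a uniformly
random base outside the true genotype, with phreds set to
$-10\log_{10}(\text{error rate})$. Optional features: conditioning on
heterozygosity (to produce a fixed number of ratio observations),
two-deme Balding–Nichols divergence, planted tri-/tetra-allelic loci
(these use multinomial read sampling without beta overdispersion), and a
latitudinal admixture gradient generator for the cline model. Everything
is seed-deterministic down to bytes on disk.

Canonical problem sizes used by the recovery checks: 30 individuals per
ploidy class {2, 3, 4} with 2000 heterozygous sites each for ploidy
classification (accuracy ≥ 95% required); ten samples × 400 loci per
ploidy for dosage recovery (≥ 99% diploid at 30×, ≥ 90% tetraploid full
dosage at 60×, with errors concentrated in 3:1 vs 2:2); 2 × 50 diploids at
2000 loci for the $F = 0.1$ Balding–Nichols recovery (±0.02); 20
populations × 6 individuals for the cline, with 50 null replicates
bounding the false-positive rate at 10%.

What these do **not** show: the simulator draws independent loci (no
linkage), unbiased read sampling (no reference/mapping bias, no allelic
dropout at restriction sites), a single shared $\rho$ and error rate, and
Hardy–Weinberg genotype proportions. Real RAD data violate all four to
varying degrees; the recovery rates above are therefore best-case
calibrations of the *method*, not guarantees for any particular data set.
Two further limits: ploidy classification needs enough usable
heterozygous sites (samples below 50 are deliberately `undetermined`, and
individuals with unusually few variable sites are the classic
misclassification risk), and the VCF reader loads files in memory via
`vcfR`, which is comfortable at RAD scale (hundreds of samples × ~10⁵
sites) but not for whole-genome cohort VCFs.

## Numerical notes

* Beta-binomial pmfs are built by ratio recurrence in log space; densities
  renormalize over the censored support to 1 within $10^{-10}$ across the
  tested $(n, p, \rho)$ grid.
* Observations in the far tail of every mixture component are floored at
  the smallest representable log-density rather than returning $-\infty$,
  keeping the optimizer on its feet.
* Genotype likelihoods use `lgamma`; the brute-force oracle in the tests
  deliberately uses direct `factorial()` arithmetic instead (exact in
  double precision at coverage ≤ 60), and the two selection paths agree on
  100% of 10 000 randomized records.
* `rho` is clamped to $[10^{-9}, 1-10^{-9}]$ inside the optimizer; the
  degenerate binomial limit is covered by tests at $\rho = 10^{-8}$.
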