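# radosage

Ploidy inference and allele-dosage genotyping from RAD-seq read counts,
for mixed-ploidy population samples.

## The problem

Reduced-representation sequencing (RAD-seq) of natural populations that mix
diploids with polyploids — for example diploid and allotetraploid trees in a
hybrid zone — poses two linked genotyping problems that standard diploid
callers do not solve:

1. **Which ploidy is each individual?** In a polyploid with *k* haploid
   chromosome sets, the expected fraction of reads carrying one allele at a
   heterozygous site lies on the grid *p* ∈ {1/k, …, (k−1)/k}: a diploid
   has a single peak at 0.50, a triploid peaks near 0.33 and 0.66, a
   tetraploid near 0.25, 0.50 and 0.75.
2. **Which allele dosage is each genotype?** In a tetraploid, two observed
   alleles are consistent with AAAT, AATT and ATTT; read counts must
   disambiguate the copy numbers.

`radosage` implements both, plus the surrounding filtering cascade,
population summaries (ploidy-normalized allele frequencies, F<sub>ST</sub>,
PCA, latitudinal cline regression on admixture proportions), mixed-ploidy
STRUCTURE export, and a fully seeded synthetic read-count generator used as
ground truth for recovery testing.

## Models

**Ploidy inference.** Allele-ratio observations (x<sub>l</sub>,
n<sub>l</sub>) at heterozygous sites with ≥ 30× coverage, censored to the
inclusive window [0.1, 0.9] to exclude mistyped homozygotes, are scored
under a mixture of censored beta-binomial densities:

    L = Σ_l log( Σ_p m_p · βb(x_l, n_l, p, ρ) )

with mixture weights m<sub>p</sub> over the grid {1/k, …, (k−1)/k}, a
single overdispersion (intraclass correlation) ρ shared across components,
and each density renormalized over the censored support. The model is
maximized per candidate ploidy (multi-start, simplex/logit transforms) and
candidates are compared by AIC = 2k − 2logL; ties go to the lower ploidy.

**Dosage genotyping.** For a sample of ploidy *n*, every dosage model
m (integer partition of *n*, e.g. 3:1:0:0) is scored on the
descending-sorted counts x with matched mean phred qualities q:

    L1 = (Σ_s x_s)! / Π_s x_s! · Π_s (m_s/n)^{x_s}      (expected alleles)
    L2 = Π_{s̄} p_{s̄}^{x_{s̄}},  p = 10^(−q/10)            (unexpected reads)
    L  = L1 · L2

computed in log space. Loci need ≥ 5 reads per ploidy level and ≤ 200
reads. The call minimizes BIC = k<sub>model</sub>·ln N − 2 logL with N the
locus read total and k<sub>model</sub> the number of distinct alleles in
the model; BIC ties resolve toward fewer alleles, then the more homozygous
model.

## Worked example

Simulate a small mixed cohort (4 diploids + 4 tetraploids, 2000 loci),
infer ploidy for one sample, call dosages, filter, and summarize:

```r
library(radosage)

cfg <- sim_config(n_samples = 4, ploidies = c(2, 4), n_loci = 2000, seed = 7)
sim <- simulate_cohort(cfg)

## ploidy of one tetraploid from its allele ratios
ratios <- heterozygous_ratios(subset(sim$counts, sample_id == "S005_k4"))
classify_ploidy(ratios)
#> ploidy classification: best k = 4
#>   k   loglik n_free_params     aic delta_aic
#> 1 2 -3178.53             1 6359.06   38.0935
#> 2 3 -3171.42             2 6346.83   25.8684
#> 3 4 -3157.48             3 6320.96    0.0000

## dosage genotypes at the known ploidies
calls <- lapply(split(sim$counts, sim$counts$sample_id),
                function(cs) genotype_sample(cs, sim$truth$ploidy[cs$sample_id[1]]))
gm <- build_genotype_matrix(calls, sim$truth$ploidy)
filtered <- apply_filter_cascade(gm, min_presence = 0.8, max_missing = 0.5)
filter_report_table(filtered$reports)
#>                stage items_in items_out n_dropped
#> 1     locus_presence     2000      1983        17
#> 2 sample_missingness        8         8         0
#> 3     locus_presence     1983      1983         0
#> 4        monomorphic     1983      1932        51

## ploidy-normalized frequencies and Fst between the ploidy classes
fm  <- freq_matrix(filtered$matrix)
grp <- setNames(ifelse(sim$truth$ploidy == 2, "diploid", "tetraploid"),
                names(sim$truth$ploidy))
fst(fm, grp)
#> [1] 0.04434

truth_compare(filtered$matrix, sim$truth)
#> truth comparison
#>  ploidy n_called n_missing  accuracy
#>       2     7709        19 0.9998703
#>       4     7491       237 0.9097584
```

The AIC table shows the tetraploid mixture clearly preferred (ΔAIC ≈ 38
over the diploid model); diploid genotypes are essentially always right,
while tetraploid full-dosage accuracy sits near 91% at this coverage, with
errors concentrated in the hard 3:1 / 2:2 distinction — the expected
behavior for count-based dosage calling.

A thin command-line wrapper over the same functions ships in
`inst/cli/radosage` (subcommands `simulate`, `ploidy`, `genotype`,
`filter`, `export-structure`, `convert`).

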