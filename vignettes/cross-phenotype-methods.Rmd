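---
title: "Comparing and contrasting GWAS of two diseases: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing and contrasting GWAS of two diseases: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crosspheno)
```

crosspheno asks a genetic question about a pair of related diseases — here
atopic dermatitis (AD) and psoriasis (PSO), two common inflammatory skin
disorders that almost never co-occur in one person: at each variant, is
the allelic effect specific to one disease, shared in the same direction,
or *opposing* (risk for one, protection for the other)? Three
complementary statistical routes answer it, each with different inputs
and assumptions, and the package adds the scaffolding around them:
quality control, allele harmonization, LD clumping, conditional
dissection of multi-signal regions, a synthetic data generator with known
truth, and a small epidemiological model that translates opposing loci
into the observed mutual exclusivity of the diseases.

## The CCMA statistic

The compare-and-contrast meta-analysis starts from two signed z-scores
per variant: `T1`, from a fixed-effects meta-analysis of the AD cohorts,
and `T2`, from the PSO cohorts, both oriented to the same effect allele.
From these it forms

* shared component: `(T1 + T2) / sqrt(2)`
* opposing component: `(T1 - T2) / sqrt(2)`

and takes `T_max`, the largest of the four absolute values, classifying
the variant by the arg-max. The `sqrt(2)` divisor is the only
normalisation under which the rotated components have unit variance when
`T1, T2` are independent standard normals; with a divisor of 2 the
shared and opposing categories could never attain the maximum (since
`|T1 + T2|/2 <= max(|T1|, |T2|)`), and the calibrated significance
thresholds would not reproduce. Independence of `T1` and `T2` under the
null is a design assumption — it requires non-overlapping control sets
between the two disease meta-analyses.

`T_max` is not normal, so p-values come from its own null. Two routes
are implemented and cross-check each other:

* `simulate_null()` draws pairs of standard normals (1e7 draws by
  default, chunked to bound memory) and records `Z_max`;
  `empirical_p()` applies the plus-one empirical formula
  `(#(Z_max > T_max) + 1)/(n + 1)`, whose smallest attainable value is
  `1/(n + 1)`.
* `analytic_tail_p()` integrates the bivariate standard normal over the
  complement of the acceptance region — a regular octagon with apothem
  `t` — reduced to a one-dimensional integral of small positive tail
  terms, which keeps full relative accuracy far below any target of
  interest. `calibrate()` root-finds on either curve.

The analytic route is the default for thresholds beyond the reach of an
empirical null (a `1e-8` target would need ~1e9 draws for a stable
quantile). At the conventional suggestive (`1e-5`) and genome-wide
(`1e-8`) targets the calibrated thresholds are `T_max ≈ 4.7` and
`≈ 6.0`. The genome-wide p-target is exposed as a parameter of
`calibrate()` rather than fixed, since reasonable analyses also use
`0.5e-8`.

## Bayesian partition meta-analysis

The second route pools all six cohorts — both diseases — in one Bayesian
model, in the style of transethnic partition meta-analysis. Studies are
clustered by a prior that prefers grouping *nearby* studies, with
distance

`D_Total = D_Disease + D_Ethnicity`

where `D_Ethnicity` is the matrix of Euclidean distances between study
centroids in MDS space (from the identity-by-state analysis), and
`D_Disease` adds `2 * max(D_Ethnicity)` for cross-disease pairs and
`max(D_Ethnicity)` for same-disease pairs of different subphenotype
(general vs childhood-onset AD). The inflation makes cross-disease
clustering strictly less attractive than any within-disease grouping.

`enumerate_partitions()` generates the partition support with a
centre-based scheme: for every cluster count `T` and every `T`-subset of
studies as centres, each study joins its nearest centre under `D_Total`;
duplicate partitions are merged from a uniform prior over the
`(T, centre-set)` pairs. For up to a dozen studies this is exhaustive,
so no MCMC is needed. Two properties follow from the distance rules and
are tested: any partition induced by a centre set containing both
diseases separates them, and cross-disease merging can only arise from
single-disease centre sets (including the trivial one-cluster partition,
which keeps prior weight `6/63` in a six-study design under the uniform
pair prior — a prior, not a posterior, statement; the data move posterior
mass onto disease-respecting partitions).

The per-variant Bayes factor uses a conjugate zero-centred normal prior
with fixed variance `W` on each cluster's common log-odds effect
(default `W = 0.04`, a prior SD of 0.2 — odds ratios mostly within
~1.5), so every cluster marginal likelihood is closed-form and the BF is
exact given the enumeration. This replaces the hierarchical
unknown-mean/scale prior and MCMC of the original transethnic software
with a deliberately simpler, exactly computable variant; under the
alternative every cluster carries an effect (mixed null/non-null
clusters are not modelled). Filtering uses Wakefield's Bayesian false
discovery probability `BFDP = PO/(PO + BF)` with `PO` the prior odds in
favour of no association; `PO = 99` (one real signal per hundred
variants) with `BFDP < 0.05`, or the stricter `PO = 999`, are the
conventional operating points. Quoted prior odds for this kind of filter
appear in the literature both as "99" and "1/99"; this package always
means odds *in favour of the null*, so larger `PO` is more conservative.

## Multinomial case-case-control model

Where individual genotypes are available, the most direct model is a
three-category multinomial logit: controls are the baseline and AD and
PSO cases are modelled with per-disease dosage log-odds `beta_AD`,
`beta_PSO`, adjusted for sex and the first four principal-component
scores. Age enters the per-study GWAS covariate set but not the
multinomial model. The fit (`fit_multinomial()`) is a straight
Newton–Raphson on the multinomial likelihood with step-halving,
converging on a relative log-likelihood change below `1e-10`, with the
coefficient covariance taken from the inverse observed information; the
`nnet` reference implementation serves as an independent cross-check in
the test suite. Runaway coefficients (|b| beyond ±15, i.e. odds ratios
beyond e^15 — separation) flag the fit non-converged and the variant is
excluded downstream.

Five Wald tests follow: a 2-df overall test (the quadratic form in
`(beta_PSO, beta_AD)`, algebraically identical to testing the rotated
pair `(beta_PSO + beta_AD, beta_PSO - beta_AD)` since the contrast
matrix is invertible) and four 1-df contrasts — PSO `(1,0)`, AD `(0,1)`,
shared `(1,1)`, opposing `(1,-1)`. The variant is classified by the
smallest of the four 1-df p-values (`p_MNM`), the logic being that the
best-powered test is the one matching the true effect structure: a
disease-specific test avoids the variance penalty of dragging in a null
coefficient, while the shared (opposing) contrast doubles the effect
magnitude when directions agree (differ). Ties break deterministically
in the order AD, PSO, shared, opposing, as in the CCMA classifier.

`stepwise_conditional()` dissects multi-signal regions (the epidermal
differentiation complex, the Th2 locus control region, the MHC): all
region variants are refit with the current conditioning set — supplied
carrier dosages such as FLG-null mutations, plus previously selected
variants — as covariates; the best variant with conditional
`p_MNM < stop_p` joins the signal list; candidates with `r^2 > 0.95`
against the conditioning set are skipped as collinear. `stop_p`
defaults to the suggestive `1e-5` and is configurable, since reasonable
analyses range from `0.005` to `1e-8`. A final joint model refits every
selected signal conditioned on all the others.

One deliberate deviation from an obvious-seeming adjustment: when
single-disease collections are pooled, cohort-membership indicators are
**not** added to the covariate set by default. Each collection carries
cases of only one disease, so its indicator perfectly predicts the
absent case category and quasi-separates the multinomial model — the
indicator coefficients diverge while adding nothing. Ancestry and batch
structure is carried by the principal-component scores instead;
`pool_panels(cohort_covariates = TRUE)` remains available for designs
where every cohort has all three outcome categories.

## Quality control

Thresholds follow common GWAS practice: variant missingness > 5 %, exact
Hardy–Weinberg p < 1e-8 (computed in controls when phenotypes are
present), MAF < 5 %, imputation info < 0.4 (strict `<`), call rate
< 95 %; sample missingness > 5 %, heterozygosity beyond mean ± 3 SD (the
“3” is a package default — reasonable analyses vary it, and no single
convention exists), and one member of each pair with `PI_HAT > 0.1875`
(halfway between expected second- and third-degree sharing), removing
the member with higher missingness. Sample-level exclusions run before
variant-level filters. The HWE test is an exact conditional enumeration
(implemented in C++ with a both-directions recurrence so the full
distribution stays in floating range); relatedness is a
method-of-moments PI_HAT from IBS counts and allele frequencies on an
LD-pruned set (window-based `r^2 < 0.2` pruning — parameters are package
defaults, as pruning conventions differ); ancestry structure comes from
classical MDS of the pairwise IBS distance matrix (deterministic up to
per-axis sign); and `lambda_gc` divides the median association
chi-square by the *computed* theoretical null median.

## LD, clumping, loci, regions

LD is composite (phase-free) `r^2`: the squared Pearson correlation of
dosages, computed from controls by default so cases' enrichment does not
distort the reference (configurable to all samples). Clumping is greedy:
best remaining variant above the statistic threshold seeds a clump and
absorbs everything within 250 kb (closed interval, lead-to-member) at
`r^2 >= 0.5`; position breaks statistic ties. The statistic column is
caller-supplied (`T_max`, a per-disease z, `-log10 p`, ...) — the
package does not fix which evidence drives clumping. Note the deliberate
asymmetry kept from the definitions: a *locus* is the lead plus variants
with `r^2 > 0.5` (strict), while *clumping* absorbs at `r^2 >= 0.5`
(inclusive); at an exact boundary value the two differ, and both are
honoured as written. A *shared region* pairs AD and PSO clumps within a
2 Mb window.

## Synthetic data

`sim_config()` describes a 3 AD + 3 PSO case-control design: per-cohort
case/control counts (200–450 cases each, about one tenth the scale of a
large published meta-analysis, so pipelines run in minutes), one AD
cohort childhood-onset, Gaussian ancestry offsets on allele frequencies
(SD 0.01–0.02), allele frequencies uniform on (0.1, 0.9), baseline
prevalences 10 % (AD) and 2 % (PSO), and five variant classes — AD-only,
PSO-only, shared, opposing, null — with default odds ratios 1.6
(disease-specific) and 1.5 / (1.5, 1/1.5) (shared / opposing), chosen so
active components carry expected meta z-scores above ~6 at this scale:
"well-powered" by design, so classification accuracy is a property of
the method, not of sampling noise.

Two genotype generators are provided. The *population* method builds a
cohort pool by a haplotype-copying process (each haplotype allele copies
its left neighbour within an LD block with probability `ld_rho`, else
refreshes at the variant's frequency — dosages stay integral and HWE is
exact within an ancestry stratum), assigns disease by the joint logistic
model with the intercept solved numerically to hit the configured
prevalence, and samples cases and (disease-free) controls. It is the
faithful generative story, but a joint model with hundreds of strong
effects has no realistic prevalence calibration, so it suits
configurations with few causal variants (LD, QC, regional dissection).
The *conditional* method draws each variant's genotypes directly from
`P(g | case)` and `P(g | neither disease)` with the variant treated as
the sole causal variant — the marginal-effect regime in which
per-variant tests are evaluated — which is exact, fast at any variant
count, and carries no LD. The large classification harnesses use it.
`simulate_summary_stats()` bypasses genotypes entirely, drawing
`beta_hat ~ N(beta, se^2)` with the standard case-control variance
approximation `se^2 = (1/(2pq))(1/n_cases + 1/n_controls)`; the test
suite cross-validates this se against genotype-level logistic fits.

What passing tests on these generators do *not* show: robustness to
realistic LD (no recombination-map structure), to imputation error, to
phenotype misclassification, or to overlapping controls between the two
disease arms (assumed absent throughout).

## The exclusivity model

Given a set of opposing loci (risk-allele frequency and per-disease odds
ratios), `conditional_prevalence()` asks what AD prevalence the genetics
alone would imply among psoriasis cases. Each disease gets a
log-additive genotype risk model with its intercept calibrated to the
marginal prevalence (10 % and 2 %); loci are independent HWE; and the
two diseases are taken *conditionally independent given genotype* — the
minimal assumption that lets two marginal risk models be combined.
`P(AD | PSO)` is then an exact enumeration over the `3^L` genotype
vectors (L ≤ 15). `exclusivity_explained()` compares the genetically
implied reduction with the observed one: epidemiological reports give a
25-fold lower AD prevalence among psoriasis cases, i.e. a gap of
`100 × (0.10 − 0.10/25) = 9.6` percentage points; a genetic
`P(AD | PSO)` of 8 % explains `100 × 2/9.6 ≈ 21 %` of it. Because locus
frequencies are user inputs, the package treats the arithmetic — not any
particular percentage — as the reproducible object.

## Numerical choices and degenerate inputs

* Positions are 1-based; interval logic is closed. Multi-allelic sites
  are handled as distinct bi-allelic records. Missing dosages are `NA`
  and every consumer treats them explicitly.
* Palindromic (A/T, C/G) variants with MAF > 0.4 are dropped at
  harmonization: strand orientation is unresolvable from frequency
  there. Harmonization is idempotent.
* HLA dosage hardening uses a strict `>` on the copy-number probability
  (default 0.9): at threshold 1 even a probability of exactly 1 hardens
  to missing, as specified.
* Monomorphic variants: HWE p = 1 by convention; `r^2` is `NA` (zero
  variance); they are excluded from PI_HAT.
* `empirical_p` can never return 0 (plus-one formula); empirical
  calibration refuses targets below `10/(n_sims + 1)` and directs the
  caller to the analytic curve.
* All tie-breaks (CCMA and MNM categories, clump leads, partition
  centre assignment) are fixed and documented, so every pipeline output
  is deterministic given a seed.

## Problem sizes used in the shipped checks

The packaged tests run the generator defaults end-to-end: 10,000 null
variants for p-value uniformity, 500 variants per class for the
CCMA-vs-MNM agreement comparison (about 6,900 samples across six
cohorts), 100 replicates at n = 4,000 for interval coverage, a 1e7-draw
Monte-Carlo null against the analytic calibration, exhaustive HWE
enumeration to n = 200, and 1000 randomized clump configurations against
brute-force search. These sizes were chosen so the full suite completes
in minutes while leaving the statistical assertions well-powered.

## Known limitations

No phasing or imputation; no liftover; no X chromosome; no
random-effects or meta-regression alternatives; no generalisation of
the CCMA statistic beyond two traits; no MCMC partition sampler beyond
a dozen studies; no modelling of overlapping controls; and the
exclusivity model deliberately ignores familial aggregation and
liability-scale formulations.
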