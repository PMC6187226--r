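# polyrisk

Tools for asking what aggregate genetic risk *does*: given a polygenic risk
score (PRS) built from external GWAS summary statistics, which intermediate
traits — clinical measures, neuropathologies, omics modules — does the score
move, and how much of the score's effect on a downstream outcome (such as
cognitive decline) do those endophenotypes explain?

The package is aimed at statistical geneticists and molecular
epidemiologists working with cohort data that pair genotypes with deep
phenotyping and brain omics. Because such cohorts are typically
access-restricted, `polyrisk` ships a fully parameterized synthetic-cohort
generator with a ground-truth ledger, so every stage of the pipeline is
testable end to end without any download.

## What it computes

**Score construction.** For individual *i* over the *m* SNPs surviving a
p-value inclusion threshold and greedy LD clumping (r² > 0.1 within a
2,000 kb window, most significant SNP kept),

&nbsp;&nbsp;&nbsp;&nbsp;PRS_i = (1/m) Σ_s d_is β_s,

the average of effect-allele dosages weighted by the summary-statistic
effects, z-scored across the cohort. Region-excluded and region-only score
variants are built under identical clumping.

**Phenome-wide scan.** Continuous traits are residualized on covariates
(age, sex, education, genotype PCs) and regressed on the scaled score;
binary traits use logistic regression with covariates in the model. The
family-wise threshold is Bonferroni over the registered variable count
(α/590 ≈ 8.5×10⁻⁵ for the default registry).

**Mediation (PAEM).** For outcome *y*, score *P* and mediator *M*:

&nbsp;&nbsp;&nbsp;&nbsp;PVE₁ = R²(y ~ P)
&nbsp;&nbsp;&nbsp;&nbsp;PVE₂ = R²(y ~ P + M) · RI_P
&nbsp;&nbsp;&nbsp;&nbsp;PAEM = 100 · (PVE₁ − PVE₂) / PVE₁

where RI_P is the score's LMG (Chevan–Sutherland) relative-importance
share — its incremental R² averaged over both orders of model entry,
normalized so the two shares sum to the model R². Significance comes from
permuting the mediator (add-one estimator, default 10,000 permutations).
`find_minimal_sets()` searches, by exhaustive enumeration over subset
sizes, for the smallest conditioning sets that render outcome and score
conditionally independent (nested-model F-test).

**Architecture maps.** Sign-binarized SNP×trait association profiles,
aligned to a reference diagnosis trait, compared with Jaccard distances,
embedded in 2-D (t-SNE, perplexity 5), and clustered by consensus label
propagation.

**Omics modules and cis regulation.** A GTEx-style correlation-with-median
sample filter; consensus label-propagation module detection on |r|-weighted
feature graphs; per-individual module scores (mean of z-scored members);
cis expression–acetylation (eQTH) scans within ±1 Mb of the TSS with
Bonferroni control; Fisher (interval overlap), hypergeometric (module
membership) and GREAT-style binomial (regulatory domain) enrichment tests.

## Worked example

```r
library(polyrisk)

cfg <- cohort_config(n_samples = 800, n_snps = 200, seed = 42)
co  <- simulate_cohort(cfg)

prs <- build_prs(co$genotypes, co$sumstats, prs_config(p_threshold = 0.05))
prs
#> prs_vector: 800 samples, 39 SNPs

covs <- as.data.frame(co$phenotypes)[, attr(co$phenotypes, "covariates")]
scan <- run_phewas(prs, co$phenotypes, alpha = 0.05)
scan[scan$significant, c("trait", "kind", "estimate", "p_value")]
#>          trait       kind  estimate      p_value
#> 1  cog_decline continuous 0.2173925 8.964776e-10
#> 2 ad_diagnosis     binary 0.2581282 5.631273e-04
#> 3      amyloid continuous 0.3474727 4.550512e-23
#> 4      tangles continuous 0.2989721 5.033967e-19
#> 5          vgf continuous 0.3011877 7.759289e-19

ry <- residualize(co$phenotypes$cog_decline, covs)
ra <- residualize(co$phenotypes$amyloid, covs)
paem(ry, prs$scaled, ra, n_perm = 1999, seed = 1, mediator_name = "amyloid")
#> PAEM mediation fit (amyloid), n = 800
#>   PVE1 (R2 y~prs):       0.04598
#>   R2 full (y~prs+M):     0.05859
#>   RI share of score:     0.6206
#>   PVE_prs2:              0.03636
#>   PAEM (%):             20.92
#>   permutation p:        5e-04 (1999 permutations)
```

Reading the fit: the scaled score explains 4.6% of the variance of
(residualized) cognitive decline on its own; once amyloid enters the model,
the score's relative-importance share of the joint R² corresponds to 3.6%,
so amyloid accounts for about 21% of the score's effect — far more than
permuted mediators ever do (p ≈ 5×10⁻⁴). For this generating configuration
the cohort ledger puts the population PAEM at 20.8, with a causal mediated
fraction of 16.6%.

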