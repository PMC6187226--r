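---
title: "Methods: polygenic scores, phenome-wide scans, and the PAEM mediation statistic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: polygenic scores, phenome-wide scans, and the PAEM mediation statistic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical models behind `polyrisk`, the
choices made where the design was genuinely open, and what the synthetic
cohorts used by the test suite do and do not establish about real data.

## 1. Score construction

The polygenic score is the *average* of effect-allele dosages weighted by
external summary-statistic effects, over SNPs that pass a p-value inclusion
threshold and survive LD clumping. Averaging rather than summing changes
nothing downstream (the score is z-scored before any analysis) but keeps the
raw scale independent of the SNP count, which makes threshold sweeps
comparable.

**Clumping order.** "LD pruning" is ambiguous between position-order pruning
and significance-ordered clumping. We use clumping: candidates are visited
in ascending p-value order and a SNP is dropped when its dosage r² with an
already-kept SNP on the same chromosome within the window exceeds the
threshold. This matches the behaviour of the standard scoring software
family, keeps the most significant representative of each LD clump, and
makes the kept set deterministic. Ties in p-value are broken by chromosome
then position so results are reproducible across platforms. The window is
interpreted as |pos_a − pos_b| ≤ window_kb·1000 on the same chromosome —
the simplest defensible reading. Defaults: p < 0.001, r² > 0.1,
window 2,000 kb.

Because candidates are visited in ascending p-value order, the kept set at a
smaller threshold is a prefix of the kept set at a larger one; kept-SNP
counts are therefore monotone in the threshold, which the threshold-sweep
function relies on.

**Allele orientation.** When the genotype file's effect allele is the
summary statistic's *other* allele, the dosage is flipped (d → 2 − d) and
the effect sign kept. Any other allele combination is an error, not a
silent drop.

## 2. Phenome-wide scan

Continuous traits are residualized on the covariates (age, sex, education,
three genotype PCs) by least squares and the residuals regressed on the
scaled score; binary traits enter a logistic model with the covariates
included. Tests are two-sided throughout, since associations are reported
in both directions. The two-stage residualize-then-regress procedure does
not propagate the covariate-fit degrees of freedom into the second-stage
standard error; on null data its p-values agree with the joint-model Wald
test to simulation accuracy (the suite checks calibration against the exact
binomial interval at α = 0.05), and we adopt it because it matches how the
downstream mediation statistic consumes traits.

Missingness policy is complete-case per test: omics layers cover different
subsets of individuals, so per-variable n legitimately differs.

The family-wise threshold is Bonferroni over the *registered* variable
count rather than a hard-coded number, because the family is a property of
the cohort configuration. The default registry (3 clinical diagnoses, 6
cognitive measures, 8 lifestyle/personality traits, 14 medical conditions,
13 brain pathologies, 58 + 80 + 49 omics modules, 292 miRNAs, 67 proteins)
counts 590 variables, giving α/590 ≈ 8.5×10⁻⁵ at α = 0.05.

## 3. The PAEM statistic

For outcome $y$, scaled score $P$ and mediator $M$:

$$\mathrm{PVE}_1 = 1 - \frac{SS_{res}(y \sim P)}{SS_{tot}}, \qquad
\mathrm{PVE}_2 = R^2(y \sim P + M)\cdot RI_P, \qquad
\mathrm{PAEM} = 100\,\frac{\mathrm{PVE}_1 - \mathrm{PVE}_2}{\mathrm{PVE}_1}.$$

$RI_P$ is the LMG (Chevan–Sutherland) relative importance of the score in
the two-regressor model. With two regressors it has the closed form

$$RI_P = \frac{R^2(y\sim P) + \left[R^2(y\sim P+M) - R^2(y\sim M)\right]}
{2\,R^2(y\sim P+M)},$$

i.e. the score's incremental R² averaged over both orders of model entry,
normalized so the two shares sum to one. We adopt this normalization
because it is the only reading under which multiplying the share by the
model-2 R² yields a variance share, making PVE₂ directly comparable to
PVE₁. The implementation works on sample correlations (algebraically
identical to the sequential least-squares route; the suite checks agreement
with an explicit `lm`-based oracle at 10⁻¹⁰ on a thousand random
instances), which makes the permutation loop O(n) per draw.

**Interpretation and range.** Writing
$\mathrm{PAEM} = 50\,(1 - \Delta R^2_{P|M}/\mathrm{PVE}_1)$ with
$\Delta R^2_{P|M} = R^2(y\sim P+M) - R^2(y\sim M) \ge 0$ shows the
statistic is bounded above by 50: full mediation — the mediator absorbing
the score's effect entirely — corresponds to PAEM = 50, which the
noise-free construction $y = M$, $M = aP + \eta$ attains exactly.
Suppression ($\Delta R^2_{P|M} > \mathrm{PVE}_1$) drives PAEM negative.
Finite-sample values outside [0, 100] are reported as-is with a flag and
never clamped; the permutation test carries the inference.

**Degenerate inputs.** PVE₁ ≤ 0 (no score effect to decompose) and
|cor(P, M)| ≥ 0.999 (collinear mediator) are errors. Permutation draws that
become degenerate (a permuted mediator collinear with the score) are scored
as 0 and counted, so the null distribution is never silently shortened; the
p-value uses the add-one estimator $(1 + \#\{PAEM_{null} \ge
PAEM_{obs}\})/(1 + n_{perm})$, which cannot return zero.

**Conditional independence.** The minimal-set search enumerates candidate
subsets by increasing size and applies the nested-model F-test
($F = [(SS_{red} - SS_{full})/1]/[SS_{full}/(n - p_{full})]$); at the first
size where any subset achieves p > α, *all* qualifying subsets of that size
are returned, which is the natural way to report "k variables were
necessary". Collinear conditioning columns are dropped with a message, and
enumeration is refused beyond 20 candidates.

## 4. The synthetic cohort

The generator emulates the statistical structure the pipeline assumes:

* **Genotypes.** Dosages are sums of two haplotypes. Within an LD block,
  each haplotype's allele indicators come from thresholding a blockwise
  AR(1) Gaussian latent vector (adjacent-SNP correlation `rho_ld`, default
  0.6, blocks of 10) at the Gaussian quantile of the SNP's allele frequency
  (MAF uniform on [0.05, 0.5]). This produces pruning-relevant LD with a
  single controllable parameter; it does not attempt realistic human
  haplotype maps.
* **External weights.** Summary statistics are estimated by marginal
  regression on an *independent* simulated replicate (default twice the
  analysis-cohort size), never on the analysis cohort, so score weights
  carry realistic estimation noise, mirroring the external-GWAS-weights
  design. Per-SNP effects are drawn Gaussian by default; an `"equal"`
  profile (equal magnitudes, random signs) gives a strongly polygenic
  architecture, used where a property concerns polygenicity itself (e.g.
  the threshold-sweep power test).
* **Causal graph.** $M_j = a_j P + \eta_j$, $y = cP + \sum_j b_j M_j +
  \varepsilon$, with $P$ the standardized true score, mediators scaled to
  unit variance and the structural outcome variance normalized to 1, so all
  paths live on the correlation scale. Defaults plant three mediators with
  $a_j = 0.40$, $b_j = 0.128$ and $c = 0.154$, anchoring the total effect
  at $T = 0.308$ — an outcome R² of 9.5%, a realistic magnitude for a
  polygenic score on a cognitive-decline slope — with roughly half the
  effect mediated. The default cohort size (1,272) matches the scale of the
  autopsy cohorts this design emulates.
* **Ledger.** The truth ledger records, per mediator, the *causal mediated
  fraction* $100\,a_jb_j/T$ and the *population PAEM* computed from the
  implied covariance matrix. These differ by construction: the population
  PAEM is capped at 50 (Section 3), so a 50%-mediated configuration has
  population PAEM below 50 (about 39.5 under the default paths). Recovery
  tests compare estimated PAEM to the population-PAEM ledger entry —
  the estimand the estimator actually targets — while `plant_mediation()`
  plants fractions on the causal scale. Recovery tests use the true
  standardized score rather than a re-estimated one, isolating the
  estimator's behaviour from score-estimation attenuation (which is a
  property of the score builder, tested separately).
* **Binary diagnosis.** Logistic link on the structural outcome with the
  intercept solved by root-finding to hit a target prevalence (default
  0.4).
* **Covariates.** Age, sex, education and three PC-like noise columns are
  independent of genotype and add a common shift (default 0.15 per
  covariate) to continuous traits, so residualization is exercised but the
  ledger's structural values are recovered exactly after it. Population
  stratification beyond supplying PC columns is out of scope.
* **Omics.** Module members load on a latent factor ($\sqrt{\rho}$ loading,
  default within-module correlation 0.6) that is optionally coupled to the
  score; leftover features are unstructured noise (truth label 0). The
  expression layer doubles as the gene table and the acetylation layer as
  the peak table; planted cis couplings pair noise features of the two
  layers within 50 kb of a TSS, and a chromatin-annotation track covering
  module-1 peaks provides a planted enrichment target.
* **SNP groups.** Under this generator's causal graph all mediators hang
  off the single aggregate score, so the only mechanistically recoverable
  SNP grouping is causal vs. non-causal, and that is what the ledger's
  group labels record. Distinct per-group trait signatures are a property
  of real data the generator deliberately does not emulate; the
  SNP-clustering operations are therefore validated on directly constructed
  sign matrices with planted profiles.

Passing tests on these cohorts establishes that each algorithm recovers the
structure it is designed to detect under its stated assumptions — not that
real cohorts satisfy those assumptions. In particular the generator's LD is
short-range and blockwise, its mediators are jointly Gaussian with linear
paths, and its omics modules are disjoint blocks; real data violate all
three in various ways.

## 5. Module detection and the sample filter

Module detection implements consensus label propagation: the feature graph
is weighted by |r| with edges kept at |r| ≥ 0.2 (sparsification is required
for label propagation; the threshold is exposed), label propagation runs 50
times with shuffled update orders, and final modules are connected
components of pairs co-assigned in ≥ 50% of runs. This preserves the
character of stochastic consensus clustering while being fully specified;
it is not a reimplementation of any published consensus algorithm.
Singletons are allowed, and an all-zero correlation matrix yields all
singletons with a warning.

The sample filter computes $d_i$ = correlation of sample $i$ with the
per-feature median and excludes samples below $Q_1 - 1.5\,\mathrm{IQR}$
(lower fence only). With identical samples the IQR is 0 and the strict
inequality keeps everyone; a constant sample vector has undefined $d_i$ and
is excluded with a warning. The planted-outlier test runs in the regime the
filter targets — coherent samples of heterogeneous quality (per-sample
noise SD uniform on [0.3, 0.8], 200 features), where the $d_i$ bulk spread
comes from quality variation and the noise sample sits far below the
fence — and demands exact recovery in ≥ 95% of replicates. With homogeneous
Gaussian quality the fence sits near 2.7σ and occasional false exclusions
are expected; that regime is a documented limitation, not a test target.

## 6. Architecture maps

Binarization keeps only the direction of effect (1 = strictly positive,
0 otherwise; zero statistics map to 0), after flipping whole trait rows
that correlate negatively with the reference diagnosis trait. Jaccard
distances use positive-sign sets, $d = 1 - |P_t \cap P_u|/|P_t \cup P_u|$,
with $d = 0$ when both sets are empty; this is a metric, which the suite
property-tests. Magnitude- or significance-thresholded binarizations would
be explicit extensions, not the default.

The 2-D embedding is an exact t-SNE written in base R (no R t-SNE package
is part of the dependency set): per-item Gaussian bandwidths are calibrated
to the target perplexity (default 5) by bisection on the supplied
*distances squared*, similarities are symmetrized, and the map minimizes
KL(P‖Q) under the Student-t kernel by gradient descent with momentum
(0.5 → 0.8 at iteration 250), learning rate 100, and 12× early
exaggeration for the first 250 iterations, from a seeded small random
initialization. The contract is seeded determinism plus neighborhood
preservation on separated groups — never specific coordinates. Perplexity
is clamped below (n−1)/3 with a warning.

## 7. cis mapping and enrichment

"Quantile-normalized" is implemented as the rank-based inverse-normal
transform $x \mapsto \Phi^{-1}((r - 0.5)/n)$ with average ranks for ties —
the standard choice for correlation-based QTL-style scans, since the paper
trail names no target distribution. The cis window anchors on the *peak
midpoint* within ±1 Mb of the TSS (the anchor is not specified by the
method's description; midpoint is the symmetric choice), and the scan's
Bonferroni threshold divides α by the number of tests actually performed.

Enrichment conventions follow each test's usual usage: Fisher's exact test
(interval overlap against the peak universe, ≥ 1 bp counting) is two-sided;
hypergeometric (module membership) and binomial (SNP-in-domain) tests are
upper-tailed, since they ask about enrichment specifically. Regulatory
domains extend the gene body by 1,000 kb on each side, truncated at the
nearest point where another gene's body starts (zero extension on a side
with overlapping bodies), clipped at position 1 and optionally at supplied
chromosome lengths; member domains are merged per gene set before coverage
is computed, so overlap is never double-counted.

## 8. Problem sizes and numerical tolerances

The test suite and the acceptance script size their simulations to be
decisive but quick: 1,000 random instances for oracle equivalence (relative
10⁻¹⁰); 60–100 replicates at n = 1,000 for mediated-fraction recovery
(±10 points against the population-PAEM ledger); 400–500 replicates with
499 permutations for null calibration (exact binomial 95% interval);
30–50 replicates at n = 800 for minimal-set recovery (≥ 80% exact
recovery); two 50-feature blocks at n = 300 for module recovery (ARI = 1);
enumeration oracles at 10⁻¹² for the enrichment tests. Round-trip and
algebraic identities are asserted at 10⁻¹⁰–10⁻¹²; the z-scored score's
mean/SD at 10⁻¹⁰.

## 9. Known limitations

* The clumping r² is estimated in the analysis cohort itself; no external
  LD reference panel is supported, and shrinkage/Bayesian score weighting
  is out of scope.
* The two-stage residualization convention (Section 2) slightly misstates
  second-stage degrees of freedom; with covariate counts ≪ n this is
  negligible, and calibration is verified by simulation rather than
  corrected analytically.
* PAEM is a variance-attribution statistic, not a counterfactual mediation
  estimand; no identification claims attach to it, and the minimal-set
  search reports conditional-independence structure, not causal direction.
* Label-propagation consensus can split very weakly connected planted
  modules at low within-module correlation; the recovery guarantee is
  established for within-block r ≥ 0.6 and block size ≥ 20 at n ≥ 200.
* The t-SNE implementation is exact (O(n²) per iteration) and intended for
  trait-map-sized inputs (tens to hundreds of items), not for embedding
  thousands of points.
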