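---
title: "Auditing the comparability of down-sampled GWAS summary statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing the comparability of down-sampled GWAS summary statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gwasaudit)
```

When restricted cohorts are removed from a GWAS meta-analysis before its
summary statistics are released, the released file differs from the
full-data analysis in two conceptually distinct ways: it has *less signal*
(smaller effective sample size, hence larger standard errors and lower
single-SNP detection power), and it may be *less representative* (if the
removed cohorts measured the phenotype differently, the remaining genetic
signal is a slightly different trait). `gwasaudit` separates these two
failure modes and quantifies both. This vignette documents the statistical
models behind each step, the tunable parameters, the synthetic-data
generators used for validation, and the numerical choices made where the
design was genuinely open.

## The LD Score regression core

All signal indicators derive from the LD Score regression expectation for
the association chi-square of SNP j,

$$E[\chi^2_j] = 1 + Na + N h^2 \ell_j / M,$$

where $\ell_j$ is the SNP's LD score, $M$ the number of SNPs behind the
heritability denominator, $N$ the (effective) sample size, $h^2$ the
observed-scale SNP heritability, and $Na$ the confounding inflation
absorbed by the intercept. The package fits this by weighted least squares
of $\chi^2_j$ on $N\ell_j/M$ with a free intercept. Weights follow the
two-step heteroskedasticity scheme: a first unweighted pass seeds
$\hat h^2$ and the intercept, and the second pass uses
$w_j = \ell_j^{-1} \cdot \tfrac{1}{2}E[\chi^2_j]^{-2}$ (with $\ell_j$
floored at 1 and the variance term floored at 0.1 for numerical safety).
The bivariate version regresses $z_{1j} z_{2j}$ on
$\sqrt{N_1 N_2}\,\ell_j/M$; its intercept absorbs sample overlap, its
slope is the genetic covariance, and
$r_g = \widehat{\mathrm{gcov}} / \sqrt{\hat h^2_1 \hat h^2_2}$. The
marginal variance terms in the bivariate weights reuse the univariate
first-pass seeds, which makes the weights for a trait paired with itself
identical to its univariate weights — so the self genetic correlation is
exactly 1, a useful internal consistency anchor.

Standard errors come from a delete-one-block jackknife over `n_blocks`
(default 200) blocks contiguous in file order; genome positions are
carried but never used. The regressions are accumulated as per-block
sufficient statistics, so the jackknife costs O(M + n_blocks) and the
joint jackknife across all T(T+1)/2 elements of a genetic covariance
matrix is cheap. SNPs with $\chi^2 > \max(80, 0.001\,N)$ are dropped
before the regression (configurable), mirroring conventional outlier
handling; the genomic inflation factor uses the fixed constant 0.4549364
for the central $\chi^2_1$ median, documented to seven digits so tests are
bit-stable.

Estimated $|r_g| > 1$ is reported unclipped with a warning flag: clipping
would hide exactly the boundary behaviour an audit needs to see.

## Key indicators and concordance checks

For each file the audit reports EffN, $\hat h^2$ (±jackknife SE), mean
$\chi^2$, $\lambda_{GC}$ (median $\chi^2$ / 0.4549364), the LDSC
intercept, and the attenuation ratio
$(\text{intercept} - 1)/(\text{mean } \chi^2 - 1)$ — undefined (NA, with a
warning) when mean $\chi^2 \le 1$. Effective sample size for binary traits
is $\sum_k 4 V_k (1-V_k) N_k$ over cohorts ($V_k$ the case proportion);
for continuous traits the total N. Pair deltas are percentage changes for
EffN, mean $\chi^2$ and $\lambda_{GC}$, absolute differences for $h^2$ and
the ratio, since the latter two are already unitless ratios whose
proportional changes are not meaningful near zero.

The concordance checks run on near-independent SNPs, defined by greedy LD
clumping: repeatedly take the remaining SNP with the smallest p-value
below `p_thresh` (default 5e-8) and discard everything with LD
$r^2 \ge$ `r2_thresh` (default 0.1) to it. Ties in p are broken by
lexicographic SNP id so the output is deterministic across platforms and
row orders.

* **Sign concordance** is tested one-sided against a null concordance of
  `p0 = 0.99`: the only failure mode of interest is *discordance*, and a
  99% null keeps the test sensitive without letting a single discordant
  SNP reject (as a 100% null would). The exact binomial p-value is
  $P(\mathrm{Bin}(n, p_0) \le k)$. Zero coefficients count as discordant
  (conservative; exact zeros are measure-zero in practice).
  `design_power()` gives the exact power of this design: with 150
  independent SNPs it exceeds 80% against a true concordance of 95%.
* **Outliers** are down-sampled coefficients outside the full-data
  $\hat\beta \pm 1.96\,\mathrm{SE}$ interval (normal quantile at any
  requested level — the large-sample framing appropriate for GWAS
  standard errors). The flags can be written into the released file as a
  final 0/1 `OUTLIER` column.
* **Coefficient regression** fits OLS of down-sampled on full-data
  coefficients, by default on absolute values (a signed option exists,
  since either convention is defensible and the choice matters only when
  effects straddle zero), and tests intercept = 0 and slope = 1 by Wald
  t-tests. Note that conditioning the SNP set on full-data significance
  truncates the regressor's range, which deflates the attainable R² in
  weak-signal simulations; the slope remains the interpretable quantity.

## The single-factor genomic SEM

The genetic covariance matrix S (heritabilities on the diagonal, genetic
covariances off it) and the sampling covariance V of its unique elements
are estimated on the shared harmonized SNP intersection with common
jackknife blocks, so V captures the dependence among all entries. The
confirmatory one-factor model with unit-variance identification is fitted
to the standardized matrix by diagonally weighted least squares:

$$\min_\theta\; (s - \sigma(\theta))^\top \mathrm{diag}(V_s)^{-1} (s - \sigma(\theta)),
\qquad \sigma(\theta) = \mathrm{vech}(\lambda\lambda^\top + \mathrm{diag}(\psi)),$$

with $s$ the half-vectorized standardized S and $V_s$ its sampling
covariance obtained by the delta method. Diagonal weighting (rather than
the full $V^{-1}$) avoids inverting a noisy 28-dimensional jackknife
matrix for seven traits. Because the standardized diagonal is identically
1 with zero sampling variance, the residual variances are profiled as
$\psi_t = \max(0, 1 - \lambda_t^2)$; a quasi-Newton (BFGS) optimizer with
analytic gradient then works on the loadings alone, initialized from the
leading eigenvector of the standardized matrix. Heywood cases
($\lambda_t^2 > 1$) are bounded — $\psi_t = 0$ — and flagged rather than
fatal, because an audit must degrade gracefully. Loadings are
canonicalized with the largest-magnitude loading positive, making the fit
invariant to the global sign indeterminacy.

Fit statistics: the model discrepancy $\chi^2$ is the residual quadratic
form against the Moore–Penrose inverse of the full jackknife $V_s$ (an
approximation — it ignores the reduction from estimating 2T parameters and
so runs slightly high on well-fitting data);
$\mathrm{df} = T(T+1)/2 - 2T$; CFI compares against the independence
baseline with a floor of 1e-12 on the baseline excess; SRMR is the root
mean square standardized residual; AIC is $\chi^2 + 2\cdot 2T$. "Good
fit" is classified as CFI > 0.9 and SRMR < 0.08. Exactly
rank-one-plus-diagonal input reproduces the loadings to machine precision
with SRMR = 0 and CFI = 1. Parameter standard errors use the DWLS
sandwich $(J^\top W J)^{-1} J^\top W V_s W J (J^\top W J)^{-1}$.

Two fits over the same traits are compared parameter-wise with
$z = (a - b)/\sqrt{se_a^2 + se_b^2}$ and a Bonferroni flag. The SNP-level
factor GWAS regresses each SNP's vector of SNP–trait genetic covariances
(taken as $z_{jt}\sqrt{h^2_t}/\sqrt{N_{jt}}$ on the standardized-trait
scale, with sampling SE $\sqrt{h^2_t/N_{jt}}$) on the loading vector by
GLS with weights from those sampling variances; with isotropic sampling
structure this reduces to OLS. Only a single-factor model is provided by
design: the audit asks whether the *published* factor solution transfers
to the down-sampled indicators, not whether a better model exists.

## Power calculus

Detection power for a 1-df association test is
$1 - F(c;\, 1,\, \lambda)$ with non-centrality $\lambda = N r^2$,
$r^2 = Z^2/N$ the squared standardized coefficient, and $c$ the central
$\chi^2_1$ quantile at the significance threshold (default genome-wide
5e-8, $c \approx 29.7$). The non-central CDF comes from the standard
library routine; for df = 1 the identity
$1 - F = \Phi(\sqrt\lambda - \sqrt c) + \Phi(-\sqrt\lambda - \sqrt c)$ is
exact and serves as an independent cross-check in the test suite (agreement
to 1e-9). Power curves default to the grid $r^2 \in \{3, 4, 5\}\times
10^{-5}$, magnitudes representative of effects reaching genome-wide
significance in recent large-scale GWAS. No winner's-curse correction is
applied to the median genome-wide-significant $r^2$; the audit compares
like with like across the two versions, so the shared selection bias
cancels from the *difference* that matters.

## PGS evaluation

Incremental R² is the variance explained by covariates + standardized
score minus that of the covariates alone: ordinary R² under linear
regression for continuous outcomes, pseudo-R² under logistic regression
for binary ones (Nagelkerke by default — the most common convention in
PGS reporting — with McFadden by flag). Confidence intervals are
percentile bootstraps over individuals (default 1000 iterations, seed
required); missing data are removed listwise with counts reported.

One subtlety: plain incremental R² is non-negative by construction (an
added regressor can never lower in-sample R², and nested deviances do the
same for the pseudo versions), so its percentile interval can never reach
0 and is uninformative for null calibration. `incremental_r2()` therefore
offers `adjusted = TRUE` (adjusted R², continuous outcomes), which is
approximately centred under a null score; the package's own calibration
tests use it, while the default reporting remains the plain quantity.
Two scores are compared per outcome by the standardized difference of
absolute coefficients, $z = (|b_A| - |b_B|)/\sqrt{se_A^2 + se_B^2}$, so
negative z reads as attenuation of the first score.

Differences between paired estimate vectors in the pattern-comparison
steps use the analogous large-sample z-test with independent SEs. The
full-data and down-sampled estimates in fact share most of their samples,
so their errors are positively correlated and the independent-SE test is
conservative for *detecting* differences — an acceptable direction of
error for an audit whose alarm condition is differences being present.

## What the synthetic generators emulate

`simulate_sumstats_pair()` draws, per SNP, a shared standardized marginal
effect $b_j \sim N(0, h^2 \ell_j / M)$ — genetic variance proportional to
the LD score, so the LD Score regression estimator is *exactly*
well-specified and recovery tests are clean. Cohort k observes
$b_j + \delta_{jk} + e_{jk}$ with sampling noise
$e_{jk} \sim N(0, \text{intercept}/\mathrm{EffN}_k)$ (the intercept
parameter injects uniform confounding) and cohort heterogeneity
$\delta_{jk} \sim N(0, \tau^2 \ell_j / M)$. The heterogeneity is
LD-scaled deliberately: constant-variance heterogeneity is uncorrelated
with LD score and would be absorbed into the LDSC intercept, leaving the
estimated full/down genetic correlation at 1 no matter how large $\tau$;
LD-scaled heterogeneity behaves as cohort-private *genetic* signal, which
is the phenomenon that actually drives published full-vs-down genetic
correlations below 1 (the ~0.95–0.98 range motivates the default
calibration $\tau \approx 0.26$ for a true cross-version correlation of
0.97 at the default two-cohort design). With $\tau > 0$ each version's
total heritability is $h^2 + \tau^2 \sum_k w_k^2$ (meta-analysis weights
$w$), which the truth record reports. Inverse-variance meta-analysis over
all cohorts gives the full file; over the retained cohorts, the
down-sampled twin — sharing the same draws, exactly like a real
down-sampled release shares its cohorts with the full analysis.

`simulate_factor_traits()` adds a shared factor effect so trait t has
heritability $h_t^2$ and pairwise genetic correlations
$\lambda_t \lambda_u$; `simulate_ld_blocks()` builds block-diagonal LD for
clumping tests; `simulate_pgs_cohort()` produces binomial dosages, an
age/sex/10-PC covariate block carrying 20% of outcome variance, and a
continuous outcome calibrated so the population incremental R² equals its
target (a binary outcome follows by liability thresholding at 30%
prevalence). All generators are deterministic per seed.

What the generators do **not** emulate — and what passing tests therefore
do not demonstrate about real data: LD between the simulated Z statistics
(LD enters only through the per-SNP variance scale, and clumping is
exercised on the separate block generator), realistic joint MAF/LD
structure, imputation noise, ancestry stratification beyond a uniform
intercept shift, and liability-scale conversions (everything is observed
scale). The audit's statistical machinery is validated under its own
model assumptions; its behaviour under model violation is exactly what
the real-data audit steps are for.

## Problem sizes and numerical conventions

The validation suite runs at M = 20,000 panel SNPs, N = 50,000 (univariate
recovery; 50 replicates at $h^2 = 0.2$), 7-trait factor panels (10
replicates), and PGS cohorts of 2,000–5,000 individuals with up to 1000
bootstrap iterations — sizes chosen so the whole suite completes in well
under a minute per module while leaving Monte Carlo error far smaller than
the tolerances tested. Replicated recovery checks compare mean bias
against 3·SD/√(replicates) rather than asserting single draws inside
±2 SE, because with 7–14 parameters per fit a calibrated estimator fails
a joint single-draw ±2 SE check ~30% of the time by chance.

Other conventions: p-values read as 0 are floored at 1e-300 (preserves
ranking, avoids −log10 overflow); alleles are uppercased and restricted to
A/C/G/T with strand-ambiguous (A/T, C/G) SNPs dropped by default during
harmonization, since strand cannot be resolved without allele frequencies,
which the audit does not require; irreconcilable allele pairs are dropped
and logged, never silently kept; Z is recomputed from BETA/SE when the two
representations disagree beyond 1e-6 (the discrepancy is counted in the
load report); coordinates are 1-based and carried but unused in
statistics. The factor optimizer declares convergence at gradient norm
below 1e-6 after BFGS termination and fails loudly otherwise.

## Known limitations

* The model $\chi^2$ for the factor fit is a residual quadratic form
  without the parameter-estimation correction; CFI inherits this mild
  conservatism. Fit *comparisons* between full and down-sampled versions,
  the audit's actual target, are unaffected.
* Jackknife V matrices from 200 blocks are noisy; the DWLS weights use
  only their diagonal by design, but the reported model $\chi^2$ uses the
  full pseudo-inverted matrix and should be read as descriptive.
* Partitioned/stratified LD Score regression and liability-scale
  heritability are out of scope, as are gene-property analyses themselves
  (only externally produced estimate tables are compared) and PGS weight
  estimation (weights are inputs).
* The large-sample z-tests for estimate differences ignore the positive
  error correlation induced by shared samples (conservative, as noted
  above); no degrees-of-freedom correction is attempted because jackknife
  SEs have large effective df.
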