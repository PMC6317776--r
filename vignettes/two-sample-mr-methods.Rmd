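---
title: "Methods: two-sample mendelian randomization from summary statistics"
author: "summaryMR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample mendelian randomization from summary statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(summaryMR)
```

## The model

Two-sample mendelian randomization (MR) estimates the causal effect of an
exposure on a disease from two independent GWAS: one providing per-SNP
associations with the exposure ($\hat\beta_{GE,j}$, in SD units of the
trait per effect allele, with standard error $\sigma_{x,j}$) and one
providing per-SNP associations with the disease ($\hat\beta_{GD,j}$, in
log-odds per allele, with $\sigma_{y,j}$). If SNP $j$ affects the disease
only through the exposure (a valid instrument), its two associations are
proportional, with the causal log odds ratio per SD, $\theta$, as the
constant of proportionality. The motivating application is the etiology of
renal cell carcinoma: obesity-related exposures (body mass index,
waist-to-hip ratio, blood pressure, lipids, glycemic traits) proxied by
genome-wide significant SNPs, evaluated against a case-control GWAS of
10,784 cases and 20,406 controls.

### Instrument construction

Candidate SNPs are retained when the exposure association is genome-wide
significant (strictly $P < 5\times10^{-8}$) and, for imputed outcome data,
the imputation info score is at least 0.7 (a missing info score passes:
the filter targets imputed variants). Correlated SNPs are removed by
greedy LD pruning: the most significant remaining SNP is kept and
everything with $R^2 \ge 0.1$ to it is dropped, repeatedly. Ties in
p-value break by rsid so the result does not depend on row order.

Harmonization aligns the outcome association to the exposure's effect
allele. A swapped allele pair negates the outcome beta; strand complements
are folded in first. Palindromic variants (A/T, C/G) are unresolvable from
allele labels: they are replaced by a user-supplied proxy when one is
given, oriented by comparing which side of 0.5 the effect-allele frequency
falls on in the two datasets when the minor allele frequency is at most
0.4 in both, and excluded otherwise (or when either frequency is missing).
An alternative `same_strand` mode aligns palindromic variants by label
alone, for datasets known to share a strand convention. Every input SNP
lands exactly once in the retained set or in the exclusion log, and
harmonizing an already-harmonized pair is a no-op. Proxy lookup is a
substitution table supplied by the user: the package performs no remote
LD queries.

### Estimators

*Wald ratios and IVW.* Each SNP contributes $\hat\theta_j =
\hat\beta_{GD,j}/\hat\beta_{GE,j}$ with first-order standard error
$\sigma_{y,j}/|\hat\beta_{GE,j}|$ and weight $w_j =
\hat\beta_{GE,j}^2/\sigma_{y,j}^2$. The inverse-variance-weighted (IVW)
estimate $\sum w_j\hat\theta_j/\sum w_j$ is the closed-form reference. A
second-order weight option (propagating the exposure error) exists but is
off by default, matching standard summary-data practice.

*Likelihood-based estimator* (the primary method). The observed pairs are
modelled as
$\hat\beta_{GE,j}\sim N(\xi_j,\sigma_{x,j}^2)$,
$\hat\beta_{GD,j}\sim N(\theta\xi_j,\sigma_{y,j}^2)$,
with the true SNP-exposure effects $\xi_j$ as nuisance parameters. Each
$\xi_j$ has the closed-form conditional maximizer
$\hat\xi_j(\theta) = (\hat\beta_{GE,j}/\sigma_{x,j}^2 +
\theta\hat\beta_{GD,j}/\sigma_{y,j}^2)/(1/\sigma_{x,j}^2 +
\theta^2/\sigma_{y,j}^2)$, so $\theta$ is found by one-dimensional
maximization of the profile log-likelihood, bounded to $[-5, 5]$ log-odds
per SD (far outside any plausible epidemiological effect; a maximizer at
the boundary raises a diagnostic error carrying the profile curve).
Confidence limits are read off the profile at a drop of
$\chi^2_{1,0.95}/2 = 1.92$ units, and the reported SE is the CI width
divided by $2 \times 1.96$. Unlike IVW this accounts for sampling error in
the exposure associations; as $\sigma_{x,j}\to 0$ the two coincide (a
tested property). The model is fixed-effect: heterogeneity is reported
(Cochran $Q$ over the Wald ratios, $I^2 = \max(0, (Q - df)/Q)$), not
modelled.

*Weighted median.* The inverse-variance-weighted empirical quantile
function of the ratios, interpolated at 0.5; consistent when SNPs carrying
at least half the weight are valid. If a single SNP exceeds half the
weight its ratio is returned with a warning. The SE is a parametric
bootstrap (default 10,000 resamples, seeded; `nBoot = 0` skips it for
simulation studies that need only the point estimate).

*MR-Egger with SIMEX.* Weighted least squares of outcome on exposure
effects with a free intercept, each SNP oriented to a non-negative
exposure effect, weights $1/\sigma_{y,j}^2$. The intercept estimates
average directional pleiotropy; its $t$ test ($n-2$ df, residual
dispersion floored at 1, the usual convention for summary-data Egger
regression) is the directional-pleiotropy test. Egger regression assumes
no measurement error in the exposure effects (NOME); when that fails the
slope attenuates. The SIMEX correction re-fits on data with added noise
$N(0, \lambda\sigma_{x,j}^2)$ over $\lambda \in \{0, 0.5, 1, 1.5, 2\}$
(1000 replicates per $\lambda$), fits a quadratic in $\lambda$ to the
averaged coefficients, and extrapolates to $\lambda = -1$. Variances are
extrapolated from the per-$\lambda$ difference between mean model-based
variance and between-replicate variance, falling back to the naive
variance (with a warning) if the extrapolation turns non-positive.

*MR-PRESSO.* The global pleiotropy test compares the observed weighted
residual sum of squares — each SNP's outcome effect against its
leave-one-out IVW prediction — to a parametric null in which both summary
estimates are redrawn around their expected values, recomputing the
statistic identically (expected values use leave-one-out IVW rather than
the likelihood estimator, matching the method's original construction and
keeping the null simulation cheap). The Monte-Carlo p-value uses the
add-one convention and is never exactly zero. Per-SNP outlier p-values are
the exceedance fractions of the per-SNP residual contributions,
Bonferroni-adjusted; flagged SNPs are removed and the likelihood estimate
recomputed (`presso_corrected`). Defaults: 10,000 simulations, outlier
alpha 0.05 (the source study reports neither; both are stated
assumptions). The distortion test is out of scope. A caveat worth knowing:
a very dominant outlier contaminates the other SNPs' leave-one-out
expectations and can mask its own per-SNP test — an intrinsic property of
the residual-sum construction, visible in the even-weight versus
dominant-weight spike experiments in the test suite.

### Stratum meta-analysis and power

Stratum estimates (four study sources; male/female) combine by
fixed-effect inverse-variance pooling with Cochran $Q$ on $n-1$ df (3 df
for four sources) and $I^2$. The two-group case is the 1-df z test,
$z^2 = Q$ exactly. The same statistic compares two exposures' estimates
(e.g. diastolic versus systolic blood pressure); those share the outcome
sample, so the result carries an explicit `independenceAssumed` flag.
Standard errors quoted only as 95% CIs are recovered as
$(\ln hi - \ln lo)/3.92$ throughout — the package's single CI-to-SE
convention.

A priori power for a binary outcome uses the asymptotic SE of the IV
log-odds estimate, $1/\sqrt{n k(1-k) R^2}$: power $=
\Phi(\mu - z_{1-\alpha/2}) + \Phi(-\mu - z_{1-\alpha/2})$ with $\mu =
\sqrt{n R^2 k(1-k)}\,|\ln OR|$. The two-sided form is used so that the
power at $OR = 1$ equals the size $\alpha$ exactly and the curve is
symmetric in $OR \leftrightarrow 1/OR$; away from the null the second
term is negligible. The independent oracle is a logistic-regression
simulation: a genetic score explaining $R^2$ of a standard-normal
exposure, a logistic disease model, case-control sampling at the study's
case fraction, and a Wald test of the score coefficient.

### Mediation

The mediated proportion is the product-of-coefficients ratio
$\beta_{E\to M}\,\theta_M/\theta_E$ on the log-odds scale. The
exposure-to-mediator effect is an external, user-supplied input (for
body mass index acting through fasting insulin, a published effect of
roughly 0.15 SD/SD combined with the instrument estimates gives about one
fifth). No CI is attached by default; a parametric bootstrap percentile
interval is available when all three SEs are supplied.

## The synthetic-data generator

The generator emulates the two-sample structure directly at the
summary-statistic level — adequate because that is exactly what the
estimators consume; no individual-level genotypes are simulated (the
power oracle separately simulates individual-level logistic data). Per
SNP: an effect-allele frequency $f_j \sim U(0.1, 0.9)$; a per-allele
exposure effect $\gamma_j$ drawn half-normal and rescaled so
$\sum_j 2f_j(1-f_j)\gamma_j^2$ equals the target variance explained
exactly (effect alleles are exposure-increasing in the truth table;
observed coding is randomized separately); a direct outcome effect
$\alpha_j \sim N(\mu_\alpha, \sigma_\alpha^2)$ on a configured fraction of
SNPs, tied to instrument strength through a Gaussian copula when an
InSIDE violation is requested. Sampling noise follows the standard
approximations $\sigma_{x,j} = 1/\sqrt{2f_j(1-f_j)n_E}$ and
$\sigma_{y,j} = 1/\sqrt{2f_j(1-f_j)nk(1-k)}$. `scrambleCoding()`
randomizes allele order and strand per dataset (with audit columns
preserving the truth) and a configurable fraction of SNPs receives
palindromic allele pairs, so harmonization is exercised end to end.

Defaults are the conditions of the motivating study: exposure GWAS of
300,000, outcome GWAS of 10,784 cases / 20,406 controls, instrument
variance explained 9.5% (the body-mass-index instrument), true effect
$\ln(1.56)$.

What the generator does *not* emulate: LD between instrument SNPs
(instruments are pruned before estimation; LD matrices for pruning tests
are a separate block fixture), winner's curse in instrument discovery,
allele-frequency differences between the two samples, and genuine
case-control sampling artefacts. Passing tests therefore validate the
estimators and their contracts under the stated measurement model, not
robustness to those additional real-data features.

## Study conditions used by the validation suite

Problem sizes were chosen so each check is informative at a few minutes
of CPU:

- **Parameter recovery**: 500 replicates of a 100-SNP valid instrument at
  the default (study-scale) conditions; mean bias below 0.01 log-odds and
  profile-CI coverage within [92%, 98%].
- **Directional pleiotropy**: 200 replicates, 200 SNPs explaining 10% of
  variance, 30% invalid SNPs with direct effects
  $N(0.1, 0.02^2)$ log-odds per allele (about six times the mediated
  per-allele effect $\theta\bar\gamma \approx 0.016$), InSIDE holding.
  The sizing follows from the estimators' bias structure: the weighted
  median's contamination bias is *bounded* — with 30% of weight one-sided,
  it is the 0.5/0.7 quantile shift of the valid ratio distribution, about
  $0.57\sigma$ of the weighted ratio spread (~0.5 at these noise levels,
  dominated by the outcome study's size) — whereas the IVW bias grows
  linearly with the mean direct effect. The claimed contrast (median bias
  under half of IVW; Egger intercept rejecting in at least 80%) is the
  bounded-versus-linear gap, and only manifests once direct effects are
  several times the mediated effect. At milder pleiotropy all estimators
  are modestly and similarly biased.
- **MR-PRESSO null calibration**: 1000 replicates of a 50-SNP valid
  instrument at 1000 null simulations each; rejection at $\alpha = 0.05$
  within $0.05 \pm 0.02$ and a uniform p-value distribution.
- **Power oracle**: the analytic formula against the logistic simulation,
  12 grid points at a reduced total of 4000 with OR at most 1.15, agreeing
  within 2 percentage points plus twice the binomial Monte-Carlo SE at
  1500 replicates. The approximation is honest only for the
  moderate-per-SD-effect regime the method is used in: forcing mid-range
  power at a small sample requires per-SD odds ratios around 1.4, where
  the unmodelled covariate attenuation in the logistic model costs several
  percentage points (a known limitation, shared with the approximation's
  usual presentations).

## Numerical and design choices

- Strict inequalities at the filter boundaries, per the source
  conventions: $P$ exactly at $5\times10^{-8}$ is excluded; an info score
  just below 0.7 is excluded; a palindromic MAF strictly above 0.4 is
  excluded.
- The likelihood search interval, profile-CI bracketing (geometric step
  doubling before `uniroot`), and the boundary diagnostic are described
  above; optimization tolerance is $10^{-10}$.
- The weighted median interpolates; below the first (above the last)
  cumulative midpoint weight the extreme ratio is returned.
- Egger's residual dispersion floor of 1 prevents anti-conservative
  intercept tests in under-dispersed instruments.
- All Monte-Carlo procedures (weighted-median bootstrap, SIMEX, PRESSO,
  the generator) take explicit seeds and are bit-reproducible; add-one
  Monte-Carlo p-values avoid literal zeros.
- Degenerate inputs fail loudly and specifically: empty instruments
  signal rather than throw in the filter, but estimators refuse
  instruments below their minimum size (2 for likelihood/IVW, 3 for
  median/Egger, 4 for PRESSO); an all-equal exposure-effect design is a
  singularity error in Egger regression.

## Known limitations

- Proxy substitution reuses the proxy's own summary rows; no LD-aware
  effect reconstruction is attempted.
- The difference test between exposures assumes independent estimates
  although they share the outcome sample; treat its p-value as
  approximate (it is flagged in the output).
- The weighted median is not unbiased under one-sided contamination with
  non-vanishing per-SNP noise (see the bounded-bias argument above); its
  advantage over IVW is a bounded- versus unbounded-bias statement.
- The power approximation degrades for large per-SD effects at small
  outcome samples, as quantified above.

```{r example, eval = FALSE}
# end-to-end on synthetic data
cfg <- simConfig(nSNP = 100, thetaTrue = log(1.56), seed = 1,
                 scrambleCoding = TRUE)
sim <- simulateInstrument(cfg)
mrLikelihood(sim$instrument)
sensitivityTable(sim$instrument, nSim = 1000, nBoot = 1000, seed = 1)
```
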