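---
title: "Bias-corrected estimating equations for multivariable Mendelian randomization"
author: "mrbce"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bias-corrected estimating equations for multivariable Mendelian randomization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Multivariable Mendelian randomization (MVMR) estimates the direct causal
effects $\theta$ of $p$ exposures on an outcome from GWAS summary
statistics, using $m$ independent SNPs as instruments. On standardized
statistics — every estimate divided by its standard error, so all
quantities live on the z scale — the workhorse inverse-variance weighted
(IVW) estimator is ordinary least squares of the SNP–outcome associations
$\hat\alpha$ on the SNP–exposure associations $\hat B$:
$\hat\theta_{IVW} = (\hat B^\top\hat B)^{-1}\hat B^\top\hat\alpha$.

Both $\hat\alpha$ and $\hat B$ are *estimates*; their errors make IVW an
errors-in-variables regression. The resulting bias has two parts:

* **Weak-instrument (measurement-error) attenuation.** On the z scale each
  exposure column carries error variance $\approx 1$ per SNP, while the
  signal per SNP is roughly $n h^2 / m$ for instruments jointly explaining
  $h^2$ of an exposure with GWAS size $n$. When many moderate-effect SNPs
  are used, the signal-to-error ratio is small and IVW shrinks toward zero.
* **Sample-overlap bias.** When the exposure and outcome GWAS share
  individuals, the estimation errors of $\hat\beta_j$ and $\hat\alpha_j$
  are correlated (the correlation equals the shared-sample fraction times
  the phenotypic/residual correlation), and the bias acquires a component
  in the direction of the exposure–outcome confounding — it need not
  shrink toward zero, and null effects can be rejected far above the
  nominal rate.

## The estimator

The package solves a bias-corrected estimating equation. Writing
$\Sigma_{bb} = \mathrm{cov}(w_{\beta}),\ \sigma_{ba} =
\mathrm{cov}(w_\beta, w_\alpha),\ \sigma^2_{aa} = \mathrm{var}(w_\alpha)$
for the per-SNP z-scale error moments, the corrected score

$$S(\theta) = -\hat B^\top(\hat\alpha - \hat B\theta)
  - m(\Sigma_{bb}\theta - \sigma_{ba})$$

has expectation zero at the true $\theta$ despite the errors, and its root
is available in closed form:

$$\hat\theta = (\hat B^\top\hat B - m\Sigma_{bb})^{-1}
  (\hat B^\top\hat\alpha - m\sigma_{ba}).$$

This is the MRBEE estimator (`fitBEE()`). Its covariance is the sandwich
$\hat F^{-1}\hat V\hat F^{-1}/m$ with bread
$\hat F = \hat B^\top\hat B/m - \Sigma_{bb}$ and meat
$\hat V = m^{-1}\sum_j \hat S_j \hat S_j^\top$,
$\hat S_j = -(\hat\alpha_j - \hat\theta^\top\hat\beta_j)\hat\beta_j -
\Sigma_{bb}\hat\theta + \sigma_{ba}$. The printed forms of the bread and
meat admit more than one $1/m$ placement; we fix the one scaling under
which the sandwich is the covariance of $\hat\theta$ itself, and the test
suite validates it against the replication SD of the estimator in
simulation (agreement within a few percent). Comparators: `fitIVW()`
(plain OLS with a heteroskedasticity-robust covariance, so IVW and the
corrected estimator differ *only* in the bias correction), `fitDIVW()`
(corrects $\Sigma_{bb}$ only — the no-overlap special case), and
`fitIVWStar()` (plain IVW after pleiotropy removal).

### Where the error moments come from

`estimateErrorCovariance()` estimates the $(p+1)\times(p+1)$ error
covariance as the *uncentered* second moment $Z^\top Z/M$ of z-scores of
$M$ genome-wide insignificant (p > 0.05 for every phenotype),
LD-independent SNPs: such SNPs carry essentially no signal, so their
z-scores are draws from the error distribution. The moment is deliberately
uncentered, following the estimator's defining formula; null z-scores have
near-zero mean, so centering would change nothing material. If the
estimate is not positive semi-definite, eigenvalues are clipped at a small
floor (default `1e-10`) with a warning; diagonal entries outside
`[0.5, 2]` — implausible for z-score error variances — are flagged but
kept. `overlapInformedTerms()` provides the analytic counterpart when the
overlap structure is known (off-diagonal $(k,l)$ entry
$n_{ov}/\sqrt{n_k n_l}\,\rho_{kl}$), used as a cross-check in the tests.

A note on selection: in real data the p > 0.05 filter is part of the
published procedure and is applied by `selectNullSnps()`. Inside the
simulation engine the matched null variants are null *by construction*, so
no filter is applied there; truncating genuinely null z-scores at
|z| < 1.96 would bias the second moment downward by a factor of about
0.76.

## The pleiotropy test

Given a fitted $\hat\theta$, the residual $\hat\alpha_j -
\hat\beta_j^\top\hat\theta$ of each SNP tests $H_{0j}: \gamma_j = 0$ (no
horizontal pleiotropy). Its delta-method variance is
$\sigma^2_{aa} + \hat\theta^\top\Sigma_{bb}\hat\theta +
\hat\beta_j^\top\widehat{\mathrm{cov}}(\hat\theta)\hat\beta_j -
2\hat\theta^\top\sigma_{ba}$, and the squared residual over this variance
is $\chi^2(1)$ under the null (`pleioTest()`; calibration against
$\chi^2(1)$ is verified by KS test on $10^4$ simulated null SNPs).

`fitBEEIterative()` alternates fitting on the retained instruments with
re-testing **all** candidates at level $\tau$ (default Bonferroni
$0.05/m$, the same threshold that defines the IVW\* comparator), stopping
when the retained set stabilizes (default cap 30 iterations). Two open
choices were resolved as follows, both for idempotence: removal is never
permanent — a SNP flagged early is re-admitted if the refreshed fit no
longer rejects it — and the causal-estimate covariance entering the test
denominator is refreshed at every iteration rather than frozen at the
initial fit. Sequential-deletion schemes are path-dependent; the
stable-mask fixed point is not, and re-running the procedure on its own
output changes nothing (tested).

`genomeScan()` applies the test to every SNP genome-wide. This can detect
outcome loci invisible to the outcome GWAS itself (e.g. when an
exposure-mediated effect and a direct effect cancel). The inflation
diagnostic is $\lambda_{GC} = \mathrm{median}(S)/0.45494$. Loci are greedy
1-Mb windows seeded by the most significant remaining SNP below the
threshold (default $5\times10^{-8}$); LD-based pruning needs external
reference data and is deliberately out of scope, so windows are
distance-only. Each locus is classified by `classifyAssociation()` into
direct / exposure-mediated / pleiotropic-shared / novel-pleiotropic / null
from the outcome-GWAS, exposure-GWAS and pleiotropy p-values at a common
threshold.

## The simulation engine

The generator works at the individual level and then *regresses*, rather
than drawing summary statistics directly, so that weak-instrument error,
sample overlap and pleiotropy arise mechanically rather than by fiat.

Univariable design: genotypes are binomial(2, MAF) with MAF ~
Uniform(0.05, 0.50), columns standardized; per-SNP effects Uniform(−1, 1)
rescaled against the realized genotype covariance so the instruments
explain **exactly** $h^2$ (default 5%) of the exposure; confounder $U$
with variance $(1-h^2)\times 0.15$ enters exposure and outcome; exposure
noise completes unit exposure variance. The two-exposure design draws
effect pairs bivariate normal with correlation 0.45, gives each exposure
5% heritability, uses a shared confounder with variance
$(1-h^2)(0.15/2)^2$, and draws the two exposure noise terms jointly so the
realized phenotypic correlation is exactly 0.5 (their correlation is the
one quantity the variance budget leaves free; genetic covariance plus the
shared confounder alone cannot reach 0.5). Both designs close the outcome
variance budget at exactly 1 — the outcome noise variance is
$1 - \mathrm{var}(x^\top\theta + G\gamma + U)$, including the pleiotropy
term, so that on the z scale the estimand equals the generating $\theta$.
The default causal effects are 0.5 per exposure (the two-exposure design
is symmetric; only exposure 1 is evaluated).

**Pleiotropy contamination.** UHP effects are i.i.d. normal on a random
10% of instruments; CHP effects on a disjoint 10% correlate −0.5 with the
instrument strengths (univariable: with $\beta$; multivariable: built on
$-(\beta_1\theta_1+\beta_2\theta_2)$). Their scale is the one genuinely
free knob in the design: we set the per-SNP pleiotropy SD to
$2.5\sqrt{h^2/m}$ — 2.5 times the typical per-instrument effect scale —
chosen a priori from two requirements the method's own premises impose:
contaminated instruments must be individually detectable outliers at the
study sample sizes (per-SNP z-scale pleiotropy ≈ 6–10, noncentrality well
above the Bonferroni χ² cutoff, matching the depiction of UHP/CHP
instruments as clear departures from the causal line), and at
$m = 250$ weak instruments with full overlap the contamination plus
overlap bias must push IVW's false-positive rate past 20%, as reported for
that regime. A much weaker contamination would be undetectable by any
outlier test and would leave every estimator with the same small CHP bias
— a regime the validation figures contradict.

**Overlap.** Shared individuals, not injected error correlation: the
exposure GWAS uses individuals $1..n$; the outcome GWAS uses
$\mathrm{round}(f\,n)$ of them plus fresh individuals from the same
generative law. Per-SNP simple regressions produce (estimate, SE) pairs,
standardized to z on return. Matched null SNPs (zero effects, same
cohorts, same regressions) feed `estimateErrorCovariance()`.

### What the generator does and does not emulate

It reproduces weak instruments, overlap-correlated errors, confounding,
and UHP/CHP contamination with exact variance budgets. It does **not**
simulate LD between variants (independence is the design), binary-liability
outcomes, winner's-curse instrument selection, population structure, or
assortative mating. Passing tests therefore validate the estimating
equation, its sandwich, and the pleiotropy test under the stated designs —
not robustness to real-data pathologies outside them.

### Problem sizes and numerical choices

Replicated experiments in the tests and the acceptance script use
n = 30,000, m ∈ {100, 250}, 500–600 replicates, and M = 1000 matched null
SNPs per replicate. Contamination enters the univariable experiments (10%
UHP + 10% CHP); the two-exposure experiment relies on the genetic
correlation between exposures as its correlated-pleiotropy challenge, and
type-I calibration is evaluated in the uncontaminated null design (the standalone generator default is M = 10,000; at
M = 1000 the noise the error-covariance estimate adds to $\hat\theta$ is
already well below its sampling SD, and the sandwich SE matches the
replication SD to within ~2%). Null-calibration scans use n = 4,000 with
$3\times10^4$ genome SNPs. Other numerical choices: collinearity is an
error above condition number $10^{10}$ (mirroring the practice of
excluding exposures with instrument-estimate correlations above ~0.75);
the corrected matrix $\hat B^\top\hat B - m\Sigma_{bb}$ must keep its
smallest eigenvalue above $10^{-8}\,\mathrm{tr}/p$ — below that the fit
fails loudly rather than ridge-regularizing, since no regularized variant
is defined; PSD repair of $\hat\Sigma$ clips eigenvalues at $10^{-10}$;
p-values are floored at the smallest positive double; the χ²(1) median
constant in $\lambda_{GC}$ is 0.45494.

## Known limitations

* Confidence intervals are honest but wider than naive IVW's for weakly
  instrumented exposures; the correction trades variance for bias.
* Exposures with near-collinear instrument estimates cannot be jointly
  included (no high-dimensional extension here).
* Contaminated instruments that evade the outlier test (pleiotropy below
  the Bonferroni detection boundary — with normally distributed
  contamination, some always exist) leave small footprints inherent to any
  test-based removal: a residual bias proportional to the surviving
  effect–pleiotropy covariance (≈ −0.002 on a true effect of 0.5 in the
  univariable experiment here), extra between-replicate variability the
  sandwich cannot see (coverage ≈ 93% instead of 95% in the contaminated
  two-exposure design), and a type-I rate of ≈ 7% instead of 5% under
  contaminated nulls.
* The error-covariance estimate assumes the null panel is LD-independent
  and genuinely null; that contract is the caller's in real data.
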