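---
title: "Two-sample Mendelian randomization with correlated variants: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample Mendelian randomization with correlated variants: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corrmr)
```

## The problem

Mendelian randomization (MR) uses germline genetic variants as instrumental
variables to estimate the causal effect of a modifiable exposure (here, the
motivating application is circulating selenium, in SD units) on a disease
outcome (a binary trait on the log-odds scale), from observational data. In
the two-sample design, the per-SNP gene–exposure associations
$(\hat\beta_{Xj}, \sigma_{Xj})$ and gene–outcome associations
$(\hat\beta_{Yj}, \sigma_{Yj})$ come from separate, non-overlapping GWAS
samples and are combined at the summary level. When instrument SNPs are in
linkage disequilibrium (LD), their sampling errors are correlated, and an
estimator that ignores this overstates precision; `corrmr` therefore works
throughout with a *signed* pairwise LD correlation matrix $\rho$.

## Estimation model

The maximum-likelihood model (`mr_ml_correlated()`) treats the observed
summary vectors as

$$\hat\beta_X \sim \mathrm{MVN}(\xi,\ \Sigma_X), \qquad
  \hat\beta_Y \sim \mathrm{MVN}(\theta\,\xi,\ \Sigma_Y),$$

independent of each other (two-sample design; no cross-trait covariance),
with $\Sigma_{X,jk} = \sigma_{Xj}\sigma_{Xk}\rho_{jk}$ and analogously for
$\Sigma_Y$. The assumptions inherited from instrumental-variable analysis
are the usual three: the SNPs are reliably associated with the exposure,
independent of confounders of the exposure–outcome relation, and affect the
outcome only through the exposure (exclusion restriction; the simulator's
`pleiotropy` knob exists precisely to study violations of this one).

For fixed $\theta$ the nuisance vector $\xi$ has a closed-form generalized
least squares solution,
$(\Sigma_X^{-1} + \theta^2 \Sigma_Y^{-1})\,\hat\xi
  = \Sigma_X^{-1}\hat\beta_X + \theta\,\Sigma_Y^{-1}\hat\beta_Y$,
so $\xi$ is profiled out and the optimization is one-dimensional in
$\theta$. We chose profiling over joint $(k+1)$-dimensional optimization
because it is exactly equivalent at the maximum, numerically robust, and
makes the likelihood surface easy to audit (the returned object carries the
profile function itself). The 1-D search uses R's `optimize()`
(golden-section with Brent-style parabolic refinement) on the bracket
$\hat\theta_{IVW} \pm 10\,\mathrm{se}_{IVW}$, expanded geometrically if the
maximum lands on an edge, to tolerance $10^{-8}$. The standard error is the
inverse square root of the negated curvature of the profile log-likelihood
at the maximum, computed by a central finite difference with step
$10^{-4}\max(|\hat\theta|, 1)$ — the observed-information analogue for the
profiled parameter.

The closed-form cross-check (`mr_ivw_correlated()`) is the generalized
weighted regression of $\hat\beta_Y$ on $\hat\beta_X$ through the origin
with weight matrix $\Omega^{-1}$, $\Omega_{jk} =
\sigma_{Yj}\sigma_{Yk}\rho_{jk}$:
$\hat\theta = (\hat\beta_X^\top \Omega^{-1}\hat\beta_Y) /
(\hat\beta_X^\top \Omega^{-1}\hat\beta_X)$. It treats the exposure betas as
fixed, so it coincides with the ML estimate in the limit
$\sigma_X \to 0$ — a limit the test suite checks numerically, alongside a
brute-force grid-search oracle for the ML maximum and a whitened-`lm()`
oracle for the IVW closed form. With one SNP both reduce to the Wald ratio
$\hat\beta_Y/\hat\beta_X$ with delta-method standard error
$\sigma_Y/|\hat\beta_X|$.

Confidence intervals are normal-approximation with multiplier 1.959964,
and p-values are two-sided standard-normal tail probabilities of
$\hat\theta/\mathrm{se}$.

## Dose scaling

Genetic effects are estimated per SD of exposure. To express results per a
trial-equivalent increment (the motivating example: 114 ug/L of circulating
selenium, the blood-selenium contrast achieved by supplementation in the
SELECT trial), `scale_to_dose()` multiplies $\hat\theta$, its SE and CI by
`dose / exposure_sd` and exponentiates to an odds ratio. `exposure_sd` — the
native-unit SD corresponding to one unit of the exposure betas — has *no
default*: it is a property of the exposure GWAS's measurement scale that the
user must supply, and the report records it prominently. The z statistic and
p-value are invariant to this linear rescaling.

## Instrument construction and strength

`select_instrument()` applies a strict `p < 5e-8` genome-wide significance
filter, optionally restricted to SNPs replicated at `p < .05` in an
independent study. `prune_ld()` performs greedy pruning: repeatedly keep the
smallest-p SNP and discard remaining SNPs with squared correlation above the
threshold; ties in p are broken by rsid lexicographic order so the result is
deterministic and order-invariant.

Per-SNP variance explained uses $2\beta^2 f(1-f)$ when the effect-allele
frequency $f$ is available (valid for betas in SD units), else the
t-statistic form $t^2/(t^2 + n - 2)$; the form used is recorded per SNP.
Total instrument $R^2$ is approximated by summing lead SNPs at independent
loci under two LD thresholds ($r^2 \le .01$ and $\le .05$), reported as a
range, and the strength F-statistic uses the multi-allelic-score form
$F = R^2 (n - k - 1) / (k (1 - R^2))$ with the $k$ belonging to that
threshold's pruned set. Published analyses in this design report ranges
computed exactly this way; with each threshold's own $k$, the two F values
need not be ordered the same way as the two $R^2$ values.

## Harmonization

Outcome associations are aligned to the exposure's effect allele: swapped
allele labels negate the outcome beta and reflect its eaf; pairs that
neither match nor swap are dropped (`allele-mismatch`), and SNPs absent from
the outcome GWAS are dropped (`unavailable`) — every drop and flip is logged
with a machine-readable reason code. Palindromic (A/T, C/G) SNPs cannot be
oriented from labels; under the default policy they are kept only when both
traits' eafs lie strictly on the same side of 0.5 *and* outside the
ambiguity window [0.42, 0.58]. Opposite-side eafs are dropped rather than
strand-flipped: for a palindromic SNP an apparent frequency mismatch cannot
be distinguished from a population-frequency difference, so flipping on that
evidence risks silently negating a true effect. Missing eaf disables
palindrome resolution (and the frequency form of $R^2$). Matching is by
rsid only; genomic coordinates are never consulted.

Correlation and covariance matrices are validated (symmetry, unit diagonal,
entries in $[-1,1]$) and, when the smallest eigenvalue falls below
$10^{-8}$, regularized by a logged diagonal ridge of
$10^{-8} - \lambda_{\min}$ — the same rule for the LD matrix and for
$\Sigma_X$, $\Sigma_Y$.

## The synthetic-data generator

No consortium-scale selenium, prostate-cancer or diabetes summary
statistics are redistributable at desk scale, so the generator stands in
for them, with defaults fixed once to mirror that study geometry:

* `k = 11` instrument SNPs with minor-allele frequencies spread over
  0.10–0.50;
* mild LD: a Markov-type correlation matrix whose neighbour correlations
  cycle through 0.25/0.15/0.05 (all $|r| \le 0.3$; squared values straddle
  both conventional pruning thresholds, so the two thresholds genuinely
  differ);
* `n_exposure = 9639` (the scale of the blood + toenail selenium GWAS
  meta-analysis) with per-allele effects `xi` calibrated so the instrument
  explains ~3.5% of exposure variance — inside the 2.5–5.0% range reported
  for the primary selenium instrument — split evenly across SNPs;
* `n_outcome = 72729` with case fraction 44825/72729 (the prostate-cancer
  consortium geometry) and a causal log-odds effect `theta` per exposure SD
  (0.2 where a non-null value is needed);
* optional per-SNP direct (horizontally pleiotropic) log-odds effects.

*Summary-level* mode draws the two beta vectors directly from the MVN model
above with analytic standard errors
$\sigma_{Xj} = (2 f_j (1-f_j)\, n_X)^{-1/2}$ and
$\sigma_{Yj} = (2 f_j (1-f_j)\, n_Y\, c(1-c))^{-1/2}$ ($c$ the case
fraction) — fast, and exact with respect to the estimators' model.
*Individual-level* mode generates genotypes by thresholding correlated
normal latents at the maf quantile (two haplotypes per individual,
Hardy–Weinberg assumed), solving for the latent correlation that induces
the target allele-level LD; a continuous exposure whose *marginal*
per-allele effects equal `xi` (conditional effects are solved from the
genotype covariance, residual variance set so the exposure has unit
variance); and a Bernoulli outcome through a logistic model whose intercept
is solved numerically to hit the configured prevalence. Per-SNP statistics
come from per-variant `lm()`/`glm()` fits on disjoint samples, and the
reported LD is the empirical genotype correlation. The threshold generator
only approximates the target LD (tested at tolerance 0.05), and
individual-level mode is capped at 50 000 individuals total — it is an
end-to-end realism check, not a consortium emulator.

What passing tests on these data do and do not show: the generator draws
from exactly the model the estimators assume (no population stratification,
no relatedness, no allele-frequency misspecification, exact rsid matching,
no winner's curse in effect sizes), so calibration results here bound what
real data can achieve rather than demonstrating it.

## Problem sizes and numerical choices

Monte-Carlo checks in the test suite use 1000 summary-level replicates for
calibration (bias, CI coverage, type-I error), 120–200 replicates where
individual-level generation is involved, and 5–20 seeded instances for the
oracle and limiting-equivalence checks; the acceptance script recomputes
calibration at 500 replicates. These sizes put Monte-Carlo error well below
the property bands they are tested against while keeping a full run in the
tens of seconds.

Degenerate inputs are handled explicitly: zero exposure beta fails the Wald
ratio; a singular $\Omega$ or $\Sigma$ beyond the ridge is an estimation
error; an empty instrument after filtering is an instrument error; rows
with non-positive SE, invalid alleles or out-of-range frequencies are
rejected at read time with line-numbered reasons. A reported p-value that
disagrees with $|\beta/\mathrm{se}|$ by more than 10% relative on the z
scale warns but does not reject.

## Known limitations

* **Finite-sample anti-conservatism at modest instrument strength.** With
  the default study geometry (per-SNP exposure |z| around 5.5 — i.e. SNPs
  near the genome-wide significance boundary), the profile-likelihood Wald
  test is slightly anti-conservative under the null: across repeated
  1000-replicate batches the empirical type-I error at nominal 5% ranges
  from about 5% to 7%, with the reported SE ~5% below the empirical
  sampling SD and mildly heavy-tailed z. This vanishes as the exposure GWAS
  grows (at 20 times the sample size the same code rejects at 5.0%), so it
  is a weak-instrument finite-sample property of the Wald construction,
  not an implementation artifact. CI coverage at a non-null effect
  ($\theta = 0.2$) is nominal (≈96%).
* First-order Wald/IVW standard errors ignore exposure-side uncertainty by
  construction; the ML model accounts for it in the point estimate and
  likelihood curvature but still relies on asymptotic normality of
  $\hat\theta$.
* No pleiotropy-robust estimators (MR-Egger, weighted median/mode), no
  heterogeneity statistics, no sample-overlap correction, no proxy-SNP
  lookup or liftover: out of scope by design.
* Trial comparison columns in the concordance report are user-supplied
  display values only; the package never recomputes trial results.
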