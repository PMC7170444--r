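---
title: "Liability-threshold twin models for binary phenotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Liability-threshold twin models for binary phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinpath)
```

## The model

twinpath analyses binary twin data on the liability scale. Each binary
phenotype (here the running example uses three: common mental disorder,
CMD; multi-site pain, Pain; and long-term sickness absence or disability
pension, SADP) is assumed to arise from a latent standard-normal liability
that is dichotomized at a threshold $\tau$: an individual is affected when
liability $> \tau$. Binary data identify only the correlation/threshold
parameterization, so every model in the package works on a standardized
scale where each trait's total liability variance is exactly 1 and the
thresholds are free parameters per trait and sex.

Twin resemblance decomposes the liability into additive genetic (A),
dominance genetic (D) or shared environmental (C), and nonshared
environmental (E) components. Co-twins correlate $r_A = 1$ (MZ) or $0.5$
(DZ) on A, $r_D = 1$ or $0.25$ on D, $r_C = 1$ on C, and $0$ on E. For a
$k$-trait model with component loading matrices $\Lambda_X$ (so the
within-twin covariance from component X is $\Lambda_X \Lambda_X^\top$),
the pair of liability vectors for a zygosity group is multivariate normal
with

$$\Sigma_\text{pair} \;=\;
\begin{pmatrix} \Sigma_w & \Sigma_x \\ \Sigma_x^\top & \Sigma_w \end{pmatrix},
\qquad
\Sigma_x = r_A\,\Sigma_A + r_D\,\Sigma_D + r_C\,\Sigma_C .$$

For opposite-sex DZ pairs the two within-twin blocks use the sex-specific
loadings and the cross block combines female loadings on one side with
male loadings on the other (quantitative sex limitation: the same factors
act in both sexes with possibly different magnitudes; the cross-sex
relatedness constants default to 0.5/0.25 and are held fixed).

Three multivariate structures are supported, in decreasing order of
parameters for $k = 3$:

* **Cholesky**: triangular $\Lambda_X$ per component — the saturated
  biometric covariance structure (15 loading parameters with A, D, E).
* **Independent pathway**: one common factor per component plus
  trait-specific factors (also 15 for $k = 3$; a genuinely different,
  non-nested shape).
* **Common pathway**: a single latent phenotype, itself decomposed as
  $a_c^2 + d_c^2 + e_c^2 = 1$, carries *all* cross-trait covariance via
  factor loadings $\lambda_i$, with trait-specific A/D/E residuals
  (11 loading parameters — the most parsimonious).

## Estimation

All fitting is full-information maximum likelihood over joint response
patterns: for each zygosity group the $2^{2k}$ pattern counts are the
sufficient statistic, and each pattern probability is the multivariate
normal rectangle probability of $\Sigma_\text{pair}$ between the
thresholds. Two integration engines are used:

* a **reference path** used by `patternProbabilities()`: the pair
  structure is conditioned on the family-shared factors (the factors of
  $\Sigma_x$), under which the two twins are independent; each twin's
  conditional orthant probability is computed exactly with bivariate and
  trivariate normal CDFs, and the outer ($\le 3$-dimensional) integral
  uses a Gauss–Hermite grid refined (12, 16, 24, 32 points per dimension)
  until no pattern changes by more than `tol` (default 1e-8). Because the
  per-node twin probabilities always sum to one, the 64 pattern
  probabilities are nonnegative and sum to 1 to machine precision at any
  grid size.
* a **fast path** inside `fitBiometric()`: the same conditioning, but the
  residual within-twin covariance is additionally split into at most two
  common factors plus a diagonal, so the innermost terms are products of
  univariate normal CDFs. With the default 8-point grids the pattern
  error is below about $3\times10^{-5}$ (checked against the reference
  path and against mvtnorm in the tests). When the residual covariance's
  smallest eigenvalue drops below `deltaMin` (0.04), the exact
  conditional-CDF path is used instead, so near-singular E structures do
  not degrade the quadrature.

Univariate (single-trait) likelihoods need only bivariate normal
rectangles and are computed exactly.

Identification is handled by *exact rescaling inside the likelihood*: raw
loadings are divided by each trait's implied standard deviation, so unit
variance holds identically and variance components are squared loadings
(hence nonnegative — no negative-variance anomalies; solutions with a
component variance near zero are flagged `boundary`). The resulting flat
ray in raw-parameter space is pinned by a quadratic penalty on the raw
variance that vanishes at the optimum and therefore cannot bias the
estimates. Optimization is L-BFGS-B with forward-difference gradients, in
two phases for multivariate models (a coarse 5-point grid to approach the
optimum, then the 8-point grid to converge; relative objective tolerance
1e-7). Starting values are correlation-informed: tetrachoric intraclass
and cross-twin cross-trait matrices are converted to method-of-moments
component covariances ($\hat\Sigma_A = 4R_{DZ} - R_{MZ}$, etc.),
projected to positive semidefiniteness and factorized per family; the
default five starts add deterministically jittered copies. On simulated
cohorts the informed start is close enough that jittered restarts
reproduce the same optimum, so the replicate experiments in the tests and
the acceptance script use a single start to keep their run time
proportionate. Reported loadings are canonicalized to a nonnegative
leading entry per factor column (the likelihood is invariant to whole-
column sign flips).

Model comparison uses AIC and BIC with the twin pair as the independent
sampling unit for BIC ($n$ = pairs; a documented `bicUnits` switch counts
individuals instead). Univariate fits use all five zygosity groups
jointly; multivariate fits are per sex on MZ + same-sex DZ pairs, with a
documented option for a joint two-sex fit under equated loadings.
Sex-equality testing equates path loadings across sexes while leaving
thresholds sex-specific, because prevalences differ by sex by design and
equating thresholds would confound mean and variance differences.

## Tetrachoric correlations

`tetrachoricMLE()` estimates the latent correlation and both thresholds
jointly by full ML (matching the likelihood used in fitting). For 2x2
tables with all cells positive this coincides with fixing thresholds at
the margin quantiles (the model is saturated); tables with an empty cell
leave a flat ridge in the joint parameter space, where the constrained
convention is used — margin-quantile thresholds, correlation profiled and
settled at the ±0.999 boundary when the profile is flat, flagged
`boundary`. Intraclass estimates for same-sex groups double-enter each
pair (both orders), which forces threshold symmetry; the standard error
is widened by $\sqrt 2$ because the information of duplicated records is
halved. Opposite-sex pairs are never double-entered: the female twin is
always twin 1 by the cohort's ordering convention, and the two
cross-trait orientations (female trait A x male trait B, and the
reverse) are genuinely different estimands under sex-specific parameters,
so both are reported rather than averaged.

## The cohort simulator

`simulateCohort()` draws pair liabilities from the model-implied
$\Sigma_\text{pair}$ and thresholds them (affected strictly above the
threshold — a zero-probability boundary, convention only). Every zygosity
group has its own random stream derived deterministically from the root
seed, so resizing or adding a group never perturbs the others. The
simulator emulates the design of a register-linked twin survey: five
zygosity-by-sex groups, sex-specific prevalences, binary traits from
thresholded correlated liabilities. It does *not* emulate measurement
error or instrument differences between survey waves, age effects on
thresholds, non-response, or event-time structure in the follow-up
outcome — passing tests therefore show that the estimators recover the
generating biometric structure, not that those survey-specific nuisances
are handled.

`presetSpec()` provides ready-made generating models. Two carry the
published point estimates of the motivating analysis: the women's
common-pathway model (latent loadings 0.81/0.29/0.51; factor loadings
0.40, 0.54, 0.66 on CMD, Pain, SADP) and the men's Cholesky model
(additive paths 0.25/0.51 onto Pain and 0.34/0.20/0.52 onto SADP).
Loadings that were never printed (specific variances, the men's CMD and
dominance paths, the E matrix) are plausible fill-in values chosen once:
specific variance is split so roughly half of each trait's total variance
is unique environmental — the qualitative pattern the published variance
breakdown shows — with no specific dominance for SADP. Prevalences
default to 25/45/14% (women) and 15/38/8% (men) for CMD/Pain/SADP,
realistic for a working-age population with these definitions. These
fill-ins are documented as non-printed values; nothing downstream treats
them as estimates.

Two further presets exist purely for method experiments.
`selection_cholesky` is designed for model-selection studies: its
additive-genetic covariance is deliberately three-dimensional (strong
CMD–Pain and CMD–SADP genetic correlations, near-zero Pain–SADP), which
no one-common-factor or single-latent-phenotype structure can reproduce
— a one-factor solution would need a Heywood case. This matters because
for three traits the independent-pathway model can exactly mimic *any*
one-factor-representable component covariance at the same parameter
count as the Cholesky, making "which family generated the data" an
ill-posed question for such structures. `selection_independent` is an
unremarkable one-common-factor-per-component generator.

## Decomposition arithmetic and rounding

The reported quantities are simple functions of the standardized
loadings: the latent factor's variance decomposition $(a_c^2, d_c^2,
e_c^2)$; per-trait common shares $a_c^2\lambda_i^2$ etc. plus squared
specific loadings (summing to 1); Cholesky factor shares
$L_{ij}^2 / \sum_j L_{ij}^2$ of a trait's component variance; component
correlations $\mathrm{cov}_X(a,b)/\sqrt{\mathrm{var}_X(a)\,
\mathrm{var}_X(b)}$; and covariance shares
$\mathrm{cov}_X(a,b)/\sum_X \mathrm{cov}_X(a,b)$. Report percentages are
rounded half away from zero (base R's `round()` rounds to even, which
does not reproduce conventional report formatting); raw proportions are
always retained alongside. Undefined cases (zero component variance, zero
total covariance) return `NA` with an explicit flag rather than a number.

```{r worked}
women <- presetSpec("women_common_pathway")
latentFactorDecomposition(women)$percent
varianceBreakdown(women, "SADP")@percent
choleskyGeneticShares(presetSpec("men_cholesky"), "SADP")$percent
```

## Numerical choices and degenerate inputs

* MVN integration: deterministic quadrature throughout (no randomized
  integration in the likelihood), so every fit and probability is exactly
  reproducible; the only randomized integrator (`mvtnorm`'s Genz–Bretz
  rule) is used for marginal rectangles of partially observed pairs and
  for heterogeneous opposite-sex multivariate structures, with a pinned
  RNG state.
* Pattern probabilities below 1e-300 are floored, with a warning — a
  guard against log(0), not a modelling device.
* Empty zygosity groups yield all-zero contingency tables; empty cohorts
  yield log-likelihood 0; degenerate 2x2 margins yield `NA` correlations
  with the threshold of the non-degenerate margin still reported.
* Missing phenotypes: contingency tables are pairwise-complete per trait
  subset; `logLikelihood(..., includeIncomplete = TRUE)` adds marginal
  rectangle probabilities over the observed entries of partially observed
  pairs. Both behaviors exist because a survey cohort can contain more
  respondents than complete pairs; neither is asserted as the only
  defensible choice.
* Model-selection tie-breaks: AIC ranks; when BIC disagrees, both winners
  are reported and the more parsimonious is designated best — the
  dual-criterion language of standard practice without inventing a
  sharper rule.

## Problem sizes used in the test-suite experiments

The replicate experiments run at 20,000 pairs per same-sex group with 20
replicates per scenario (parameter recovery and AIC selection for the
three multivariate families; BIC/AIC sex-limitation calibration and
power), 50,000 pairs per group for the univariate correlation-limit
checks, 50 random tables for the tetrachoric oracle comparison, and a
$10^7$-draw Monte-Carlo oracle for the trivariate pattern probabilities.
These sizes give Monte-Carlo error well inside each check's tolerance
(e.g. ±0.02 on a tetrachoric at 50,000 pairs) while keeping a full run
proportionate.

## Known limitations

* C and D are never estimated together (not identifiable from twins
  reared together); the qualitative sex-limitation model (sex-specific
  genetic factors, estimated cross-sex relatedness) is representable in
  the generator via `rAos` but not estimated.
* Dominance variance is weakly identified at realistic sample sizes; in
  recovery experiments the latent dominance share is regularly shrunk
  toward its boundary in individual replicates. Under the
  independent-pathway structure the effect is strongest: the likelihood
  is nearly flat along directions that trade common-A against common-D
  and specific-D variance, so loading-level recovery of an ADE
  independent-pathway model is not achievable at these sizes (the MLE
  attains a better likelihood than the generating parameters while
  differing substantially in the A/D split). The shipped
  independent-pathway experiment generator is therefore an AE structure,
  like the Cholesky selection generator.
* AIC selection between the common-pathway model and the (more richly
  parameterized) Cholesky is intrinsically narrow-margin when the
  common-pathway model is true: the expected AIC gap is
  $2\,\Delta k - E[\chi^2_{\Delta k}] = \Delta k$, so single replicates
  can prefer the larger model; conclusions should rest on replicate
  majorities, as the tests do.
* No covariate effects on thresholds (age, birth cohort), no ordinal
  extension, no event-time modelling of the follow-up outcome.
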