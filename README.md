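# twinpath

Liability-threshold twin models for binary phenotypes.

## What this is for

Classical twin studies ask how much of the variation in a trait — and of
the *covariation* between traits — is genetic, by comparing monozygotic
(MZ) twins, who share all segregating genes, with dizygotic (DZ) twins,
who share half on average (a quarter for dominance effects). When the
traits are binary (a diagnosis, a register event), the analysis moves to
the **liability scale**: each phenotype reflects a latent standard-normal
liability dichotomized at a threshold, and twin resemblance is measured by
tetrachoric correlations and modelled with multivariate normal
integration.

twinpath implements that full workflow for epidemiologists and
behaviour-genetics researchers, motivated by the study design linking
common mental disorders (CMD), multi-site pain, and later long-term work
disability (sickness absence / disability pension, SADP) in a
population-based twin cohort with five zygosity-by-sex groups (MZ female,
MZ male, DZ female, DZ male, DZ opposite-sex):

* **Tetrachoric correlations** — phenotypic (within individual),
  intraclass (cross-twin same-trait) and cross-twin cross-trait, by
  zygosity group, with double entry for same-sex pairs and both
  orientations for opposite-sex pairs.
* **Univariate biometric models** (ACE / ADE / AE / CE / E) for binary
  traits by full-information maximum likelihood, with quantitative
  sex-limitation tests anchored by opposite-sex DZ pairs.
* **Trivariate Cholesky, independent-pathway and common-pathway models**
  per sex, AIC/BIC model selection.
* **Decomposition** of the winning model into the quantities such studies
  report: the latent shared liability's A/D/E split, common vs specific
  variance per trait, per-factor shares of a trait's genetic variance,
  genetic and environmental correlations, covariance shares.
* A **cohort simulator** that generates twin data under any of these
  models (the liability-threshold generative process itself), plus a
  pipeline (`runAnalysis`) that runs descriptives → correlations →
  univariate selection → multivariate selection → decomposition with a
  seed-reproducible output bundle.

The central model: for component loading matrices $\Lambda_A, \Lambda_D,
\Lambda_E$ (within-twin covariance $\Sigma_X = \Lambda_X \Lambda_X^T$,
total liability variance standardized to 1 per trait), a twin pair's
liabilities are multivariate normal with cross-twin covariance
$r_A \Sigma_A + r_D \Sigma_D$, where $(r_A, r_D)$ is $(1, 1)$ for MZ and
$(0.5, 0.25)$ for DZ pairs. Pattern probabilities are MVN rectangle
integrals of that structure; the fit maximizes the multinomial likelihood
of the observed response-pattern counts.

## Worked example

Simulate a cohort from the women's common-pathway structure (latent
liability loadings 0.81 / 0.29 / 0.51 for A / D / E; factor loadings
0.40, 0.54, 0.66 on CMD, Pain, SADP), fit the three multivariate
families, and decompose the winner:

```r
library(twinpath)

spec <- presetSpec("women_common_pathway")
co   <- simulateCohort(spec, c(MZ_F = 20000, DZ_F = 20000), seed = 21)

fits <- lapply(c("common_pathway", "cholesky", "independent_pathway"),
               fitBiometric, cohort = co, sex = "F")
compareFits(fits)[, c("model", "minus2LnL", "nParams", "aic", "bic")]
#>                 model minus2LnL nParams      aic      bic
#> 1      common_pathway  254339.2      14 254367.2 254487.6
#> 2            cholesky  254332.0      18 254368.0 254522.7
#> 3 independent_pathway  254333.2      18 254369.2 254523.9

latentFactorDecomposition(fits[[1]])$percent
#>  A  D  E
#> 68  5 27
```

The comparison table shows the common-pathway model winning on AIC (and
clearly on BIC): the Cholesky fits the data slightly better (−2lnL lower
by 7.2) but pays for four extra parameters. The decomposition says that at
this replicate about 68% of the latent shared liability's variance is
estimated as additive genetic, 5% as dominance genetic (weakly identified
at this sample size) and 27% as nonshared environmental. The generating
values are reproduced exactly from the spec itself:

```r
latentFactorDecomposition(spec)$percent
#>  A  D  E
#> 66  8 26
varianceBreakdown(spec, "SADP")@percent[["common_A"]]
#> [1] 29
choleskyGeneticShares(presetSpec("men_cholesky"), "SADP")$percent
#> factor1 factor2 factor3
#>      27       9      63
```

— i.e. 66/8/26% of the latent factor from A/D/E; 29% of SADP's variance
from common additive genes; and, in the men's Cholesky model, 27% / 9% /
63% of SADP's genetic variance attributable to genetic factors shared
with CMD, shared with Pain, and unique to SADP.

See the vignette (`vignettes/twin-liability-models.Rmd`) for the model,
estimation details, and the design of the simulation experiments.

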