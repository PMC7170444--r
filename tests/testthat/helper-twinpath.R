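## Shared fixtures and independent oracles, built in code.

adeSpec <- function(a2 = 0.5, d2 = 0.2, e2 = 0.3, prevF = 0.25,
                    prevM = prevF, trait = "CMD") {
  biometricSpec("univariate_ADE", trait,
                paramsF = list(a = sqrt(a2), d = sqrt(d2), e = sqrt(e2)),
                prevalencesF = prevF, prevalencesM = prevM)
}

aeSpec <- function(a2F, a2M = a2F, prevF = 0.25, prevM = 0.15,
                   trait = "CMD") {
  biometricSpec("univariate_AE", trait,
                paramsF = list(a = sqrt(a2F), e = sqrt(1 - a2F)),
                paramsM = list(a = sqrt(a2M), e = sqrt(1 - a2M)),
                prevalencesF = prevF, prevalencesM = prevM)
}

tinyPairs <- function() {
  data.frame(pairId = c("p1", "p2", "p3"),
             zygosity = c("MZ_F", "DZ_M", "DZ_OS"),
             sex1 = c("F", "M", "F"), sex2 = c("F", "M", "M"),
             CMD_1 = c(1, 0, 1), CMD_2 = c(1, 1, 0),
             stringsAsFactors = FALSE)
}

## Independent lattice-search tetrachoric oracle: thresholds fixed at the
## margin quantiles, correlation maximizing the multinomial likelihood over
## a 0.001 grid, cell probabilities from mvtnorm (exact bivariate code).
latticeTetrachoric <- function(tab, step = 0.001) {
  n <- sum(tab)
  tauR <- qnorm(sum(tab[1, ]) / n)
  tauC <- qnorm(sum(tab[, 1]) / n)
  grid <- seq(-0.999, 0.999, by = step)
  ll <- vapply(grid, function(r) {
    p00 <- mvtnorm::pmvnorm(upper = c(tauR, tauC),
                            corr = matrix(c(1, r, r, 1), 2),
                            algorithm = mvtnorm::TVPACK(1e-12))
    p <- c(p00, pnorm(tauC) - p00, pnorm(tauR) - p00,
           1 - pnorm(tauR) - pnorm(tauC) + p00)
    p <- pmax(p, 1e-12)
    tab[1, 1] * log(p[1]) + tab[2, 1] * log(p[2]) +
      tab[1, 2] * log(p[3]) + tab[2, 2] * log(p[4])
  }, numeric(1))
  grid[which.max(ll)]
}

## Independent MVN rectangle oracle for a full 2k-dim pattern probability
## (randomized Genz-Bretz integration at tight tolerance, pinned RNG).
gbPatternOracle <- function(spec, group, abseps = 1e-8) {
  S <- expectedStructure(spec, group)
  k <- length(traitNames(spec))
  sexes <- if (group == "DZ_OS") c("F", "M") else
    rep(substr(group, nchar(group), nchar(group)), 2)
  tau <- c(thresholds(spec, sexes[1]), thresholds(spec, sexes[2]))
  nm <- names(patternProbabilities(spec, group))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  vapply(nm, function(pat) {
    bits <- as.integer(strsplit(gsub("|", "", pat, fixed = TRUE), "")[[1]])
    lo <- ifelse(bits == 1, tau, -Inf)
    hi <- ifelse(bits == 1, Inf, tau)
    set.seed(4242)
    as.numeric(mvtnorm::pmvnorm(lower = lo, upper = hi, corr = S,
                                algorithm = mvtnorm::GenzBretz(
                                  abseps = abseps, maxpts = 500000L)))
  }, numeric(1))
}

## Squared standardized loadings of a spec/fit, flattened for recovery
## error measurement (canonical orientation assumed on both sides).
squaredLoadings <- function(spec, sex = "F") {
  pars <- if (sex == "F") spec@paramsF else spec@paramsM
  unlist(lapply(pars, function(x) {
    if (is.matrix(x)) x[lower.tri(x, diag = TRUE)]^2 else as.numeric(x)^2
  }))
}
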