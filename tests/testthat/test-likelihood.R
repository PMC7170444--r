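test_that("pure-E pattern probabilities factor into independent margins", {
  e <- biometricSpec("univariate_E", "CMD", paramsF = list(e = 1),
                     prevalencesF = 0.3)
  tau <- qnorm(0.7)
  p <- patternProbabilities(e, "MZ_F")
  expect_equal(p[["1|1"]], (1 - pnorm(tau))^2, tolerance = 1e-12)
  expect_equal(p[["0|1"]], pnorm(tau) * (1 - pnorm(tau)), tolerance = 1e-12)
})

test_that("pattern probabilities are nonnegative and sum to 1", {
  for (sc in c("women_common_pathway", "men_cholesky")) {
    sp <- presetSpec(sc)
    for (g in c("MZ_F", "DZ_F", "DZ_OS")) {
      p <- patternProbabilities(sp, g)
      expect_length(p, 64)
      expect_true(all(p >= 0))
      expect_lt(abs(sum(p) - 1), 1e-6)
    }
  }
})

test_that("quadrature pattern probabilities agree with the mvtnorm oracle", {
  sp <- presetSpec("women_common_pathway")
  for (g in c("MZ_F", "DZ_F")) {
    p <- patternProbabilities(sp, g)
    oracle <- gbPatternOracle(sp, g)
    expect_lt(max(abs(p - oracle)), 5e-6)
  }
})

test_that("the fast fitting engine tracks the reference probabilities", {
  sp <- presetSpec("men_cholesky")
  for (g in c("MZ_M", "DZ_M")) {
    fast <- twinpath:::.groupPatternProbs(sp, g)
    ref <- patternProbabilities(sp, g)
    expect_lt(max(abs(fast - ref)), 1e-4)
  }
})

test_that("pattern probabilities match brute-force Monte-Carlo frequencies", {
  sp <- presetSpec("women_common_pathway")
  S <- expectedStructure(sp, "DZ_F")
  tau <- rep(thresholds(sp, "F"), 2)
  n <- 1e6
  set.seed(71)
  Z <- matrix(rnorm(n * 6), n, 6) %*% chol(S)
  idx <- as.integer((t(t(Z) > tau) * 1) %*% 2^(0:5))
  freq <- tabulate(idx + 1L, 64) / n
  p <- patternProbabilities(sp, "DZ_F")
  expect_lt(max(abs(freq - as.numeric(p))), 1.5e-3)  # ~4 MC SEs
})

test_that("log-likelihood is linear in counts and zero for an empty cohort", {
  sp <- adeSpec()
  co <- simulateCohort(sp, c(MZ_F = 400, DZ_F = 300), seed = 3)
  pd <- pairData(co)
  pd2 <- pd; pd2$pairId <- paste0(pd$pairId, "_b")
  doubled <- twinCohort(rbind(pd, pd2), "CMD")
  expect_equal(logLikelihood(sp, doubled), 2 * logLikelihood(sp, co),
               tolerance = 1e-10)
  empty <- simulateCohort(sp, c(MZ_F = 0), seed = 1)
  expect_equal(logLikelihood(sp, empty), 0)
})

test_that("the generating model beats a perturbed model in likelihood", {
  sp <- presetSpec("women_common_pathway")
  co <- simulateCohort(sp, c(MZ_F = 25000, DZ_F = 25000), seed = 79)
  pars2 <- sp@paramsF
  pars2$lambda[1] <- pars2$lambda[1] + 0.2
  sp2 <- biometricSpec("common_pathway", traitNames(sp), paramsF = pars2,
                       thresholdsF = sp@thresholdsF,
                       thresholdsM = sp@thresholdsM, normalize = TRUE)
  expect_gt(logLikelihood(sp, co), logLikelihood(sp2, co))
})

test_that("-2lnL is invariant to pair order and trait order", {
  sp <- presetSpec("selection_independent")
  co <- simulateCohort(sp, c(MZ_M = 2000, DZ_M = 2000), seed = 83)
  ll <- logLikelihood(sp, co)
  ## pair order
  pd <- pairData(co)
  set.seed(1); pd <- pd[sample(nrow(pd)), ]
  expect_equal(logLikelihood(sp, twinCohort(pd, traitNames(co))), ll,
               tolerance = 1e-9)
  ## trait order: permute the spec's loading vectors and the cohort's
  ## trait list consistently
  perm <- c(2, 3, 1)
  tn <- traitNames(co)[perm]
  spPerm <- biometricSpec("independent_pathway", tn,
                          paramsF = lapply(sp@paramsF, function(v) v[perm]),
                          paramsM = lapply(sp@paramsM, function(v) v[perm]),
                          thresholdsF = sp@thresholdsF[perm],
                          thresholdsM = sp@thresholdsM[perm])
  ## trait order changes the quadrature's coordinate system, so the
  ## comparison is at reference integration precision, not exact arithmetic
  coPerm <- twinCohort(pairData(co), tn)
  llRef <- logLikelihood(sp, co, engine = "reference")
  llPermRef <- logLikelihood(spPerm, coPerm, engine = "reference")
  expect_lt(abs(llPermRef - llRef), 1e-3)
})

test_that("partial patterns marginalize over the unobserved entries", {
  sp <- presetSpec("women_common_pathway")
  full <- patternProbabilities(sp, "MZ_F")
  pat <- c(1, 0, NA, 0, NA, NA)
  marg <- patternProbability(sp, "MZ_F", pat)
  completions <- 0
  for (b3 in 0:1) for (b5 in 0:1) for (b6 in 0:1)
    completions <- completions + full[[paste0("10", b3, "|0", b5, b6)]]
  expect_equal(marg, completions, tolerance = 1e-6)
})

test_that("incomplete pairs add marginal contributions when requested", {
  sp <- adeSpec()
  co <- simulateCohort(sp, c(MZ_F = 200), seed = 5)
  pd <- pairData(co)
  pd$CMD_2[1:10] <- NA
  coi <- twinCohort(pd, "CMD")
  llc <- logLikelihood(sp, coi)
  lli <- logLikelihood(sp, coi, includeIncomplete = TRUE)
  ## ten singleton margins, each log P(x) for a binary margin
  tau <- sp@thresholdsF
  byHand <- sum(log(ifelse(pd$CMD_1[1:10] == 1, 1 - pnorm(tau), pnorm(tau))))
  expect_equal(lli - llc, byHand, tolerance = 1e-6)
})
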