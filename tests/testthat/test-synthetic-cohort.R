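test_that("expected structures reproduce the closed-form biometrical identities", {
  ## pure unique environment: liabilities are independent
  e <- biometricSpec("univariate_E", "CMD", paramsF = list(e = 1),
                     prevalencesF = 0.3)
  expect_equal(unname(expectedStructure(e, "MZ_F")), diag(2),
               ignore_attr = TRUE)

  ## ADE: rMZ = a^2 + d^2, rDZ = a^2/2 + d^2/4
  sp <- adeSpec(0.5, 0.2, 0.3)
  expect_equal(expectedStructure(sp, "MZ_F")[1, 2], 0.70)
  expect_equal(expectedStructure(sp, "DZ_F")[1, 2], 0.30)
  expect_equal(expectedStructure(sp, "DZ_OS")[1, 2], 0.30)

  ## common pathway: within-twin cross-trait correlation is
  ## lambda_a * lambda_b (unit latent variance)
  cp <- presetSpec("women_common_pathway")
  S <- expectedStructure(cp, "MZ_F")
  expect_equal(S[1, 2], 0.40 * 0.54, tolerance = 1e-6)
})

test_that("common-pathway structure matches a brute-force latent simulation", {
  cp <- presetSpec("women_common_pathway")
  pars <- cp@paramsF
  n <- 400000
  set.seed(77)
  ## simulate the latent system directly, independent of expectedStructure
  L <- pars$latent[["A"]] * rnorm(n) + pars$latent[["D"]] * rnorm(n) +
    pars$latent[["E"]] * rnorm(n)
  y <- sapply(1:3, function(i)
    pars$lambda[i] * L + pars$sA[i] * rnorm(n) + pars$sD[i] * rnorm(n) +
      pars$sE[i] * rnorm(n))
  S <- expectedStructure(cp, "MZ_F")[1:3, 1:3]
  expect_equal(unname(cor(y)), unname(S), tolerance = 0.01)
})

test_that("expected structures are valid correlation matrices with MZ >= DZ", {
  specs <- list(presetSpec("women_common_pathway"),
                presetSpec("men_cholesky"),
                presetSpec("selection_independent"),
                adeSpec(0.4, 0.1, 0.5))
  for (sp in specs) {
    for (g in c("MZ_F", "MZ_M", "DZ_F", "DZ_M", "DZ_OS")) {
      S <- expectedStructure(sp, g)
      expect_equal(unname(diag(S)), rep(1, nrow(S)))
      expect_equal(S, t(S), ignore_attr = TRUE)
      expect_gt(min(eigen(S, symmetric = TRUE)$values), -1e-10)
    }
    ## monotonicity under nonnegative loadings: elementwise MZ cross-twin
    ## block >= same-sex DZ cross-twin block
    k <- length(traitNames(sp))
    cross <- function(g) expectedStructure(sp, g)[seq_len(k), k + seq_len(k)]
    expect_true(all(cross("MZ_F") - cross("DZ_F") >= -1e-12))
  }
})

test_that("an invalid spec yields a hard non-PSD error naming the group", {
  ## rAos > 1 makes the opposite-sex structure indefinite for a heritable trait
  bad <- biometricSpec("univariate_AE", "CMD",
                       paramsF = list(a = sqrt(0.9), e = sqrt(0.1)),
                       prevalencesF = 0.3, rAos = 2)
  expect_error(expectedStructure(bad, "DZ_OS"), "DZ_OS")
})

test_that("simulation is seed-deterministic with independent group streams", {
  sp <- adeSpec()
  n <- c(MZ_F = 200, DZ_F = 150)
  a <- simulateCohort(sp, n, seed = 5)
  b <- simulateCohort(sp, n, seed = 5)
  expect_identical(pairData(a), pairData(b))
  expect_false(identical(pairData(a),
                         pairData(simulateCohort(sp, n, seed = 6))))
  ## adding a group leaves existing groups untouched
  c3 <- simulateCohort(sp, c(n, DZ_OS = 100), seed = 5)
  mz <- function(x) pairData(x)[pairData(x)$zygosity == "MZ_F", ]
  expect_identical(mz(a), mz(c3))
  ## empty simulation
  expect_equal(nPairs(simulateCohort(sp, c(MZ_F = 0), seed = 1)), 0)
})

test_that("simulated cohorts recover the generating correlations", {
  ## pure-E: MZ intraclass tetrachoric near 0
  e <- biometricSpec("univariate_E", "CMD", paramsF = list(e = 1),
                     prevalencesF = 0.3)
  co <- simulateCohort(e, c(MZ_F = 50000), seed = 13)
  expect_lt(abs(rho(intraclassTetrachoric(co, "CMD", "MZ_F"))), 0.02)

  ## trivariate self-consistency: simulated tetrachorics match the
  ## model-implied structure
  cp <- presetSpec("women_common_pathway")
  co2 <- simulateCohort(cp, c(MZ_F = 100000), seed = 17)
  S <- expectedStructure(cp, "MZ_F")
  expect_lt(abs(rho(intraclassTetrachoric(co2, "CMD", "MZ_F")) - S[1, 4]),
            0.02)
  expect_lt(abs(rho(crossTwinCrossTrait(co2, "CMD", "Pain", "MZ_F")) -
                  S[1, 5]), 0.02)
  expect_lt(abs(rho(crossTwinCrossTrait(co2, "Pain", "SADP", "MZ_F")) -
                  S[2, 6]), 0.02)
})

test_that("simulated pattern frequencies follow the MVN rectangle probabilities", {
  cp <- presetSpec("women_common_pathway")
  n <- 200000
  co <- simulateCohort(cp, c(DZ_F = n), seed = 23)
  ct <- contingencyTable(co, traitNames(co), "DZ_F")
  p <- patternProbabilities(cp, "DZ_F")
  gof <- suppressWarnings(
    chisq.test(ct@counts[names(p)], p = as.numeric(p)))
  expect_gt(gof$p.value, 0.001)
})

test_that("preset scenarios carry the intended printed path coefficients", {
  cp <- presetSpec("women_common_pathway")
  expect_equal(sum(cp@paramsF$latent^2), 1, tolerance = 1e-12)
  expect_equal(unname(cp@paramsF$latent^2), c(0.6561, 0.0841, 0.2601),
               tolerance = 1e-3)
  expect_equal(cp@paramsF$lambda, c(0.40, 0.54, 0.66), tolerance = 1e-6)

  mc <- presetSpec("men_cholesky")
  expect_equal(unname(mc@paramsF$LA[3, ]), c(0.34, 0.20, 0.52),
               tolerance = 1e-6)
  expect_equal(unname(mc@paramsF$LA[2, 1:2]), c(0.25, 0.51),
               tolerance = 1e-6)
  ## unit liability variance per trait
  for (sc in c("women_common_pathway", "men_cholesky",
               "selection_cholesky", "selection_independent")) {
    sp <- presetSpec(sc)
    lm <- loadingMatrices(sp, "F")
    v <- Reduce(`+`, lapply(lm, function(m) rowSums(m^2)))
    expect_equal(unname(v), rep(1, 3), tolerance = 1e-9)
  }
})
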