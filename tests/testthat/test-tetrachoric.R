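test_that("balanced independent table gives rho 0 at zero thresholds", {
  est <- tetrachoricMLE(matrix(c(25, 25, 25, 25), 2))
  expect_equal(rho(est), 0, tolerance = 1e-4)
  expect_equal(unname(thresholds(est)), c(0, 0), tolerance = 1e-4)
})

test_that("perfect concordance hits the +1 boundary with a flag", {
  est <- tetrachoricMLE(matrix(c(50, 0, 0, 50), 2))
  expect_gt(rho(est), 0.995)
  expect_true("boundary" %in% est@flags)
})

test_that("degenerate margins give an undefined correlation, thresholds reported", {
  est <- tetrachoricMLE(matrix(c(30, 0, 70, 0), 2))  # no row-variable 1s
  expect_true(is.na(rho(est)))
  expect_true("degenerate" %in% est@flags)
  expect_equal(unname(thresholds(est)[1]), Inf)
  expect_equal(unname(thresholds(est)[2]), qnorm(0.3), tolerance = 1e-9)
})

test_that("rho is recovered from a table built from exact BVN rectangle probabilities", {
  tau <- c(0.5, 0.8); r <- 0.4
  p00 <- as.numeric(mvtnorm::pmvnorm(upper = tau,
                                     corr = matrix(c(1, r, r, 1), 2),
                                     algorithm = mvtnorm::TVPACK(1e-12)))
  p <- matrix(c(p00, pnorm(tau[2]) - p00, pnorm(tau[1]) - p00,
                1 - sum(pnorm(tau)) + p00), 2)
  tab <- round(10000 * p)
  est <- tetrachoricMLE(tab)
  expect_equal(rho(est), 0.4, tolerance = 0.02)
  expect_equal(unname(thresholds(est)), tau, tolerance = 0.02)
  expect_false(is.na(seRho(est)))
})

test_that("the MLE agrees with the lattice-search oracle on random tables", {
  set.seed(301)
  for (i in 1:12) {
    tau <- runif(2, -1.2, 1.2); r <- runif(1, -0.85, 0.85)
    p00 <- as.numeric(mvtnorm::pmvnorm(upper = tau,
                                       corr = matrix(c(1, r, r, 1), 2),
                                       algorithm = mvtnorm::TVPACK(1e-12)))
    p <- c(p00, pnorm(tau[2]) - p00, pnorm(tau[1]) - p00,
           1 - sum(pnorm(tau)) + p00)
    tab <- matrix(rmultinom(1, 2000, p), 2)
    if (any(tab == 0)) next  # the oracle target is defined for identified tables
    expect_lt(abs(rho(tetrachoricMLE(tab)) - latticeTetrachoric(tab)),
              0.002)
  }
})

test_that("transposing the table swaps thresholds and preserves rho", {
  tab <- matrix(c(820, 170, 240, 770), 2)
  a <- tetrachoricMLE(tab)
  b <- tetrachoricMLE(t(tab))
  expect_equal(rho(a), rho(b), tolerance = 1e-6)
  expect_equal(a@tauRow, b@tauCol, tolerance = 1e-6)
  expect_equal(a@tauCol, b@tauRow, tolerance = 1e-6)
})

test_that("intraclass estimates are double-entered and order-invariant", {
  sp <- adeSpec()
  co <- simulateCohort(sp, c(MZ_F = 4000), seed = 31)
  est <- intraclassTetrachoric(co, "CMD", "MZ_F")
  expect_true("double-entry" %in% est@flags)
  expect_equal(est@tauRow, est@tauCol)
  expect_equal(est@n, 4000)
  ## swapping twins within randomly chosen pairs changes nothing
  pd <- pairData(co)
  set.seed(9)
  sw <- runif(nrow(pd)) < 0.5
  tmp <- pd$CMD_1[sw]; pd$CMD_1[sw] <- pd$CMD_2[sw]; pd$CMD_2[sw] <- tmp
  est2 <- intraclassTetrachoric(twinCohort(pd, "CMD"), "CMD", "MZ_F")
  expect_equal(rho(est), rho(est2), tolerance = 1e-9)
  ## concordant-only group sits at the boundary
  pd2 <- pd; pd2$CMD_2 <- pd2$CMD_1
  est3 <- intraclassTetrachoric(twinCohort(pd2, "CMD"), "CMD", "MZ_F")
  expect_gt(rho(est3), 0.995)
  expect_true("boundary" %in% est3@flags)
})

test_that("intraclass correlations recover the ADE closed forms", {
  sp <- adeSpec(0.5, 0.2, 0.3)
  co <- simulateCohort(sp, c(MZ_F = 50000, DZ_F = 50000), seed = 37)
  expect_equal(rho(intraclassTetrachoric(co, "CMD", "MZ_F")), 0.70,
               tolerance = 0.02)
  expect_equal(rho(intraclassTetrachoric(co, "CMD", "DZ_F")), 0.30,
               tolerance = 0.02)
})

test_that("cross-twin cross-trait reduces to intraclass for a duplicated trait", {
  sp <- adeSpec()
  co <- simulateCohort(sp, c(MZ_F = 3000), seed = 41)
  pd <- pairData(co)
  pd$Dup_1 <- pd$CMD_1; pd$Dup_2 <- pd$CMD_2
  co2 <- twinCohort(pd, c("CMD", "Dup"))
  cc <- crossTwinCrossTrait(co2, "CMD", "Dup", "MZ_F")
  ic <- intraclassTetrachoric(co2, "CMD", "MZ_F")
  expect_equal(rho(cc), rho(ic), tolerance = 1e-6)
})

test_that("independent traits give near-zero cross-trait correlations", {
  sp <- biometricSpec("independent_pathway", c("T1", "T2"),
                      paramsF = list(cA = c(0, 0), cE = c(0, 0),
                                     sA = sqrt(c(0.5, 0.4)),
                                     sE = sqrt(c(0.5, 0.6))),
                      prevalencesF = c(0.3, 0.4))
  co <- simulateCohort(sp, c(MZ_F = 20000), seed = 43)
  expect_lt(abs(rho(crossTwinCrossTrait(co, "T1", "T2", "MZ_F"))), 0.02)
  expect_lt(abs(rho(phenotypicCorrelation(co, "T1", "T2"))), 0.02)
})

test_that("DZ_OS cross-trait estimates report both orientations separately", {
  sp <- presetSpec("men_cholesky")
  co <- simulateCohort(sp, c(DZ_OS = 3000), seed = 47)
  est <- crossTwinCrossTrait(co, "CMD", "Pain", "DZ_OS")
  expect_named(est, c("femaleA_maleB", "maleA_femaleB"))
  expect_false("double-entry" %in% est$femaleA_maleB@flags)
})

test_that("phenotypic correlation recovers the within-twin liability correlation", {
  cp <- presetSpec("women_common_pathway")
  co <- simulateCohort(cp, c(MZ_F = 25000, DZ_F = 25000), seed = 53)
  S <- expectedStructure(cp, "MZ_F")
  est <- phenotypicCorrelation(co, "CMD", "Pain")
  expect_lt(abs(rho(est) - S[1, 2]), 0.02)
  expect_true("naive-se" %in% est@flags)
  ## a trait against itself is perfectly concordant
  pd <- pairData(co)
  pd$Dup_1 <- pd$CMD_1; pd$Dup_2 <- pd$CMD_2
  co2 <- twinCohort(pd, c("CMD", "Dup"))
  expect_gt(rho(phenotypicCorrelation(co2, "CMD", "Dup")), 0.995)
})

test_that("the tidy correlation table mirrors the group-by-kind layout", {
  cp <- presetSpec("women_common_pathway")
  co <- simulateCohort(cp, c(MZ_F = 1500, DZ_OS = 1500), seed = 59)
  tab <- correlationTable(co)
  expect_setequal(unique(tab$group), c("MZ_F", "DZ_OS", "all"))
  ## 3 intraclass + 3 pooled cross-trait for MZ_F; DZ_OS doubles the
  ## cross-trait rows; 3 phenotypic rows
  expect_equal(sum(tab$group == "MZ_F"), 6)
  expect_equal(sum(tab$group == "DZ_OS"), 9)
  expect_equal(sum(tab$kind == "phenotypic"), 3)
})
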