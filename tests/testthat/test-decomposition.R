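test_that("latent-factor decomposition reproduces the printed worked arithmetic", {
  cp <- presetSpec("women_common_pathway")
  dec <- latentFactorDecomposition(cp)
  expect_equal(unname(dec$percent), c(66, 8, 26))
  expect_equal(sum(dec$percent), 100, tolerance = 1)
  ## degenerate latent factor
  one <- biometricSpec("common_pathway", c("T1", "T2", "T3"),
                       paramsF = list(latent = c(A = 1, D = 0, E = 0),
                                      lambda = c(0.5, 0.5, 0.5),
                                      sA = rep(0, 3), sD = rep(0, 3),
                                      sE = sqrt(1 - rep(0.25, 3))),
                       prevalencesF = c(0.3, 0.3, 0.3))
  expect_equal(unname(latentFactorDecomposition(one)$percent), c(100, 0, 0))
})

test_that("variance breakdowns give the printed common shares and sum to one", {
  cp <- presetSpec("women_common_pathway")
  expect_equal(varianceBreakdown(cp, "CMD")@percent[["common_A"]], 10)
  expect_equal(varianceBreakdown(cp, "Pain")@percent[["common_A"]], 19)
  expect_equal(varianceBreakdown(cp, "SADP")@percent[["common_A"]], 29)
  for (tr in c("CMD", "Pain", "SADP"))
    expect_equal(sum(varianceBreakdown(cp, tr)@components), 1,
                 tolerance = 1e-6)
  ## a trait decoupled from the latent factor has only specific variance
  dec <- biometricSpec("common_pathway", c("T1", "T2"),
                       paramsF = list(latent = c(A = 0.8, D = 0, E = 0.6),
                                      lambda = c(0.7, 0),
                                      sA = c(0.3, 0.6), sD = c(0, 0),
                                      sE = c(sqrt(1 - 0.49 - 0.09),
                                             0.8)),
                       prevalencesF = c(0.3, 0.3))
  b <- varianceBreakdown(dec, "T2")
  expect_equal(sum(b@components[startsWith(names(b@components),
                                           "common")]), 0)
  expect_equal(sum(b@components[startsWith(names(b@components),
                                           "specific")]), 1,
               tolerance = 1e-6)
})

test_that("Cholesky genetic shares reproduce the printed percentages", {
  mc <- presetSpec("men_cholesky")
  expect_equal(unname(choleskyGeneticShares(mc, "SADP")$percent),
               c(27, 9, 63))
  expect_equal(unname(choleskyGeneticShares(mc, "Pain")$percent),
               c(19, 81))
  expect_equal(sum(choleskyGeneticShares(mc, "SADP")$percent), 100,
               tolerance = 1)
  ## single-factor loading vector
  solo <- biometricSpec("cholesky", c("T1", "T2", "T3"),
                        paramsF = list(
                          LA = rbind(c(0.6, 0, 0), c(0.5, 0, 0),
                                     c(0.4, 0, 0)),
                          LE = rbind(c(0.8, 0, 0), c(0, sqrt(0.75), 0),
                                     c(0, 0, sqrt(0.84)))),
                        prevalencesF = rep(0.3, 3))
  expect_equal(unname(choleskyGeneticShares(solo, "T3")$percent),
               c(100, 0, 0))
  ## zero genetic variance -> undefined shares
  eOnly <- biometricSpec("cholesky", c("T1", "T2"),
                         paramsF = list(LA = matrix(0, 2, 2),
                                        LE = diag(2)),
                         prevalencesF = c(0.3, 0.3))
  expect_warning(s <- choleskyGeneticShares(eOnly, "T2"), "undefined")
  expect_true(all(is.na(s$shares)))
})

test_that("component correlations handle shared and degenerate structures", {
  ## identical loading rows -> perfect genetic correlation
  same <- biometricSpec("cholesky", c("T1", "T2"),
                        paramsF = list(LA = rbind(c(0.6, 0), c(0.6, 0)),
                                       LE = rbind(c(0.8, 0), c(0, 0.8))),
                        prevalencesF = c(0.3, 0.3))
  expect_equal(componentCorrelation(same, "T1", "T2", "A")@value, 1,
               tolerance = 1e-9)
  ## common pathway with no specific loadings: r_g = 1 whatever lambda is
  cpNoSpec <- biometricSpec("common_pathway", c("T1", "T2"),
                            paramsF = list(latent = c(A = 0.8, E = 0.6),
                                           lambda = c(1, 1),
                                           sA = c(0, 0), sE = c(0, 0)),
                            prevalencesF = c(0.3, 0.4))
  expect_equal(componentCorrelation(cpNoSpec, "T1", "T2", "A")@value, 1,
               tolerance = 1e-9)
  ## zero component variance -> undefined with a flag
  eOnly <- biometricSpec("cholesky", c("T1", "T2"),
                         paramsF = list(LA = matrix(0, 2, 2),
                                        LE = diag(2)),
                         prevalencesF = c(0.3, 0.3))
  cc <- componentCorrelation(eOnly, "T1", "T2", "A")
  expect_true(is.na(cc@value))
  expect_true("undefined" %in% cc@flags)
})

test_that("genetic correlations survive the recovery pipeline", {
  sp <- presetSpec("selection_cholesky")
  rgTrue <- componentCorrelation(sp, "CMD", "Pain", "A")@value
  co <- simulateCohort(sp, c(MZ_F = 20000, DZ_F = 20000), seed = 139)
  fit <- fitBiometric("cholesky", co, sex = "F",
                      constraints = list(components = c("A", "E")),
                      options = list(nStarts = 1))
  rgHat <- componentCorrelation(fit, "CMD", "Pain", "A")@value
  expect_equal(rgHat, rgTrue, tolerance = 0.05)
})

test_that("covariance shares are symmetric and match the latent split", {
  cp <- presetSpec("women_common_pathway")
  cs <- covarianceShare(cp, "CMD", "Pain")
  ## all cross-trait covariance flows through the latent factor, so the
  ## shares equal the latent variance decomposition
  expect_equal(unname(cs$shares),
               unname(latentFactorDecomposition(cp)$proportions),
               tolerance = 1e-9)
  expect_equal(sum(cs$shares), 1, tolerance = 1e-9)
  cs2 <- covarianceShare(cp, "Pain", "CMD")
  expect_equal(cs$shares, cs2$shares, tolerance = 1e-12)
  ## only-A covariance
  aOnly <- biometricSpec("cholesky", c("T1", "T2"),
                         paramsF = list(LA = rbind(c(0.6, 0), c(0.5, 0.3)),
                                        LE = rbind(c(0.8, 0),
                                                   c(0, sqrt(1 - 0.34)))),
                         prevalencesF = c(0.3, 0.3))
  expect_equal(unname(covarianceShare(aOnly, "T1", "T2")$shares[["A"]]), 1)
})

test_that("component correlations are invariant to whole-column sign flips", {
  sp <- presetSpec("selection_cholesky")
  flipped <- sp
  flipped@paramsF$LA[, 2] <- -flipped@paramsF$LA[, 2]
  flipped@paramsM <- flipped@paramsF
  for (pair in list(c("CMD", "Pain"), c("Pain", "SADP")))
    expect_equal(componentCorrelation(flipped, pair[1], pair[2], "A")@value,
                 componentCorrelation(sp, pair[1], pair[2], "A")@value,
                 tolerance = 1e-12)
})

test_that("rounding for reports goes half away from zero", {
  expect_equal(roundHalfAway(c(0.5, 1.5, 2.5, -0.5)), c(1, 2, 3, -1))
  expect_equal(roundHalfAway(65.61), 66)
  expect_equal(roundHalfAway(8.41), 8)
})
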