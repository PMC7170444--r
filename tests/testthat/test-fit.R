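fastOpts <- list(nStarts = 1)

test_that("the saturated univariate model reproduces observed cell proportions", {
  sp <- adeSpec()
  co <- simulateCohort(sp, c(MZ_F = 3000, DZ_F = 2500, DZ_OS = 2000),
                       seed = 101)
  fit <- fitBiometric("saturated", co)
  expect_true(converged(fit))
  est <- estimates(fit)
  for (g in c("MZ_F", "DZ_F", "DZ_OS")) {
    ct <- contingencyTable(co, "CMD", g)
    obs <- matrix(c(ct@counts[["0|0"]], ct@counts[["1|0"]],
                    ct@counts[["0|1"]], ct@counts[["1|1"]]), 2) / ct@nComplete
    fitted <- twinpath:::.cellProbs(est[[paste0(g, ".rho")]],
                                    est[[paste0(g, ".tau1")]],
                                    est[[paste0(g, ".tau2")]])
    expect_lt(max(abs(fitted - obs)), 1e-4)
  }
  ## a saturated fit never has a worse likelihood than a structured model
  ade <- fitBiometric("ADE", co, options = fastOpts)
  expect_lte(fit@minus2LnL, ade@minus2LnL + 1e-6)
})

test_that("univariate ADE parameters are recovered from simulated data", {
  sp <- adeSpec(0.5, 0.2, 0.3, prevF = 0.25, prevM = 0.15)
  co <- simulateCohort(sp, c(MZ_F = 20000, MZ_M = 20000, DZ_F = 20000,
                             DZ_M = 20000, DZ_OS = 20000), seed = 103)
  fit <- fitBiometric("ADE", co, options = fastOpts)
  expect_true(converged(fit))
  est <- estimates(fit)
  for (s in c("F", "M")) {
    expect_lt(abs(est[[paste0(s, ".a[1]")]]^2 - 0.5), 0.05)
    expect_lt(abs(est[[paste0(s, ".d[1]")]]^2 - 0.2), 0.05)
    expect_lt(abs(est[[paste0(s, ".e[1]")]]^2 - 0.3), 0.05)
  }
  expect_equal(est[["tau.F.CMD"]], qnorm(0.75), tolerance = 0.03)
  expect_equal(est[["tau.M.CMD"]], qnorm(0.85), tolerance = 0.03)
  ## AIC/BIC identities
  st <- fitStats(fit)
  expect_equal(st[["aic"]], st[["minus2LnL"]] + 2 * st[["nParams"]])
  expect_equal(st[["bic"]],
               st[["minus2LnL"]] + st[["nParams"]] * log(st[["nUnits"]]))
})

test_that("nested univariate models order correctly and the LRT is boundary-calibrated", {
  sp <- aeSpec(0.45)  # generating dominance variance is zero
  lrts <- numeric(40)
  for (r in seq_along(lrts)) {
    co <- simulateCohort(sp, c(MZ_F = 1500, MZ_M = 1500, DZ_F = 1500,
                               DZ_M = 1500, DZ_OS = 1500), seed = 7000 + r)
    ae <- fitBiometric("AE", co, constraints = list(sexEqual = TRUE),
                       options = fastOpts)
    ade <- fitBiometric("ADE", co, constraints = list(sexEqual = TRUE),
                        options = fastOpts)
    expect_gte(ae@minus2LnL, ade@minus2LnL - 0.01)
    lrts[r] <- max(ae@minus2LnL - ade@minus2LnL, 0)
  }
  ## with d entering as a squared path, d^2 = 0 sits on the boundary: the
  ## LRT follows the half-and-half mixture of 0 and chi-square(1)
  expect_gt(mean(lrts < 1e-4), 0.25)
  expect_lt(mean(lrts < 1e-4), 0.75)
  expect_lte(mean(lrts > qchisq(0.95, 1)), 0.15)
})

test_that("fit comparison ranks by AIC with parsimony tie-breaks", {
  sp <- adeSpec()
  co <- simulateCohort(sp, c(MZ_F = 2000, DZ_F = 2000), seed = 107)
  ae <- fitBiometric("AE", co, sex = "F", options = fastOpts)
  e <- fitBiometric("E", co, sex = "F", options = fastOpts)
  cmp <- compareFits(ae, e)
  expect_equal(cmp$model[1], "univariate_AE")  # heritable data
  expect_equal(nrow(compareFits(ae)), 1)
  ## mismatched cohorts are a hard error
  co2 <- simulateCohort(sp, c(MZ_F = 999, DZ_F = 2000), seed = 108)
  ae2 <- fitBiometric("AE", co2, sex = "F", options = fastOpts)
  expect_error(compareFits(ae, ae2), "same cohort")
  ## equal -2lnL: fewer parameters ranks first
  f1 <- ae; f2 <- ae
  f2@nParams <- f2@nParams + 2
  f2@aic <- f2@minus2LnL + 2 * f2@nParams
  f2@bic <- f2@minus2LnL + f2@nParams * log(f2@nUnits)
  cmp2 <- compareFits(f2, f1)
  expect_equal(cmp2$nParams[1], f1@nParams)
})

test_that("common-pathway parameters are recovered and loadings are canonical", {
  sp <- presetSpec("women_common_pathway")
  co <- simulateCohort(sp, c(MZ_F = 20000, DZ_F = 20000), seed = 109)
  fit <- fitBiometric("common_pathway", co, sex = "F", options = fastOpts)
  expect_true(converged(fit))
  err <- abs(squaredLoadings(fit@spec) - squaredLoadings(sp))
  expect_lt(median(err), 0.05)
  ## canonicalized: latent loadings and lambda leading entry nonnegative
  expect_true(all(fit@spec@paramsF$latent >= 0))
  expect_gte(fit@spec@paramsF$lambda[1], 0)
})

test_that("the Cholesky model never fits worse than its special cases", {
  sp <- presetSpec("women_common_pathway")
  co <- simulateCohort(sp, c(MZ_F = 8000, DZ_F = 8000), seed = 113)
  fc <- fitBiometric("cholesky", co, sex = "F", options = fastOpts)
  fi <- fitBiometric("independent_pathway", co, sex = "F",
                     options = fastOpts)
  fp <- fitBiometric("common_pathway", co, sex = "F", options = fastOpts)
  expect_lte(fc@minus2LnL, fi@minus2LnL + 0.5)
  expect_lte(fc@minus2LnL, fp@minus2LnL + 0.5)
  cmp <- compareFits(fc, fi, fp)
  expect_s3_class(cmp, "data.frame")
  expect_false(is.unsorted(cmp$aic))
})

test_that("dominance loadings can be dropped per trait", {
  sp <- presetSpec("women_common_pathway")
  co <- simulateCohort(sp, c(MZ_F = 5000, DZ_F = 5000), seed = 127)
  fit <- fitBiometric("common_pathway", co, sex = "F",
                      constraints = list(dropD = "SADP"),
                      options = fastOpts)
  expect_equal(unname(fit@spec@paramsF$sD[3]), 0)
  full <- fitBiometric("common_pathway", co, sex = "F", options = fastOpts)
  expect_equal(fit@nParams, full@nParams - 1)
  expect_gte(fit@minus2LnL, full@minus2LnL - 0.05)
})

test_that("the equated model never beats the sex-specific model in likelihood", {
  sp <- aeSpec(0.5, 0.5)
  co <- simulateCohort(sp, c(MZ_F = 4000, MZ_M = 4000, DZ_F = 4000,
                             DZ_M = 4000, DZ_OS = 4000), seed = 131)
  st <- sexEqualityTest("AE", co, options = fastOpts)
  expect_gte(st$lrt, 0)
  expect_equal(st$df, 1)
  expect_gte(st$equated@minus2LnL, st$sexSpecific@minus2LnL - 1e-4)
  expect_output(print(st), "Sex-equality")
})

test_that("a one-sex cohort without DZ_OS pairs triggers the identifiability warning", {
  sp <- aeSpec(0.5)
  co <- simulateCohort(sp, c(MZ_F = 500, DZ_F = 500), seed = 137)
  expect_warning(sexEqualityTest("AE", co, options = fastOpts),
                 "under-identified")
})
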