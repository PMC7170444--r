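test_that("CSV round trip preserves the pair set and applies the OS ordering", {
  tmp <- tempfile(fileext = ".csv")
  writeLines(c("pair_id,zygosity,sex1,sex2,CMD_1,CMD_2",
               "p1,MZ_F,F,F,1,1",
               "p2,DZ_OS,M,F,0,1",
               "p3,DZ_M,M,M,1,"), tmp)
  co <- readCohort(tmp)
  expect_s4_class(co, "TwinCohort")
  expect_equal(nPairs(co), 3)
  expect_equal(traitNames(co), "CMD")
  ## opposite-sex pair stored female-first with phenotypes swapped
  os <- pairData(co)[pairData(co)$zygosity == "DZ_OS", ]
  expect_equal(os$sex1, "F")
  expect_equal(os$CMD_1, 1)
  expect_equal(os$CMD_2, 0)
  ## write/read round trip, order-insensitive
  out <- tempfile(fileext = ".csv")
  writeCohort(co, out)
  co2 <- readCohort(out)
  ord <- function(x) {
    d <- pairData(x)
    d[order(d$pairId), ]
  }
  expect_equal(ord(co), ord(co2), ignore_attr = TRUE)
})

test_that("invalid rows are rejected with reasons; contradictions are hard errors", {
  tmp <- tempfile(fileext = ".csv")
  writeLines(c("pair_id,zygosity,sex1,sex2,CMD_1,CMD_2",
               "p1,MZ_F,F,F,1,1",
               "p2,MZ_M,M,M,2,0",
               "p2,MZ_M,M,M,0,0"), tmp)
  expect_warning(co <- readCohort(tmp), "rejected")
  expect_equal(nPairs(co), 1)
  expect_setequal(co@rejected$row, c(2, 3))
  writeLines(c("pair_id,zygosity,sex1,sex2,CMD_1,CMD_2",
               "p1,MZX,F,F,1,1"), tmp)
  expect_error(readCohort(tmp), "unknown zygosity.*MZX")
  writeLines(c("pair_id,zygosity,sex1,sex2,CMD_1,CMD_2",
               "p1,MZ_F,F,M,1,1"), tmp)
  expect_error(readCohort(tmp), "contradiction")
})

test_that("contingency tables count patterns, zeros included, and track missingness", {
  df <- data.frame(pairId = paste0("p", 1:10), zygosity = "MZ_F",
                   sex1 = "F", sex2 = "F", CMD_1 = 1, CMD_2 = 1)
  ct <- contingencyTable(twinCohort(df, "CMD"), "CMD", "MZ_F")
  expect_equal(unname(ct@counts[["1|1"]]), 10)
  expect_equal(sum(ct@counts), 10)

  df2 <- data.frame(pairId = paste0("q", 1:4), zygosity = "DZ_M",
                    sex1 = "M", sex2 = "M",
                    CMD_1 = c(0, 0, 1, 1), CMD_2 = c(0, 1, 0, 1))
  ct2 <- contingencyTable(twinCohort(df2, "CMD"), "CMD", "DZ_M")
  expect_true(all(ct2@counts == 1))

  ## a missing value makes the pair incomplete but keeps it in the cohort
  df2$CMD_2[1] <- NA
  co <- twinCohort(df2, "CMD")
  expect_equal(nPairs(co), 4)
  ct3 <- contingencyTable(co, "CMD", "DZ_M")
  expect_equal(ct3@nIncomplete, 1)
  expect_equal(sum(ct3@counts) + ct3@nIncomplete, 4)

  ## empty group: all-zero table, not an error
  ct4 <- contingencyTable(co, "CMD", "MZ_F")
  expect_equal(sum(ct4@counts), 0)

  ## trivariate table has 64 patterns
  sp <- presetSpec("women_common_pathway")
  co3 <- simulateCohort(sp, c(MZ_F = 50), seed = 1)
  expect_length(contingencyTable(co3, traitNames(co3), "MZ_F")@counts, 64)
})

test_that("contingency tables are permutation-equivariant in trait order", {
  sp <- presetSpec("women_common_pathway")
  co <- simulateCohort(sp, c(DZ_F = 400), seed = 8)
  t1 <- contingencyTable(co, c("CMD", "Pain", "SADP"), "DZ_F")
  t2 <- contingencyTable(co, c("SADP", "CMD", "Pain"), "DZ_F")
  remap <- function(nm) {
    ## pattern "abc|def" over (CMD, Pain, SADP) -> "cab|fde" over
    ## (SADP, CMD, Pain)
    parts <- strsplit(nm, "|", fixed = TRUE)[[1]]
    p <- function(s) paste0(substr(s, 3, 3), substr(s, 1, 1), substr(s, 2, 2))
    paste0(p(parts[1]), "|", p(parts[2]))
  }
  for (nm in names(t1@counts))
    expect_equal(unname(t2@counts[[remap(nm)]]), unname(t1@counts[[nm]]))
})

test_that("prevalence pools twins, respects sex and missingness", {
  df <- data.frame(pairId = c("a", "b"), zygosity = "MZ_F",
                   sex1 = "F", sex2 = "F",
                   CMD_1 = c(1, 0), CMD_2 = c(0, 0))
  co <- twinCohort(df, "CMD")
  expect_equal(prevalence(co, "CMD", "F"), 0.25)
  expect_warning(p <- prevalence(co, "CMD", "M"), "no non-missing")
  expect_true(is.na(p))
  df$CMD_1 <- 1; df$CMD_2 <- 1
  expect_equal(prevalence(twinCohort(df, "CMD"), "CMD", "F"), 1)
})

test_that("simulated prevalence matches the generating threshold", {
  sp <- adeSpec(prevF = 0.30)
  co <- simulateCohort(sp, c(MZ_F = 10000), seed = 42)  # 20,000 individuals
  expect_equal(prevalence(co, "CMD", "F"), 0.30, tolerance = 0.034)
  expect_lt(abs(prevalence(co, "CMD", "F") - 0.30), 0.01)
})

test_that("contingency JSON export carries patterns and counts", {
  df <- tinyPairs()
  co <- twinCohort(df, "CMD")
  js <- contingencyJSON(contingencyTable(co, "CMD", "MZ_F"))
  parsed <- jsonlite::fromJSON(js)
  expect_equal(parsed$group, "MZ_F")
  expect_equal(parsed$counts[["1|1"]], 1)
})
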