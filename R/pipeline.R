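#' @include decompose.R
NULL

.allStages <- c("descriptives", "correlations", "univariate",
                "multivariate", "decomposition")

#' Configuration for a full twin analysis run
#'
#' Bundles everything \code{\link{runAnalysis}} needs: the input cohort (or
#' a generating model plus group sizes to simulate one), the stages to run,
#' the multivariate families to compare, the selection criterion
#' preference, and the seed.
#'
#' @param cohort a \linkS4class{TwinCohort}, or \code{NULL} to simulate.
#' @param simSpec a \linkS4class{BiometricSpec} used when \code{cohort} is
#'   \code{NULL}.
#' @param nPairs named pair counts per zygosity group for simulation.
#' @param stages subset of \code{c("descriptives", "correlations",
#'   "univariate", "multivariate", "decomposition")}, run in this canonical
#'   order.
#' @param families multivariate families to compare.
#' @param univariateFamilies candidate grid for the univariate stage; each
#'   is fitted with and without the sex-equality constraint.
#' @param criterion \code{"AIC"}, \code{"BIC"} or \code{"both"}. With
#'   \code{"both"}, AIC ranks; if BIC disagrees both winners are reported
#'   and the more parsimonious one is designated best.
#' @param outputDir optional directory; stage tables are written as CSV and
#'   the bundle metadata as JSON.
#' @param seed integer seed (simulation and any stochastic stage).
#' @param fitOptions options passed to \code{\link{fitBiometric}}.
#' @param verbose print stage progress.
#' @return A list of class \code{"AnalysisConfig"}.
#' @export
analysisConfig <- function(cohort = NULL, simSpec = NULL, nPairs = NULL,
                           stages = .allStages,
                           families = c("cholesky", "independent_pathway",
                                        "common_pathway"),
                           univariateFamilies = c("ADE", "AE", "CE", "E"),
                           criterion = c("AIC", "BIC", "both"),
                           outputDir = NULL, seed = 1,
                           fitOptions = list(), verbose = FALSE) {
  criterion <- match.arg(criterion)
  stages <- unique(match.arg(stages, .allStages, several.ok = TRUE))
  if (is.null(cohort) && is.null(simSpec))
    stop("give either a cohort or a simSpec to simulate from")
  if (!is.null(cohort)) stopifnot(methods::is(cohort, "TwinCohort"))
  if (!is.null(simSpec)) {
    stopifnot(methods::is(simSpec, "BiometricSpec"))
    if (is.null(cohort) && is.null(nPairs))
      stop("nPairs is required to simulate a cohort")
  }
  structure(list(cohort = cohort, simSpec = simSpec, nPairs = nPairs,
                 stages = stages, families = families,
                 univariateFamilies = univariateFamilies,
                 criterion = criterion, outputDir = outputDir,
                 seed = as.integer(seed), fitOptions = fitOptions,
                 verbose = verbose),
            class = "AnalysisConfig")
}

.bestByCriterion <- function(cmp, criterion) {
  aw <- attr(cmp, "aicWinner")
  bw <- attr(cmp, "bicWinner")
  if (criterion == "AIC") return(aw)
  if (criterion == "BIC") return(bw)
  if (identical(aw, bw)) return(aw)
  ## disagreement: designate the more parsimonious of the two winners
  pa <- cmp$nParams[match(aw, cmp$model)]
  pb <- cmp$nParams[match(bw, cmp$model)]
  if (pb <= pa) bw else aw
}

#' Run the full twin analysis sequence
#'
#' Executes, in order: (1) descriptive prevalences by sex; (2) the full
#' correlation table by zygosity group; (3) per-trait univariate model
#' selection with sex-equality tests; (4) per-sex multivariate comparison
#' of the configured families; (5) decomposition of each sex's winning
#' model (latent-factor decomposition and variance breakdowns for a
#' common-pathway winner, genetic factor shares for a Cholesky winner, and
#' component correlations/covariance shares for all). Traits whose best
#' univariate model carries no dominance component have their specific
#' dominance loadings dropped in the multivariate stage.
#'
#' Reruns with the same configuration and seed give identical results; the
#' seed and package version are embedded in the bundle metadata.
#'
#' @param config an \code{\link{analysisConfig}}.
#' @return A list of class \code{"twinAnalysisBundle"} with one element per
#'   executed stage plus \code{meta}.
#' @export
runAnalysis <- function(config) {
  stopifnot(inherits(config, "AnalysisConfig"))
  cohort <- config$cohort
  if (is.null(cohort))
    cohort <- simulateCohort(config$simSpec, config$nPairs, config$seed)
  traits <- traitNames(cohort)
  stages <- .allStages[.allStages %in% config$stages]
  bundle <- list()
  bundle$meta <- list(seed = config$seed,
                      package = "twinpath",
                      version = as.character(utils::packageVersion("twinpath")),
                      stages = stages, criterion = config$criterion,
                      traits = traits,
                      nPairs = as.list(zygosityCounts(cohort)))
  note <- function(...) if (isTRUE(config$verbose)) message(...)
  runStage <- function(stage, fn) {
    note("stage: ", stage)
    tryCatch(fn(), error = function(e)
      stop("stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  if ("descriptives" %in% stages) {
    bundle$descriptives <- runStage("descriptives", function() {
      rows <- expand.grid(trait = traits, sex = c("F", "M"),
                          stringsAsFactors = FALSE)
      rows$prevalence <- mapply(function(tr, sx)
        suppressWarnings(prevalence(cohort, tr, sx)),
        rows$trait, rows$sex)
      rows
    })
  }
  if ("correlations" %in% stages) {
    bundle$correlations <- runStage("correlations",
                                    function() correlationTable(cohort))
  }
  univBest <- NULL
  if ("univariate" %in% stages) {
    bundle$univariate <- runStage("univariate", function() {
      out <- list()
      for (tr in traits) {
        fits <- list()
        for (fam in config$univariateFamilies) {
          for (se in c(FALSE, TRUE)) {
            key <- paste0(fam, if (se) "_sexEqual" else "_sexSpecific")
            fits[[key]] <- fitBiometric(fam, cohort, sex = "both",
                                        trait = tr,
                                        constraints = list(sexEqual = se),
                                        options = config$fitOptions)
          }
        }
        cmp <- compareFits(fits)
        cmp$label <- names(fits)[match(
          paste(cmp$model, cmp$sexEqual),
          vapply(fits, function(f)
            paste(f@spec@family, isTRUE(f@details$sexEqual)), character(1)))]
        best <- cmp$label[1]
        sexTest <- sexEqualityTest(sub("_sex.*", "", best), cohort,
                                   trait = tr, options = config$fitOptions)
        out[[tr]] <- list(comparison = cmp, best = best, sexTest = sexTest)
      }
      out
    })
    univBest <- lapply(bundle$univariate, `[[`, "best")
  }
  multiBest <- NULL
  if ("multivariate" %in% stages) {
    bundle$multivariate <- runStage("multivariate", function() {
      dropD <- character(0)
      if (!is.null(univBest)) {
        dropD <- traits[vapply(traits, function(tr)
          !grepl("D", sub("_sex.*", "", univBest[[tr]])), logical(1))]
      }
      out <- list()
      for (sx in c("F", "M")) {
        zc <- zygosityCounts(cohort)
        if (zc[[paste0("MZ_", sx)]] == 0 && zc[[paste0("DZ_", sx)]] == 0)
          next
        fits <- list()
        for (fam in config$families)
          fits[[fam]] <- fitBiometric(fam, cohort, sex = sx,
                                      constraints = list(dropD = dropD),
                                      options = config$fitOptions)
        cmp <- compareFits(fits)
        out[[sx]] <- list(comparison = cmp, fits = fits,
                          best = .bestByCriterion(cmp, config$criterion),
                          dropD = dropD)
      }
      out
    })
    multiBest <- lapply(bundle$multivariate, `[[`, "best")
  }
  if ("decomposition" %in% stages) {
    if (is.null(multiBest))
      stop("stage 'decomposition' requires the multivariate stage")
    bundle$decomposition <- runStage("decomposition", function() {
      out <- list()
      for (sx in names(bundle$multivariate)) {
        entry <- bundle$multivariate[[sx]]
        fit <- entry$fits[[entry$best]]
        dec <- list(model = entry$best)
        if (entry$best == "common_pathway") {
          dec$latent <- latentFactorDecomposition(fit, sex = sx)
          dec$breakdown <- lapply(stats::setNames(traits, traits),
                                  function(tr)
                                    varianceBreakdown(fit, tr, sex = sx))
        }
        if (entry$best == "cholesky") {
          dec$geneticShares <- lapply(stats::setNames(traits, traits),
                                      function(tr)
                                        choleskyGeneticShares(fit, tr,
                                                              sex = sx))
        }
        pairsOf <- utils::combn(traits, 2)
        rg <- list()
        for (j in seq_len(ncol(pairsOf))) {
          a <- pairsOf[1, j]; b <- pairsOf[2, j]
          key <- paste(a, b, sep = "_")
          rg[[key]] <- list(
            rA = componentCorrelation(fit, a, b, "A", sex = sx)@value,
            rE = componentCorrelation(fit, a, b, "E", sex = sx)@value,
            covarianceShares = covarianceShare(fit, a, b, sex = sx)$shares)
        }
        dec$correlations <- rg
        out[[sx]] <- dec
      }
      out
    })
  }
  class(bundle) <- "twinAnalysisBundle"
  if (!is.null(config$outputDir)) .writeBundle(bundle, config$outputDir)
  bundle
}

.writeBundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(bundle$descriptives))
    utils::write.csv(bundle$descriptives,
                     file.path(dir, "descriptives.csv"), row.names = FALSE)
  if (!is.null(bundle$correlations))
    utils::write.csv(bundle$correlations,
                     file.path(dir, "correlations.csv"), row.names = FALSE)
  if (!is.null(bundle$univariate)) {
    tabs <- do.call(rbind, lapply(names(bundle$univariate), function(tr) {
      cmp <- bundle$univariate[[tr]]$comparison
      cmp$trait <- tr
      cmp
    }))
    utils::write.csv(tabs, file.path(dir, "univariate.csv"),
                     row.names = FALSE)
  }
  if (!is.null(bundle$multivariate)) {
    tabs <- do.call(rbind, lapply(names(bundle$multivariate), function(sx) {
      cmp <- bundle$multivariate[[sx]]$comparison
      cmp$fitSex <- sx
      cmp
    }))
    utils::write.csv(tabs, file.path(dir, "multivariate.csv"),
                     row.names = FALSE)
  }
  meta <- bundle$meta
  if (!is.null(bundle$decomposition))
    meta$decomposition <- rapply(bundle$decomposition, function(x) x,
                                 classes = c("numeric", "character"),
                                 how = "list")
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(dir)
}

#' @export
print.twinAnalysisBundle <- function(x, ...) {
  cat("twinAnalysisBundle (seed", x$meta$seed, ")\n")
  cat("  stages:", paste(x$meta$stages, collapse = ", "), "\n")
  if (!is.null(x$multivariate))
    for (sx in names(x$multivariate))
      cat("  best multivariate model (", sx, "): ",
          x$multivariate[[sx]]$best, "\n", sep = "")
  invisible(x)
}

#' Stratified re-analysis (cohort-effect check)
#'
#' Runs the correlation, model-fitting and decomposition stages within each
#' stratum of a pair-level column (e.g. the survey cohort label) and
#' summarizes whether the winning multivariate family agrees across strata.
#' Strata too small for a stage skip it with a logged reason.
#'
#' @param config an \code{\link{analysisConfig}} whose cohort carries the
#'   stratifier.
#' @param stratifier pair-level column name (default \code{"cohortLabel"}).
#' @param minPairs smallest per-sex group size for which model fitting is
#'   attempted.
#' @return List with per-stratum bundles and a \code{concordance} summary.
#' @export
cohortEffectCheck <- function(config, stratifier = "cohortLabel",
                              minPairs = 50) {
  stopifnot(inherits(config, "AnalysisConfig"))
  cohort <- config$cohort
  if (is.null(cohort))
    cohort <- simulateCohort(config$simSpec, config$nPairs, config$seed)
  p <- pairData(cohort)
  if (!stratifier %in% names(p))
    stop("stratifier column not found: ", stratifier)
  levelsS <- unique(p[[stratifier]])
  levelsS <- levelsS[!is.na(levelsS)]
  if (!length(levelsS)) stop("stratifier has no non-missing levels")
  out <- list()
  skipped <- list()
  for (lv in levelsS) {
    sub <- twinCohort(p[p[[stratifier]] %in% lv, , drop = FALSE],
                      traitNames(cohort))
    if (nPairs(sub) == 0) {
      skipped[[as.character(lv)]] <- "no pairs in stratum"
      next
    }
    zc <- zygosityCounts(sub)
    stages <- setdiff(config$stages, "descriptives")
    small <- (zc[["MZ_F"]] < minPairs || zc[["DZ_F"]] < minPairs) &&
      (zc[["MZ_M"]] < minPairs || zc[["DZ_M"]] < minPairs)
    if (small) {
      skipped[[as.character(lv)]] <-
        "too few pairs for model fitting; stage skipped"
      stages <- intersect(stages, c("correlations"))
      if (!length(stages)) next
    }
    cfg <- config
    cfg$cohort <- sub
    cfg$stages <- stages
    cfg$outputDir <- if (!is.null(config$outputDir))
      file.path(config$outputDir, paste0("stratum_", lv)) else NULL
    out[[as.character(lv)]] <- runAnalysis(cfg)
  }
  winners <- lapply(out, function(b)
    if (!is.null(b$multivariate)) lapply(b$multivariate, `[[`, "best"))
  winners <- winners[!vapply(winners, is.null, logical(1))]
  concordant <- NULL
  if (length(winners) >= 2) {
    sexes <- Reduce(intersect, lapply(winners, names))
    concordant <- all(vapply(sexes, function(sx) {
      w <- vapply(winners, function(x) x[[sx]], character(1))
      length(unique(w)) == 1
    }, logical(1)))
  }
  list(strata = out, skipped = skipped, winners = winners,
       concordant = concordant)
}
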