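#' @include AllGenerics.R
NULL

## Zygosity-by-sex groups used throughout. MZ and same-sex DZ pairs carry one
## sex; opposite-sex DZ pairs are stored female-first (ordering convention).
.zygosityLevels <- c("MZ_F", "MZ_M", "DZ_F", "DZ_M", "DZ_OS")

.groupSexes <- function(group) {
  switch(group,
         MZ_F = c("F", "F"), DZ_F = c("F", "F"),
         MZ_M = c("M", "M"), DZ_M = c("M", "M"),
         DZ_OS = c("F", "M"),
         stop("unknown zygosity group: ", group))
}

.modelFamilies <- c("univariate_ACE", "univariate_ADE", "univariate_AE",
                    "univariate_CE", "univariate_E", "cholesky",
                    "independent_pathway", "common_pathway", "saturated")

#' TwinCohort: a collection of twin pairs with binary phenotypes
#'
#' One row per complete pair: pair identifier, zygosity-by-sex group
#' (\code{MZ_F}, \code{MZ_M}, \code{DZ_F}, \code{DZ_M}, \code{DZ_OS}), the sex
#' of each twin, an optional cohort label, and one column per twin per trait
#' (\code{<trait>_1}, \code{<trait>_2}) coded 0/1/\code{NA}. Opposite-sex
#' pairs are stored with the female twin first.
#'
#' @slot pairs data.frame with columns \code{pairId}, \code{zygosity},
#'   \code{sex1}, \code{sex2}, \code{cohortLabel} and two phenotype columns
#'   per trait.
#' @slot traits ordered character vector of trait names.
#' @slot rejected data.frame describing input rows that were rejected during
#'   import (columns \code{row}, \code{reason}); empty for programmatically
#'   built cohorts.
#' @export
setClass("TwinCohort",
         representation(pairs = "data.frame", traits = "character",
                        rejected = "data.frame"),
         prototype(rejected = data.frame(row = integer(), reason = character(),
                                         stringsAsFactors = FALSE)))

setValidity("TwinCohort", function(object) {
  p <- object@pairs
  msgs <- character()
  need <- c("pairId", "zygosity", "sex1", "sex2", "cohortLabel")
  if (!all(need %in% names(p)))
    return(paste("missing pair columns:",
                 paste(setdiff(need, names(p)), collapse = ", ")))
  for (tr in object@traits) {
    cols <- paste0(tr, c("_1", "_2"))
    if (!all(cols %in% names(p)))
      msgs <- c(msgs, paste("missing phenotype columns for trait", tr))
  }
  if (length(msgs)) return(msgs)
  if (anyDuplicated(p$pairId))
    msgs <- c(msgs, "pair IDs are not unique")
  if (!all(p$zygosity %in% .zygosityLevels))
    msgs <- c(msgs, "unknown zygosity codes present")
  for (tr in object@traits) {
    v <- c(p[[paste0(tr, "_1")]], p[[paste0(tr, "_2")]])
    if (!all(is.na(v) | v %in% c(0, 1)))
      msgs <- c(msgs, paste0("phenotype ", tr, " contains values outside {0, 1, NA}"))
  }
  ss <- p$zygosity %in% c("MZ_F", "DZ_F")
  if (any(ss & (p$sex1 != "F" | p$sex2 != "F")))
    msgs <- c(msgs, "female same-sex group contains non-female twins")
  sm <- p$zygosity %in% c("MZ_M", "DZ_M")
  if (any(sm & (p$sex1 != "M" | p$sex2 != "M")))
    msgs <- c(msgs, "male same-sex group contains non-male twins")
  os <- p$zygosity == "DZ_OS"
  if (any(os & (p$sex1 != "F" | p$sex2 != "M")))
    msgs <- c(msgs, "opposite-sex pairs must be stored female-first")
  if (length(msgs)) msgs else TRUE
})

#' BiometricSpec: structure and parameters of a liability-threshold twin model
#'
#' Describes a generating or fitted model: the model family, per-sex
#' standardized path loadings, per-sex liability thresholds, and the
#' cross-sex relatedness constants used for opposite-sex dizygotic pairs.
#' All parameters are on the standardized liability scale: for every sex and
#' trait the model-implied liability variance is 1.
#'
#' Parameter lists by family (all loadings standardized):
#' \itemize{
#'   \item univariate families: scalars \code{a}, \code{c}, \code{d},
#'     \code{e} (absent components 0).
#'   \item \code{cholesky}: lower-triangular \code{LA}, \code{LD} or
#'     \code{LC}, and \code{LE} (k x k).
#'   \item \code{independent_pathway}: common loading vectors \code{cA},
#'     \code{cD}/\code{cC}, \code{cE} and specific vectors \code{sA},
#'     \code{sD}/\code{sC}, \code{sE} (length k).
#'   \item \code{common_pathway}: \code{latent} (named \code{A}, \code{D} or
#'     \code{C}, \code{E}; unit norm), factor loadings \code{lambda}
#'     (length k) and specific vectors \code{sA}, \code{sD}/\code{sC},
#'     \code{sE}.
#' }
#'
#' @slot family one of the supported model families.
#' @slot traits ordered trait names (length k).
#' @slot paramsF,paramsM per-sex parameter lists (see Details).
#' @slot thresholdsF,thresholdsM per-trait liability thresholds
#'   (standard-normal scale).
#' @slot rAos cross-sex additive relatedness for DZ_OS pairs (default 0.5).
#' @slot rDos cross-sex dominance relatedness for DZ_OS pairs (default 0.25).
#' @export
setClass("BiometricSpec",
         representation(family = "character", traits = "character",
                        paramsF = "list", paramsM = "list",
                        thresholdsF = "numeric", thresholdsM = "numeric",
                        rAos = "numeric", rDos = "numeric"),
         prototype(rAos = 0.5, rDos = 0.25))

setValidity("BiometricSpec", function(object) {
  msgs <- character()
  if (!object@family %in% .modelFamilies)
    return(paste("unknown model family:", object@family))
  ## the saturated family stores per-group estimates, not loadings
  if (object@family == "saturated") return(TRUE)
  k <- length(object@traits)
  if (length(object@thresholdsF) != k || length(object@thresholdsM) != k)
    msgs <- c(msgs, "thresholds must have one entry per trait")
  if (!all(is.finite(c(object@thresholdsF, object@thresholdsM))))
    msgs <- c(msgs, "thresholds must be finite")
  for (sex in c("F", "M")) {
    lam <- tryCatch(loadingMatrices(object, sex), error = function(e) e)
    if (inherits(lam, "error")) {
      msgs <- c(msgs, paste0("params", sex, ": ", conditionMessage(lam)))
      next
    }
    hasC <- sum(lam$C^2) > 1e-12
    hasD <- sum(lam$D^2) > 1e-12
    if (hasC && hasD)
      msgs <- c(msgs, "C and D are not jointly identified; specify only one")
    v <- rowSums(lam$A^2) + rowSums(lam$D^2) + rowSums(lam$C^2) +
      rowSums(lam$E^2)
    if (any(abs(v - 1) > 1e-6))
      msgs <- c(msgs,
                paste0("params", sex, ": total liability variance differs ",
                       "from 1 (max dev ", format(max(abs(v - 1))), ")"))
  }
  if (length(msgs)) msgs else TRUE
})

#' ContingencyTable: joint response-pattern counts for one zygosity group
#'
#' The sufficient statistic for all pattern likelihoods: counts of every
#' joint binary outcome pattern (one value per twin per trait) among pairs
#' with complete data on the selected traits.
#'
#' @slot group zygosity group code.
#' @slot traits ordered trait subset the patterns refer to.
#' @slot counts named numeric vector over all \code{2^(2k)} patterns; names
#'   like \code{"101|110"} give twin 1's and twin 2's outcomes in trait
#'   order.
#' @slot nComplete number of pairs with complete data (equals
#'   \code{sum(counts)}).
#' @slot nIncomplete number of pairs in the group excluded for missingness.
#' @export
setClass("ContingencyTable",
         representation(group = "character", traits = "character",
                        counts = "numeric", nComplete = "numeric",
                        nIncomplete = "numeric"))

setValidity("ContingencyTable", function(object) {
  k <- length(object@traits)
  msgs <- character()
  if (length(object@counts) != 4^k)
    msgs <- c(msgs, "counts must cover all 2^(2k) patterns")
  if (any(object@counts < 0))
    msgs <- c(msgs, "counts must be nonnegative")
  if (abs(sum(object@counts) - object@nComplete) > 1e-8)
    msgs <- c(msgs, "counts must sum to nComplete")
  if (length(msgs)) msgs else TRUE
})

#' TetrachoricEstimate: maximum-likelihood latent correlation from a 2x2 table
#'
#' @slot rho latent correlation in [-1, 1] (\code{NA} when undefined).
#' @slot tauRow,tauCol liability thresholds for the row and column variables.
#' @slot seRho standard error from the observed information.
#' @slot n number of independent units (pairs or individuals; double-entered
#'   tables report the pair count, not the doubled record count).
#' @slot flags character notes, e.g. \code{"double-entry"}, \code{"boundary"},
#'   \code{"degenerate"}, \code{"naive-se"}.
#' @export
setClass("TetrachoricEstimate",
         representation(rho = "numeric", tauRow = "numeric",
                        tauCol = "numeric", seRho = "numeric", n = "numeric",
                        flags = "character"))

setValidity("TetrachoricEstimate", function(object) {
  if (!is.na(object@rho) && abs(object@rho) > 1)
    "rho must lie in [-1, 1]" else TRUE
})

#' TwinFit: a fitted liability-threshold twin model
#'
#' Result of full-information maximum-likelihood estimation of one model
#' family on one cohort: the fitted structure (as a
#' \linkS4class{BiometricSpec} holding the estimated standardized loadings
#' and thresholds), the flat estimate vector, -2 log-likelihood, parameter
#' count, AIC/BIC and convergence diagnostics.
#'
#' @slot spec fitted model structure with estimated parameters.
#' @slot sex \code{"F"}, \code{"M"} or \code{"both"} - which part of the
#'   cohort the fit used.
#' @slot estimates named numeric vector of standardized loadings and
#'   thresholds.
#' @slot minus2LnL -2 log-likelihood at the optimum.
#' @slot nParams number of identified free parameters.
#' @slot aic,bic information criteria (\code{aic = minus2LnL + 2 nParams};
#'   \code{bic = minus2LnL + nParams log(nUnits)}).
#' @slot nUnits number of independent sampling units (twin pairs).
#' @slot convergedFlag optimizer convergence indicator.
#' @slot flags character condition notes (boundary estimates, floored
#'   probabilities, ...).
#' @slot details list with optimization internals (starts, objective values,
#'   cohort digest used by \code{\link{compareFits}}).
#' @export
setClass("TwinFit",
         representation(spec = "BiometricSpec", sex = "character",
                        estimates = "numeric", minus2LnL = "numeric",
                        nParams = "numeric", aic = "numeric", bic = "numeric",
                        nUnits = "numeric", convergedFlag = "logical",
                        flags = "character", details = "list"))

setValidity("TwinFit", function(object) {
  msgs <- character()
  if (abs(object@aic - (object@minus2LnL + 2 * object@nParams)) > 1e-6)
    msgs <- c(msgs, "aic inconsistent with minus2LnL and nParams")
  if (object@nUnits > 0 &&
      abs(object@bic - (object@minus2LnL +
                        object@nParams * log(object@nUnits))) > 1e-6)
    msgs <- c(msgs, "bic inconsistent with minus2LnL, nParams and nUnits")
  if (length(msgs)) msgs else TRUE
})

#' VarianceBreakdown: common/specific variance components for one trait
#'
#' @slot trait trait name.
#' @slot components named proportions of total phenotypic variance
#'   (\code{common_A}, \code{common_D} or \code{common_C}, \code{common_E},
#'   \code{specific_A}, ...); sums to 1.
#' @slot percent the same, rounded half away from zero to integer percent.
#' @export
setClass("VarianceBreakdown",
         representation(trait = "character", components = "numeric",
                        percent = "numeric"))

#' ComponentCorrelation: genetic or environmental correlation between traits
#'
#' @slot traitPair the two trait names.
#' @slot component \code{"A"}, \code{"D"}, \code{"C"} or \code{"E"}.
#' @slot value correlation in [-1, 1] (\code{NA} when a component variance
#'   is zero).
#' @slot flags character notes.
#' @export
setClass("ComponentCorrelation",
         representation(traitPair = "character", component = "character",
                        value = "numeric", flags = "character"))

setValidity("ComponentCorrelation", function(object) {
  if (!is.na(object@value) && abs(object@value) > 1 + 1e-8)
    "value must lie in [-1, 1]" else TRUE
})

## ---- show methods ----

setMethod("show", "TwinCohort", function(object) {
  cat("TwinCohort with", nrow(object@pairs), "pairs,",
      length(object@traits), "traits (",
      paste(object@traits, collapse = ", "), ")\n")
  tab <- table(factor(object@pairs$zygosity, levels = .zygosityLevels))
  cat("  ", paste(sprintf("%s: %d", names(tab), as.integer(tab)),
                  collapse = "  "), "\n")
  if (nrow(object@rejected))
    cat("  (", nrow(object@rejected), "input rows rejected )\n")
})

setMethod("show", "BiometricSpec", function(object) {
  cat("BiometricSpec:", object@family, "model for",
      paste(object@traits, collapse = ", "), "\n")
  cat("  thresholds F:", paste(format(object@thresholdsF, digits = 3),
                               collapse = " "),
      " M:", paste(format(object@thresholdsM, digits = 3), collapse = " "),
      "\n")
  cat("  cross-sex relatedness: r_A =", object@rAos, ", r_D =", object@rDos,
      "\n")
})

setMethod("show", "ContingencyTable", function(object) {
  cat("ContingencyTable for", object@group, "over",
      paste(object@traits, collapse = ", "), "\n")
  cat("  complete pairs:", object@nComplete,
      " incomplete:", object@nIncomplete, "\n")
  nz <- object@counts[object@counts > 0]
  show <- utils::head(sort(nz, decreasing = TRUE), 8)
  cat("  top patterns:",
      paste(sprintf("%s=%d", names(show), as.integer(show)),
            collapse = " "), "\n")
})

setMethod("show", "TetrachoricEstimate", function(object) {
  cat(sprintf("TetrachoricEstimate: rho = %s (se %s), tau = (%s, %s), n = %d\n",
              format(object@rho, digits = 3),
              format(object@seRho, digits = 3),
              format(object@tauRow, digits = 3),
              format(object@tauCol, digits = 3), as.integer(object@n)))
  if (length(object@flags)) cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})

setMethod("show", "TwinFit", function(object) {
  cat("TwinFit:", object@spec@family, "(", object@sex, ") on",
      paste(object@spec@traits, collapse = ", "), "\n")
  cat(sprintf("  -2lnL = %.3f, params = %d, AIC = %.3f, BIC = %.3f, n = %d\n",
              object@minus2LnL, as.integer(object@nParams), object@aic,
              object@bic, as.integer(object@nUnits)))
  cat("  converged:", object@convergedFlag,
      if (length(object@flags)) paste0(" [", paste(object@flags, collapse = "; "), "]"),
      "\n")
})

setMethod("show", "VarianceBreakdown", function(object) {
  cat("VarianceBreakdown for", object@trait, "\n")
  print(round(object@components, 4))
})

setMethod("show", "ComponentCorrelation", function(object) {
  cat(sprintf("r_%s(%s, %s) = %s\n", tolower(object@component),
              object@traitPair[1], object@traitPair[2],
              format(object@value, digits = 3)))
  if (length(object@flags)) cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})

## ---- accessors ----

#' @rdname traitNames
#' @export
setMethod("traitNames", "TwinCohort", function(x) x@traits)

#' @rdname traitNames
#' @export
setMethod("traitNames", "BiometricSpec", function(x) x@traits)

#' @rdname traitNames
#' @export
setMethod("traitNames", "TwinFit", function(x) x@spec@traits)

#' @rdname nPairs
#' @export
setMethod("nPairs", "TwinCohort", function(x) nrow(x@pairs))

#' @rdname pairData
#' @export
setMethod("pairData", "TwinCohort", function(x) x@pairs)

#' @rdname estimates
#' @export
setMethod("estimates", "TwinFit", function(x) x@estimates)

#' @rdname fitStats
#' @export
setMethod("fitStats", "TwinFit", function(x)
  c(minus2LnL = x@minus2LnL, nParams = x@nParams, aic = x@aic, bic = x@bic,
    nUnits = x@nUnits))

#' @rdname converged
#' @export
setMethod("converged", "TwinFit", function(x) x@convergedFlag)

#' @rdname rho
#' @export
setMethod("rho", "TetrachoricEstimate", function(x) x@rho)

#' @rdname seRho
#' @export
setMethod("seRho", "TetrachoricEstimate", function(x) x@seRho)

#' @rdname thresholds
#' @export
setMethod("thresholds", "TetrachoricEstimate", function(x, ...)
  c(row = x@tauRow, col = x@tauCol))

#' @rdname thresholds
#' @param sex \code{"F"} or \code{"M"}.
#' @export
setMethod("thresholds", "BiometricSpec", function(x, sex = "F", ...) {
  tau <- if (sex == "F") x@thresholdsF else x@thresholdsM
  stats::setNames(tau, x@traits)
})
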