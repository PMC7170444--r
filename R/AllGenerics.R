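#' @include RcppExports.R
NULL

#' Trait names of an object
#'
#' @param x a \linkS4class{TwinCohort}, \linkS4class{BiometricSpec} or
#'   \linkS4class{TwinFit}.
#' @return Character vector of trait names, in model order.
#' @export
setGeneric("traitNames", function(x) standardGeneric("traitNames"))

#' Number of twin pairs
#'
#' @param x a \linkS4class{TwinCohort}.
#' @return Integer count of pairs.
#' @export
setGeneric("nPairs", function(x) standardGeneric("nPairs"))

#' Pair-level data
#'
#' @param x a \linkS4class{TwinCohort}.
#' @return The underlying \code{data.frame}, one row per pair.
#' @export
setGeneric("pairData", function(x) standardGeneric("pairData"))

#' Parameter estimates of a fitted model
#'
#' @param x a \linkS4class{TwinFit}.
#' @return Named numeric vector of standardized path loadings and thresholds.
#' @export
setGeneric("estimates", function(x) standardGeneric("estimates"))

#' Fit statistics
#'
#' @param x a \linkS4class{TwinFit}.
#' @return Named numeric vector with \code{minus2LnL}, \code{nParams},
#'   \code{aic}, \code{bic} and \code{nUnits}.
#' @export
setGeneric("fitStats", function(x) standardGeneric("fitStats"))

#' Convergence status
#'
#' @param x a \linkS4class{TwinFit}.
#' @return \code{TRUE} if the optimizer reported convergence.
#' @export
setGeneric("converged", function(x) standardGeneric("converged"))

#' Estimated latent correlation
#'
#' @param x a \linkS4class{TetrachoricEstimate}.
#' @return The tetrachoric correlation (may be \code{NA} for degenerate
#'   tables).
#' @export
setGeneric("rho", function(x) standardGeneric("rho"))

#' Standard error of the latent correlation
#'
#' @param x a \linkS4class{TetrachoricEstimate}.
#' @return Standard error from the observed information (corrected for
#'   double entry where applicable).
#' @export
setGeneric("seRho", function(x) standardGeneric("seRho"))

#' Estimated liability thresholds
#'
#' @param x a \linkS4class{TetrachoricEstimate} or \linkS4class{BiometricSpec}.
#' @param ... further arguments (for \linkS4class{BiometricSpec}: \code{sex}).
#' @return Numeric thresholds on the standard-normal liability scale.
#' @export
setGeneric("thresholds", function(x, ...) standardGeneric("thresholds"))
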