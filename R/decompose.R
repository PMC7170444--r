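#' @include fit.R
NULL

## Accept either a TwinFit or a BiometricSpec; return the spec and the
## parameter list for the requested sex.
.specAndPars <- function(fit, sex = NULL) {
  spec <- if (methods::is(fit, "TwinFit")) fit@spec else fit
  stopifnot(methods::is(spec, "BiometricSpec"))
  if (is.null(sex))
    sex <- if (methods::is(fit, "TwinFit") && fit@sex %in% c("F", "M"))
      fit@sex else "F"
  pars <- if (sex == "F") spec@paramsF else spec@paramsM
  list(spec = spec, pars = pars, sex = sex)
}

## Which second component does a spec carry, D or C?
.secondComponent <- function(spec, sex) {
  lm <- loadingMatrices(spec, sex)
  if (sum(lm$C^2) > 1e-12) "C" else "D"
}

#' Decompose the latent shared liability of a common-pathway model
#'
#' Returns the proportions of the latent factor's variance attributable to
#' each component: the squared latent loadings (a_c^2, d_c^2, e_c^2).
#' Percentages are rounded half away from zero for report formatting; the
#' raw proportions are retained.
#'
#' @param fit a common-pathway \linkS4class{TwinFit} or
#'   \linkS4class{BiometricSpec}.
#' @param sex which parameter set to decompose (defaults to the fitted
#'   sex).
#' @return List with \code{proportions} (named numeric) and \code{percent}
#'   (rounded integers).
#' @examples
#' latentFactorDecomposition(presetSpec("women_common_pathway"))$percent
#' # A: 66, D: 8, E: 26
#' @export
latentFactorDecomposition <- function(fit, sex = NULL) {
  sp <- .specAndPars(fit, sex)
  if (sp$spec@family != "common_pathway")
    stop("latent-factor decomposition requires a common-pathway model")
  u <- sp$pars$latent
  prop <- u^2
  list(proportions = prop, percent = roundHalfAway(100 * prop))
}

#' Common/specific variance breakdown for one trait of a common-pathway model
#'
#' Splits the trait's total (unit) liability variance into the variance
#' transmitted through the latent shared liability - component X's share of
#' the latent variance times the squared factor loading - and the squared
#' trait-specific loadings.
#'
#' @param fit a common-pathway \linkS4class{TwinFit} or
#'   \linkS4class{BiometricSpec}.
#' @param trait trait name.
#' @param sex parameter set to use.
#' @return A \linkS4class{VarianceBreakdown}; components sum to 1.
#' @examples
#' b <- varianceBreakdown(presetSpec("women_common_pathway"), "CMD")
#' b@percent[["common_A"]]  # 10, i.e. 0.81^2 * 0.40^2
#' @export
varianceBreakdown <- function(fit, trait, sex = NULL) {
  sp <- .specAndPars(fit, sex)
  if (sp$spec@family != "common_pathway")
    stop("variance breakdown requires a common-pathway model")
  i <- match(trait, sp$spec@traits)
  if (is.na(i)) stop("unknown trait: ", trait)
  u <- sp$pars$latent
  lam <- sp$pars$lambda[i]
  comps <- names(u)
  common <- stats::setNames(u^2 * lam^2, paste0("common_", comps))
  specific <- stats::setNames(
    vapply(comps, function(cp) {
      s <- sp$pars[[paste0("s", cp)]]
      if (is.null(s)) 0 else s[i]^2
    }, numeric(1)), paste0("specific_", comps))
  components <- c(common, specific)
  methods::new("VarianceBreakdown", trait = trait, components = components,
               percent = roundHalfAway(100 * components))
}

#' Per-factor shares of a trait's genetic variance in a Cholesky model
#'
#' For the target trait, each triangular factor's squared loading divided
#' by the trait's total variance from that component: factor j's share of
#' trait i is \code{L[i, j]^2 / sum_j L[i, j]^2}. With the factors ordered
#' as the traits, the first shares measure genetic overlap with the
#' earlier traits and the last the genetic variance unique to the target.
#'
#' @param fit a Cholesky \linkS4class{TwinFit} or
#'   \linkS4class{BiometricSpec}.
#' @param target trait name.
#' @param component which component's loadings to decompose (default
#'   \code{"A"}).
#' @param sex parameter set to use.
#' @return List with \code{shares} (named proportions over factors 1..i)
#'   and \code{percent}; \code{NA} with a warning when the target has no
#'   variance from the component.
#' @examples
#' shares <- choleskyGeneticShares(presetSpec("men_cholesky"), "SADP")
#' shares$percent  # 27, 9, 63
#' @export
choleskyGeneticShares <- function(fit, target, component = "A", sex = NULL) {
  sp <- .specAndPars(fit, sex)
  if (sp$spec@family != "cholesky")
    stop("factor shares require a Cholesky model")
  i <- match(target, sp$spec@traits)
  if (is.na(i)) stop("unknown trait: ", target)
  L <- sp$pars[[paste0("L", component)]]
  if (is.null(L)) stop("component ", component, " absent from the model")
  l2 <- L[i, seq_len(i)]^2
  tot <- sum(l2)
  if (tot < 1e-12) {
    warning("trait ", target, " has no ", component, " variance; ",
            "shares are undefined")
    return(list(shares = rep(NA_real_, i), percent = rep(NA_real_, i)))
  }
  shares <- l2 / tot
  names(shares) <- paste0("factor", seq_len(i))
  list(shares = shares, percent = roundHalfAway(100 * shares))
}

## Component covariance matrix implied by a parameter set.
.componentCov <- function(spec, pars, component, k) {
  lm <- .loadingsFromPars(pars, .familyKind(spec@family)$kind, k,
                          .presentComponents(pars, spec@family))
  tcrossprod(lm[[component]])
}

.presentComponents <- function(pars, family) {
  if (startsWith(family, "univariate"))
    return(toupper(names(pars)[names(pars) %in% c("a", "d", "c", "e")]))
  if (family == "cholesky")
    return(sub("^L", "", names(pars)[startsWith(names(pars), "L")]))
  if (family == "independent_pathway")
    return(sub("^c", "", names(pars)[startsWith(names(pars), "c")]))
  names(pars$latent)
}

#' Genetic or environmental correlation between two traits
#'
#' The correlation between the component-X influences on the two traits,
#' assembled from the fitted loading matrices of any multivariate family:
#' \code{cov_X(a, b) / sqrt(var_X(a) var_X(b))}. For a common-pathway model
#' the latent pathway contributes \code{lambda_a lambda_b} times the
#' component's share of the latent variance.
#'
#' @param fit a multivariate \linkS4class{TwinFit} or
#'   \linkS4class{BiometricSpec}.
#' @param traitA,traitB trait names.
#' @param component \code{"A"}, \code{"D"}, \code{"C"} or \code{"E"}.
#' @param sex parameter set to use.
#' @return A \linkS4class{ComponentCorrelation}; value \code{NA} with flag
#'   \code{"undefined"} when either trait has zero component variance.
#' @export
componentCorrelation <- function(fit, traitA, traitB, component = "A",
                                 sex = NULL) {
  sp <- .specAndPars(fit, sex)
  k <- length(sp$spec@traits)
  ia <- match(traitA, sp$spec@traits)
  ib <- match(traitB, sp$spec@traits)
  if (is.na(ia) || is.na(ib)) stop("unknown trait name")
  S <- .componentCov(sp$spec, sp$pars, component, k)
  va <- S[ia, ia]; vb <- S[ib, ib]
  if (va < 1e-12 || vb < 1e-12)
    return(methods::new("ComponentCorrelation",
                        traitPair = c(traitA, traitB), component = component,
                        value = NA_real_, flags = "undefined"))
  methods::new("ComponentCorrelation", traitPair = c(traitA, traitB),
               component = component,
               value = S[ia, ib] / sqrt(va * vb), flags = character())
}

#' Component shares of the phenotypic covariance between two traits
#'
#' Splits the model-implied liability covariance between two traits into
#' the contributions of each variance component:
#' \code{cov_X(a, b) / sum_X cov_X(a, b)}.
#'
#' @param fit a multivariate \linkS4class{TwinFit} or
#'   \linkS4class{BiometricSpec}.
#' @param traitA,traitB distinct trait names.
#' @param sex parameter set to use.
#' @return Named list with \code{covariances}, \code{shares} (summing to
#'   1) and \code{flags} (notes \code{"sign-mismatch"} when components have
#'   opposite signs, \code{"undefined"} when the total covariance is 0).
#' @export
covarianceShare <- function(fit, traitA, traitB, sex = NULL) {
  if (identical(traitA, traitB)) stop("traits must be distinct")
  sp <- .specAndPars(fit, sex)
  k <- length(sp$spec@traits)
  ia <- match(traitA, sp$spec@traits)
  ib <- match(traitB, sp$spec@traits)
  if (is.na(ia) || is.na(ib)) stop("unknown trait name")
  comps <- .presentComponents(sp$pars, sp$spec@family)
  covs <- vapply(comps, function(cp)
    .componentCov(sp$spec, sp$pars, cp, k)[ia, ib], numeric(1))
  tot <- sum(covs)
  flags <- character()
  if (abs(tot) < 1e-12) {
    warning("total covariance between ", traitA, " and ", traitB,
            " is zero; shares are undefined")
    return(list(covariances = covs, shares = covs * NA_real_,
                flags = "undefined"))
  }
  if (any(covs > 1e-12) && any(covs < -1e-12))
    flags <- c(flags, "sign-mismatch")
  list(covariances = covs, shares = covs / tot, flags = flags)
}
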