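#' @include tetrachoric.R
NULL

## Default settings for the fitting-grade quadrature engine. nOuter/nInner
## are Gauss-Hermite points per dimension; deltaMin is the smallest residual
## diagonal variance for which the factor+diagonal inner representation is
## used (below it the exact conditional-CDF path takes over).
.engineDefaults <- function() {
  list(nOuter = 8, nInner = 8, deltaMin = 0.04, prune = 1e-9,
       exactInner = FALSE, hi = FALSE)
}

## Pattern probabilities for one pair structure: within-twin covariances
## Sw (shared by both twins of a same-sex pair), symmetric cross-twin
## covariance Sx, thresholds per twin.
.pairEngine <- function(Sw, Sx, tau1, tau2, opts = .engineDefaults()) {
  k <- nrow(Sw)
  same <- identical(tau1, tau2)
  if (max(abs(Sx)) < 1e-12) {
    W <- matrix(0, k, 0)
  } else {
    W <- t(.mvnFactor(Sx + diag(1e-10, k)))  # W %*% t(W) = Sx
  }
  Su <- Sw - Sx
  eu <- eigen(Su, symmetric = TRUE)
  lmin <- min(eu$values)
  if (lmin < -1e-8)
    stop("residual within-twin covariance is not positive semidefinite")
  lmin <- max(lmin, 0)
  useFast <- !opts$exactInner && k >= 2 && lmin >= opts$deltaMin
  og <- .ghGridCached(opts$nOuter, ncol(W), opts$prune)
  if (useFast) {
    lam <- pmax(eu$values - lmin, 0)
    keep <- lam > 1e-10
    V <- eu$vectors[, keep, drop = FALSE] %*%
      diag(sqrt(lam[keep]), sum(keep))
    ig <- .ghGridCached(opts$nInner, ncol(V), opts$prune)
    .pairPatternCpp(W, V, rep(sqrt(lmin), k), diag(k), rep(1, k),
                    tau1, tau2, og$nodes, og$weights, ig$nodes, ig$weights,
                    same, TRUE, FALSE)
  } else {
    s <- pmax(sqrt(pmax(diag(Su), 0)), 1e-6)
    R <- Su / tcrossprod(s)
    R[R > 1] <- 1; R[R < -1] <- -1
    diag(R) <- 1
    .pairPatternCpp(W, matrix(0, k, 0), rep(1, k), R, s,
                    tau1, tau2, og$nodes, og$weights,
                    matrix(0, 1, 0), 1, same, FALSE, isTRUE(opts$hi))
  }
}

## Exact joint pattern probabilities for a univariate (k = 1) group.
.bivPatternProbs <- function(tau1, tau2, rho) {
  p00 <- .phi2(tau1, tau2, rho)
  p1 <- stats::pnorm(tau1)
  p2 <- stats::pnorm(tau2)
  stats::setNames(c(p00, p2 - p00, p1 - p00, 1 - p1 - p2 + p00),
                  c("0|0", "1|0", "0|1", "1|1"))
}

## Blocks of the pair structure for a spec/group.
.pairBlocks <- function(spec, group) {
  sexes <- .groupSexes(group)
  L1 <- loadingMatrices(spec, sexes[1])
  L2 <- if (sexes[2] == sexes[1]) L1 else loadingMatrices(spec, sexes[2])
  r <- .relatedness(group, spec@rAos, spec@rDos)
  within <- function(L) Reduce(`+`, lapply(L, tcrossprod))
  Sx <- r[["A"]] * tcrossprod(L1$A, L2$A) +
    r[["D"]] * tcrossprod(L1$D, L2$D) +
    r[["C"]] * tcrossprod(L1$C, L2$C)
  tau1 <- if (sexes[1] == "F") spec@thresholdsF else spec@thresholdsM
  tau2 <- if (sexes[2] == "F") spec@thresholdsF else spec@thresholdsM
  list(Sw1 = within(L1),
       Sw2 = if (sexes[2] == sexes[1]) within(L1) else within(L2),
       Sx = Sx, tau1 = tau1, tau2 = tau2)
}

## All pattern probabilities for one group under a spec. Chooses the exact
## bivariate path (k = 1), the structured quadrature engine (same-sex, or
## opposite-sex with sex-equal parameters), or the mvtnorm fall-back.
.groupPatternProbs <- function(spec, group, opts = .engineDefaults()) {
  b <- .pairBlocks(spec, group)
  k <- length(spec@traits)
  if (k == 1) {
    p <- .bivPatternProbs(b$tau1, b$tau2, b$Sx[1, 1])
    return(p)
  }
  symmetric <- isTRUE(all.equal(b$Sx, t(b$Sx), tolerance = 1e-10)) &&
    isTRUE(all.equal(b$Sw1, b$Sw2, tolerance = 1e-10))
  if (symmetric) {
    p <- .pairEngine(b$Sw1, (b$Sx + t(b$Sx)) / 2, b$tau1, b$tau2, opts)
    names(p) <- .patternNames(k)
    return(p)
  }
  ## general (sex-heterogeneous opposite-sex) structure
  S <- expectedStructure(spec, group)
  nm <- .patternNames(k)
  tau <- c(b$tau1, b$tau2)
  p <- vapply(nm, function(pat) {
    bits <- .parsePattern(pat)
    lo <- ifelse(bits == 1, tau, -Inf)
    hi <- ifelse(bits == 1, Inf, tau)
    .mvnRect(lo, hi, S, abseps = 1e-7)
  }, numeric(1))
  p
}

#' Joint response-pattern probabilities for a zygosity group
#'
#' Computes the multivariate-normal rectangle probabilities of all
#' \code{2^(2k)} joint binary outcome patterns of a twin pair under the
#' model-implied liability structure, by deterministic quadrature refined
#' until successive refinements change no pattern by more than \code{tol}.
#' The probabilities are exactly nonnegative and sum exactly to 1.
#'
#' @param spec a \linkS4class{BiometricSpec}.
#' @param group zygosity group code.
#' @param tol absolute refinement tolerance (default 1e-8).
#' @return Named probability vector over patterns \code{"t1|t2"}.
#' @examples
#' sp <- biometricSpec("univariate_E", "CMD", paramsF = list(e = 1),
#'                     prevalencesF = 0.3)
#' patternProbabilities(sp, "MZ_F")  # independence: products of margins
#' @export
patternProbabilities <- function(spec, group, tol = 1e-8) {
  group <- match.arg(group, .zygosityLevels)
  k <- length(spec@traits)
  if (k == 1) {
    b <- .pairBlocks(spec, group)
    return(.bivPatternProbs(b$tau1, b$tau2, b$Sx[1, 1]))
  }
  opts <- .engineDefaults()
  opts$exactInner <- TRUE
  opts$hi <- TRUE
  opts$prune <- 1e-12
  b <- .pairBlocks(spec, group)
  symmetric <- isTRUE(all.equal(b$Sx, t(b$Sx), tolerance = 1e-10)) &&
    isTRUE(all.equal(b$Sw1, b$Sw2, tolerance = 1e-10))
  if (!symmetric) return(.groupPatternProbs(spec, group, opts))
  Sx <- (b$Sx + t(b$Sx)) / 2
  prev <- NULL
  for (n in c(12, 16, 24, 32)) {
    opts$nOuter <- n
    p <- .pairEngine(b$Sw1, Sx, b$tau1, b$tau2, opts)
    if (!is.null(prev) && max(abs(p - prev)) < tol) break
    prev <- p
  }
  names(p) <- .patternNames(k)
  p
}

#' Probability of one (possibly partial) response pattern
#'
#' For a fully observed pattern this is the corresponding entry of
#' \code{\link{patternProbabilities}}. Entries may be \code{NA} for
#' unobserved phenotypes, in which case the marginal rectangle probability
#' over the observed entries is returned.
#'
#' @param spec a \linkS4class{BiometricSpec}.
#' @param group zygosity group code.
#' @param pattern numeric vector of length 2k over (twin 1 traits, twin 2
#'   traits) with entries 0, 1 or \code{NA}.
#' @param tol absolute integration tolerance.
#' @return A single probability.
#' @export
patternProbability <- function(spec, group, pattern, tol = 1e-8) {
  group <- match.arg(group, .zygosityLevels)
  k <- length(spec@traits)
  if (length(pattern) != 2 * k)
    stop("pattern must have one entry per twin per trait (length ", 2 * k, ")")
  if (!anyNA(pattern)) {
    p <- patternProbabilities(spec, group, tol)
    key <- paste0(paste(pattern[seq_len(k)], collapse = ""), "|",
                  paste(pattern[k + seq_len(k)], collapse = ""))
    return(unname(p[key]))
  }
  b <- .pairBlocks(spec, group)
  S <- expectedStructure(spec, group)
  tau <- c(b$tau1, b$tau2)
  obs <- !is.na(pattern)
  if (!any(obs)) return(1)
  lo <- ifelse(pattern[obs] == 1, tau[obs], -Inf)
  hi <- ifelse(pattern[obs] == 1, Inf, tau[obs])
  .mvnRect(lo, hi, S[obs, obs, drop = FALSE], abseps = tol)
}

#' Log-likelihood of a cohort under a model specification
#'
#' Full-information log-likelihood: the sum over zygosity groups of pattern
#' counts times log pattern probabilities. With
#' \code{includeIncomplete = TRUE} pairs with partially observed phenotypes
#' contribute the marginal rectangle probability over their observed
#' entries. Probabilities underflowing to zero are floored at 1e-300 and
#' flagged with a warning.
#'
#' @param spec a \linkS4class{BiometricSpec}.
#' @param cohort a \linkS4class{TwinCohort} with the same trait set.
#' @param includeIncomplete include partially observed pairs via marginal
#'   probabilities.
#' @param engine \code{"fast"} (the fitting-grade quadrature) or
#'   \code{"reference"} (refined to 1e-8).
#' @return Log-likelihood value (0 for an empty cohort).
#' @export
logLikelihood <- function(spec, cohort, includeIncomplete = FALSE,
                          engine = c("fast", "reference")) {
  engine <- match.arg(engine)
  stopifnot(methods::is(cohort, "TwinCohort"))
  if (!identical(traitNames(cohort), spec@traits))
    stop("cohort traits do not match the spec")
  ll <- 0
  floored <- FALSE
  counts <- zygosityCounts(cohort)
  for (group in names(which(counts > 0))) {
    ct <- contingencyTable(cohort, spec@traits, group)
    if (ct@nComplete > 0) {
      p <- if (engine == "fast")
        .groupPatternProbs(spec, group) else
          patternProbabilities(spec, group)
      use <- ct@counts > 0
      pv <- p[names(ct@counts)][use]
      if (any(pv < 1e-300)) {
        floored <- TRUE
        pv <- pmax(pv, 1e-300)
      }
      ll <- ll + sum(ct@counts[use] * log(pv))
    }
    if (includeIncomplete && ct@nIncomplete > 0) {
      p <- cohort@pairs[cohort@pairs$zygosity == group, , drop = FALSE]
      k <- length(spec@traits)
      m <- as.matrix(p[, c(paste0(spec@traits, "_1"),
                           paste0(spec@traits, "_2"))])
      inc <- rowSums(is.na(m)) > 0 & rowSums(!is.na(m)) > 0
      if (any(inc)) {
        pats <- m[inc, , drop = FALSE]
        key <- apply(pats, 1, paste, collapse = ",")
        for (u in unique(key)) {
          pat <- pats[match(u, key), ]
          pu <- max(patternProbability(spec, group, pat, tol = 1e-7), 1e-300)
          ll <- ll + sum(key == u) * log(pu)
        }
      }
    }
  }
  if (floored)
    warning("some pattern probabilities underflowed and were floored at 1e-300")
  ll
}
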