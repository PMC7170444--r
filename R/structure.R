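#' @include cohort.R
NULL

.components <- c("A", "D", "C", "E")

## Relatedness coefficients (correlation of the component between co-twins).
.relatedness <- function(group, rAos = 0.5, rDos = 0.25) {
  switch(group,
         MZ_F = , MZ_M = c(A = 1, D = 1, C = 1),
         DZ_F = , DZ_M = c(A = 0.5, D = 0.25, C = 1),
         DZ_OS = c(A = rAos, D = rDos, C = 1),
         stop("unknown zygosity group: ", group))
}

.zeroMat <- function(k) matrix(0, k, 1)

#' Full loading matrices of a model specification
#'
#' Expands the family-specific parameter list into one loading matrix per
#' variance component (columns = latent factors, rows = traits), such that
#' the within-twin covariance contributed by component X is
#' \code{L_X \%*\% t(L_X)}. For the common-pathway family the latent
#' pathway and the trait-specific factors appear as separate columns.
#'
#' @param spec a \linkS4class{BiometricSpec}.
#' @param sex \code{"F"} or \code{"M"}.
#' @return Named list of matrices \code{A}, \code{D}, \code{C}, \code{E}.
#' @export
loadingMatrices <- function(spec, sex = c("F", "M")) {
  sex <- match.arg(sex)
  pars <- if (sex == "F") spec@paramsF else spec@paramsM
  k <- length(spec@traits)
  fam <- spec@family
  getv <- function(name, default) {
    v <- pars[[name]]
    if (is.null(v)) default else v
  }
  if (startsWith(fam, "univariate")) {
    out <- list(A = matrix(getv("a", 0), 1, 1),
                D = matrix(getv("d", 0), 1, 1),
                C = matrix(getv("c", 0), 1, 1),
                E = matrix(getv("e", 0), 1, 1))
  } else if (fam == "cholesky") {
    out <- list(A = getv("LA", matrix(0, k, k)),
                D = getv("LD", matrix(0, k, k)),
                C = getv("LC", matrix(0, k, k)),
                E = getv("LE", matrix(0, k, k)))
    for (nm in names(out)) {
      L <- out[[nm]]
      if (!is.matrix(L) || any(dim(L) != k))
        stop("cholesky loading ", nm, " must be a ", k, "x", k, " matrix")
      if (any(abs(L[upper.tri(L)]) > 1e-12))
        stop("cholesky loading ", nm, " must be lower triangular")
    }
  } else if (fam == "independent_pathway") {
    mk <- function(common, specific) {
      cbind(matrix(getv(common, rep(0, k)), k, 1),
            diag(getv(specific, rep(0, k)), k, k))
    }
    out <- list(A = mk("cA", "sA"), D = mk("cD", "sD"),
                C = mk("cC", "sC"), E = mk("cE", "sE"))
  } else if (fam == "common_pathway") {
    latent <- getv("latent", c(A = 0, D = 0, C = 0, E = 0))
    for (nm in .components) if (is.na(latent[nm])) latent[nm] <- 0
    if (abs(sum(latent^2) - 1) > 1e-6)
      stop("common-pathway latent loadings must have unit norm")
    lambda <- getv("lambda", rep(0, k))
    mk <- function(comp, specific) {
      cbind(matrix(latent[comp] * lambda, k, 1),
            diag(getv(specific, rep(0, k)), k, k))
    }
    out <- list(A = mk("A", "sA"), D = mk("D", "sD"),
                C = mk("C", "sC"), E = mk("E", "sE"))
  } else {
    stop("loadingMatrices not defined for family ", fam)
  }
  lapply(out, function(m) {
    rownames(m) <- if (nrow(m) == k) spec@traits else NULL
    m
  })
}

#' Construct a BiometricSpec
#'
#' Convenience constructor with optional row-wise standardization: with
#' \code{normalize = TRUE} every trait's loadings are rescaled so the total
#' model-implied liability variance is exactly 1 (binary data identify only
#' the correlation/threshold parameterization, so the standardized scale is
#' the natural one).
#'
#' @param family model family (see \linkS4class{BiometricSpec}).
#' @param traits ordered trait names.
#' @param paramsF,paramsM per-sex parameter lists; \code{paramsM} defaults
#'   to \code{paramsF}.
#' @param thresholdsF,thresholdsM per-trait liability thresholds;
#'   \code{thresholdsM} defaults to \code{thresholdsF}.
#' @param prevalencesF,prevalencesM alternatively, target prevalences from
#'   which thresholds are derived (\code{qnorm(1 - p)}).
#' @param rAos,rDos cross-sex relatedness constants for DZ_OS pairs.
#' @param normalize rescale loadings row-wise to unit liability variance.
#' @return A validated \linkS4class{BiometricSpec}.
#' @examples
#' biometricSpec("univariate_ADE", "CMD",
#'               paramsF = list(a = sqrt(0.5), d = sqrt(0.2), e = sqrt(0.3)),
#'               prevalencesF = 0.25)
#' @export
biometricSpec <- function(family, traits, paramsF, paramsM = paramsF,
                          thresholdsF = NULL, thresholdsM = NULL,
                          prevalencesF = NULL, prevalencesM = NULL,
                          rAos = 0.5, rDos = 0.25, normalize = FALSE) {
  if (is.null(thresholdsF)) {
    if (is.null(prevalencesF)) stop("give thresholdsF or prevalencesF")
    thresholdsF <- stats::qnorm(1 - prevalencesF)
  }
  if (is.null(thresholdsM)) {
    thresholdsM <- if (!is.null(prevalencesM))
      stats::qnorm(1 - prevalencesM) else thresholdsF
  }
  if (normalize) {
    paramsF <- .normalizePars(paramsF, family, length(traits))
    paramsM <- .normalizePars(paramsM, family, length(traits))
  }
  methods::new("BiometricSpec", family = family, traits = traits,
               paramsF = paramsF, paramsM = paramsM,
               thresholdsF = unname(thresholdsF),
               thresholdsM = unname(thresholdsM),
               rAos = rAos, rDos = rDos)
}

## Rescale loadings trait-wise so total liability variance is 1.
.normalizePars <- function(pars, fam, k) {
  if (startsWith(fam, "univariate")) {
    v <- sum(unlist(pars[c("a", "d", "c", "e")])^2, na.rm = TRUE)
    pars <- lapply(pars, function(x) x / sqrt(v))
  } else if (fam == "cholesky") {
    v <- Reduce(`+`, lapply(pars, function(L) rowSums(L^2)))
    s <- sqrt(v)
    pars <- lapply(pars, function(L) L / s)
  } else if (fam == "independent_pathway") {
    v <- rep(0, k)
    for (nm in names(pars)) v <- v + pars[[nm]]^2
    s <- sqrt(v)
    pars <- lapply(pars, function(x) x / s)
  } else if (fam == "common_pathway") {
    pars$latent <- pars$latent / sqrt(sum(pars$latent^2))
    v <- pars$lambda^2
    for (nm in c("sA", "sD", "sC", "sE"))
      if (!is.null(pars[[nm]])) v <- v + pars[[nm]]^2
    s <- sqrt(v)
    for (nm in c("lambda", "sA", "sD", "sC", "sE"))
      if (!is.null(pars[[nm]])) pars[[nm]] <- pars[[nm]] / s
  }
  pars
}

#' Model-implied liability correlation structure for a zygosity group
#'
#' Returns the 2k x 2k correlation matrix of the latent liabilities of a
#' twin pair: within-twin blocks are the sums of the component covariances
#' for that twin's sex; the cross-twin block scales each component by its
#' relatedness - (1, 1) for MZ, (0.5, 0.25) for same-sex DZ, and the
#' spec's \code{rAos}/\code{rDos} for opposite-sex DZ pairs (shared
#' environment always 1). For DZ_OS the female twin's rows come first and
#' the cross block combines female paths on one side with male paths on the
#' other.
#'
#' @param spec a \linkS4class{BiometricSpec}.
#' @param group zygosity group code.
#' @return Symmetric 2k x 2k matrix with unit diagonal; attribute
#'   \code{group} carries the group code.
#' @examples
#' sp <- biometricSpec("univariate_ADE", "CMD",
#'                     paramsF = list(a = sqrt(0.5), d = sqrt(0.2),
#'                                    e = sqrt(0.3)),
#'                     prevalencesF = 0.25)
#' expectedStructure(sp, "MZ_F")[1, 2]  # a^2 + d^2 = 0.7
#' @export
expectedStructure <- function(spec, group) {
  group <- match.arg(group, .zygosityLevels)
  sexes <- .groupSexes(group)
  L1 <- loadingMatrices(spec, sexes[1])
  L2 <- if (sexes[2] == sexes[1]) L1 else loadingMatrices(spec, sexes[2])
  r <- .relatedness(group, spec@rAos, spec@rDos)
  within <- function(L) Reduce(`+`, lapply(L, tcrossprod))
  Sw1 <- within(L1)
  Sw2 <- if (sexes[2] == sexes[1]) Sw1 else within(L2)
  Sx <- r["A"] * tcrossprod(L1$A, L2$A) + r["D"] * tcrossprod(L1$D, L2$D) +
    r["C"] * tcrossprod(L1$C, L2$C)
  S <- rbind(cbind(Sw1, Sx), cbind(t(Sx), Sw2))
  S <- (S + t(S)) / 2
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10)
    stop("model-implied structure for group ", group,
         " is not positive semidefinite (min eigenvalue ",
         format(min(ev)), ")")
  k <- length(spec@traits)
  dimnames(S) <- list(c(paste0(spec@traits, "_1"), paste0(spec@traits, "_2")),
                      c(paste0(spec@traits, "_1"), paste0(spec@traits, "_2")))
  attr(S, "group") <- group
  S
}

#' Serialize a BiometricSpec to YAML
#'
#' @param spec a \linkS4class{BiometricSpec}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeBiometricSpec <- function(spec, path) {
  asList <- function(pars) lapply(pars, function(x) {
    if (is.matrix(x)) apply(x, 1, as.numeric, simplify = FALSE)
    else as.numeric(x)
  })
  obj <- list(family = spec@family, traits = as.list(spec@traits),
              params_f = asList(spec@paramsF),
              params_m = asList(spec@paramsM),
              thresholds_f = as.numeric(spec@thresholdsF),
              thresholds_m = as.numeric(spec@thresholdsM),
              r_A_os = spec@rAos, r_D_os = spec@rDos,
              latent_names = if (!is.null(spec@paramsF$latent))
                names(spec@paramsF$latent) else NULL)
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' Read a BiometricSpec from YAML
#'
#' @param path file written by \code{\link{writeBiometricSpec}}.
#' @return A \linkS4class{BiometricSpec}.
#' @export
readBiometricSpec <- function(path) {
  obj <- yaml::read_yaml(path)
  k <- length(obj$traits)
  fromList <- function(pars) {
    out <- lapply(pars, function(x) {
      if (is.list(x)) do.call(rbind, lapply(x, as.numeric))
      else as.numeric(x)
    })
    if (!is.null(out$latent) && !is.null(obj$latent_names))
      names(out$latent) <- obj$latent_names
    out
  }
  biometricSpec(family = obj$family, traits = unlist(obj$traits),
                paramsF = fromList(obj$params_f),
                paramsM = fromList(obj$params_m),
                thresholdsF = obj$thresholds_f,
                thresholdsM = obj$thresholds_m,
                rAos = obj$r_A_os, rDos = obj$r_D_os)
}
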