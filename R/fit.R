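#' @include likelihood.R
NULL

.uniAliases <- c(ADE = "univariate_ADE", ACE = "univariate_ACE",
                 AE = "univariate_AE", CE = "univariate_CE",
                 E = "univariate_E")

.familyKind <- function(family) {
  if (family %in% names(.uniAliases)) family <- .uniAliases[[family]]
  if (startsWith(family, "univariate")) return(list(family = family, kind = "uni"))
  switch(family,
         cholesky = list(family = family, kind = "chol"),
         independent_pathway = list(family = family, kind = "ip"),
         common_pathway = list(family = family, kind = "cp"),
         saturated = list(family = family, kind = "saturated"),
         stop("unsupported model family: ", family))
}

.uniComponents <- function(family) {
  switch(family,
         univariate_ACE = c("A", "C", "E"), univariate_ADE = c("A", "D", "E"),
         univariate_AE = c("A", "E"), univariate_CE = c("C", "E"),
         univariate_E = "E")
}

## ---- parameter skeletons ----
## A skeleton describes the raw optimizer layout for one parameter set
## (one sex, or both sexes when equated): a list of blocks with entry
## counts and free masks. Unit-variance identification is imposed inside
## the objective by row-wise rescaling, so all stored entries are raw.

.ltriIndex <- function(k) which(lower.tri(matrix(0, k, k), diag = TRUE))

.skeleton <- function(kind, k, comps, dropD, traits) {
  blocks <- list()
  addBlock <- function(name, len, free, init) {
    blocks[[length(blocks) + 1]] <<- list(name = name, len = len,
                                          free = free, init = init)
  }
  if (kind == "uni") {
    for (comp in comps)
      addBlock(tolower(comp), 1, TRUE,
               c(A = 0.6, D = 0.35, C = 0.35, E = 0.65)[[comp]])
  } else if (kind == "chol") {
    nl <- k * (k + 1) / 2
    idx <- .ltriIndex(k)
    rows <- row(matrix(0, k, k))[idx]
    cols <- col(matrix(0, k, k))[idx]
    for (comp in comps) {
      free <- rep(TRUE, nl)
      if (comp == "D" && length(dropD))
        free[rows %in% match(dropD, traits)] <- FALSE
      init <- rep(0.1, nl)
      init[rows == cols] <- c(A = 0.55, D = 0.3, C = 0.3, E = 0.65)[[comp]]
      addBlock(paste0("L", comp), nl, free, init)
    }
  } else if (kind == "ip") {
    for (comp in comps) {
      freeC <- rep(TRUE, k)
      freeS <- rep(TRUE, k)
      if (comp == "D" && length(dropD)) {
        freeC[match(dropD, traits)] <- FALSE
        freeS[match(dropD, traits)] <- FALSE
      }
      addBlock(paste0("c", comp), k, freeC,
               rep(c(A = 0.45, D = 0.25, C = 0.25, E = 0.3)[[comp]], k))
      addBlock(paste0("s", comp), k, freeS,
               rep(c(A = 0.4, D = 0.2, C = 0.2, E = 0.6)[[comp]], k))
    }
  } else if (kind == "cp") {
    addBlock("latent", length(comps), rep(TRUE, length(comps)),
             c(A = 0.75, D = 0.3, C = 0.3, E = 0.55)[comps])
    addBlock("lambda", k, rep(TRUE, k), rep(0.5, k))
    for (comp in comps) {
      free <- rep(TRUE, k)
      if (comp == "D" && length(dropD)) free[match(dropD, traits)] <- FALSE
      addBlock(paste0("s", comp), k, free,
               rep(c(A = 0.4, D = 0.2, C = 0.2, E = 0.6)[[comp]], k))
    }
  }
  nFree <- sum(vapply(blocks, function(b) sum(b$free), numeric(1)))
  nConstraints <- switch(kind, uni = 1, chol = k, ip = k, cp = k + 1)
  list(kind = kind, k = k, comps = comps, blocks = blocks,
       nFree = nFree, nConstraints = nConstraints)
}

## raw theta segment -> named list of raw parameter arrays
.unpackSet <- function(theta, skel) {
  out <- list()
  pos <- 0
  for (b in skel$blocks) {
    vals <- rep(0, b$len)
    nf <- sum(b$free)
    vals[b$free] <- theta[pos + seq_len(nf)]
    pos <- pos + nf
    out[[b$name]] <- vals
  }
  out
}

.packInit <- function(skel) {
  unlist(lapply(skel$blocks, function(b) b$init[b$free]))
}

## raw set -> standardized family parameter list (+ penalty terms)
.standardizeSet <- function(raw, skel, traits) {
  k <- skel$k
  kind <- skel$kind
  penalty <- 0
  if (kind == "uni") {
    v <- sum(unlist(raw)^2)
    penalty <- (v - 1)^2
    s <- sqrt(max(v, 1e-12))
    pars <- lapply(raw, function(x) x / s)
  } else if (kind == "chol") {
    mats <- list()
    for (nm in names(raw)) {
      L <- matrix(0, k, k)
      L[.ltriIndex(k)] <- raw[[nm]]
      mats[[nm]] <- L
    }
    v <- Reduce(`+`, lapply(mats, function(L) rowSums(L^2)))
    penalty <- sum((v - 1)^2)
    s <- sqrt(pmax(v, 1e-12))
    pars <- lapply(mats, function(L) L / s)
  } else if (kind == "ip") {
    v <- rep(0, k)
    for (nm in names(raw)) v <- v + raw[[nm]]^2
    penalty <- sum((v - 1)^2)
    s <- sqrt(pmax(v, 1e-12))
    pars <- lapply(raw, function(x) x / s)
  } else { # cp
    u <- raw$latent
    un <- sqrt(max(sum(u^2), 1e-12))
    penalty <- (sum(u^2) - 1)^2
    latent <- stats::setNames(u / un, skel$comps)
    v <- raw$lambda^2
    for (nm in names(raw))
      if (startsWith(nm, "s")) v <- v + raw[[nm]]^2
    penalty <- penalty + sum((v - 1)^2)
    s <- sqrt(pmax(v, 1e-12))
    pars <- list(latent = latent, lambda = raw$lambda / s)
    for (nm in names(raw))
      if (startsWith(nm, "s")) pars[[nm]] <- raw[[nm]] / s
  }
  list(pars = pars, penalty = penalty)
}

## standardized parameter list -> loading matrices (A, D, C, E)
.loadingsFromPars <- function(pars, kind, k, comps) {
  z <- matrix(0, k, 1)
  out <- list(A = z, D = z, C = z, E = z)
  if (kind == "uni") {
    for (comp in c("A", "D", "C", "E")) {
      nm <- tolower(comp)
      if (!is.null(pars[[nm]])) out[[comp]] <- matrix(pars[[nm]], 1, 1)
    }
  } else if (kind == "chol") {
    for (comp in comps) out[[comp]] <- pars[[paste0("L", comp)]]
  } else if (kind == "ip") {
    for (comp in comps)
      out[[comp]] <- cbind(matrix(pars[[paste0("c", comp)]], k, 1),
                           diag(pars[[paste0("s", comp)]], k, k))
  } else {
    for (comp in comps)
      out[[comp]] <- cbind(matrix(pars$latent[[comp]] * pars$lambda, k, 1),
                           diag(pars[[paste0("s", comp)]], k, k))
  }
  out
}

## ---- data preparation ----

.groupsForSex <- function(sex, includeOS = FALSE) {
  switch(sex,
         F = c("MZ_F", "DZ_F"),
         M = c("MZ_M", "DZ_M"),
         both = if (includeOS) .zygosityLevels else
           c("MZ_F", "MZ_M", "DZ_F", "DZ_M"))
}

.fitData <- function(cohort, traits, groups) {
  counts <- zygosityCounts(cohort)
  dat <- list()
  for (g in intersect(groups, names(which(counts > 0)))) {
    ct <- contingencyTable(cohort, traits, g)
    if (ct@nComplete == 0) next
    dat[[g]] <- list(group = g, counts = ct@counts, n = ct@nComplete,
                     sexes = .groupSexes(g))
  }
  dat
}

.dataDigest <- function(dat, traits) {
  list(traits = traits,
       groups = vapply(dat, function(d) d$n, numeric(1)))
}

## ---- correlation-informed starting values ----

.psdProject <- function(S, floor = 0.02) {
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  v <- pmax(e$values, floor)
  e$vectors %*% (t(e$vectors) * v)
}

.corMatrices <- function(cohort, sex) {
  traits <- traitNames(cohort)
  k <- length(traits)
  mz <- paste0("MZ_", sex); dz <- paste0("DZ_", sex)
  fill <- function(group) {
    R <- diag(k)
    for (i in seq_len(k)) {
      r <- intraclassTetrachoric(cohort, traits[i], group)@rho
      R[i, i] <- if (is.na(r)) 0.4 else r
    }
    if (k > 1) {
      for (i in seq_len(k - 1)) for (j in (i + 1):k) {
        r <- crossTwinCrossTrait(cohort, traits[i], traits[j], group)@rho
        R[i, j] <- R[j, i] <- if (is.na(r)) 0.1 else r
      }
    }
    R
  }
  Rw <- diag(k)
  if (k > 1) {
    sub <- subsetCohort(cohort, groups = c(mz, dz))
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      r <- phenotypicCorrelation(sub, traits[i], traits[j])@rho
      Rw[i, j] <- Rw[j, i] <- if (is.na(r)) 0.2 else r
    }
  }
  list(RMZ = fill(mz), RDZ = fill(dz), Rw = Rw)
}

.startFromCorrelations <- function(skel, cohort, sex, traits) {
  k <- skel$k
  cm <- .corMatrices(cohort, if (sex == "both") "F" else sex)
  RMZ <- cm$RMZ; RDZ <- cm$RDZ; Rw <- cm$Rw
  hasD <- "D" %in% skel$comps
  hasC <- "C" %in% skel$comps
  if (hasD) {
    SA <- 4 * RDZ - RMZ
    SD <- 2 * RMZ - 4 * RDZ
    SC <- matrix(0, k, k)
  } else if (hasC) {
    SA <- 2 * (RMZ - RDZ)
    SC <- 2 * RDZ - RMZ
    SD <- matrix(0, k, k)
  } else {
    SA <- if ("A" %in% skel$comps) 0.8 * RMZ + 0.4 * RDZ else matrix(0, k, k)
    SD <- SC <- matrix(0, k, k)
  }
  SE <- Rw - RMZ
  diag(SE) <- pmax(1 - diag(SA) - diag(SD) - diag(SC), 0.1)
  proj <- function(S, floor) .psdProject(S, floor)
  SA <- proj(SA, 0.02); SD <- proj(SD, 0.005); SC <- proj(SC, 0.005)
  SE <- proj(SE, 0.05)
  raw <- list()
  if (skel$kind == "uni") {
    for (comp in skel$comps) {
      S0 <- switch(comp, A = SA, D = SD, C = SC, E = SE)
      raw[[tolower(comp)]] <- sqrt(max(S0[1, 1], 0.02))
    }
  } else if (skel$kind == "chol") {
    for (comp in skel$comps) {
      S0 <- switch(comp, A = SA, D = SD, C = SC, E = SE)
      L <- t(chol(S0 + diag(1e-4, k)))
      raw[[paste0("L", comp)]] <- L[.ltriIndex(k)]
    }
  } else if (skel$kind == "ip") {
    for (comp in skel$comps) {
      S0 <- switch(comp, A = SA, D = SD, C = SC, E = SE)
      e <- eigen(S0, symmetric = TRUE)
      cv <- e$vectors[, 1] * sqrt(max(e$values[1], 0.01))
      if (cv[which.max(abs(cv))] < 0) cv <- -cv
      sv <- sqrt(pmax(diag(S0) - cv^2, 0.02))
      raw[[paste0("c", comp)]] <- cv
      raw[[paste0("s", comp)]] <- sv
    }
  } else { # cp
    lam <- rep(0.5, k)
    if (k >= 3 && all(abs(Rw[upper.tri(Rw)]) > 0.02)) {
      lam <- vapply(seq_len(k), function(i) {
        oth <- setdiff(seq_len(k), i)
        sqrt(abs(Rw[i, oth[1]] * Rw[i, oth[2]] / Rw[oth[1], oth[2]]))
      }, numeric(1))
    }
    lam <- pmin(pmax(lam, 0.2), 0.9)
    off <- function(S) {
      vals <- (S / tcrossprod(lam))[upper.tri(S)]
      stats::median(vals)
    }
    u2 <- c(A = min(max(off(SA), 0.05), 0.85),
            D = if (hasD) min(max(off(SD), 0.01), 0.5) else 0,
            C = if (hasC) min(max(off(SC), 0.01), 0.5) else 0)
    uE2 <- max(1 - sum(u2), 0.05)
    uAll <- c(u2, E = uE2)
    uAll <- uAll / sum(uAll)
    raw$latent <- sqrt(uAll[skel$comps])
    raw$lambda <- lam
    for (comp in skel$comps) {
      S0 <- switch(comp, A = SA, D = SD, C = SC, E = SE)
      raw[[paste0("s", comp)]] <-
        sqrt(pmax(diag(S0) - uAll[[comp]] * lam^2, 0.02))
    }
  }
  ## flatten in skeleton order, respecting free masks
  theta <- numeric(0)
  for (b in skel$blocks) {
    vals <- raw[[b$name]]
    if (is.null(vals) || length(vals) != b$len) vals <- b$init
    theta <- c(theta, vals[b$free])
  }
  theta
}

.thresholdStart <- function(cohort, traits, sexes) {
  out <- numeric(0)
  for (s in sexes) {
    pv <- vapply(traits, function(tr) {
      p <- suppressWarnings(prevalence(cohort, tr, s))
      if (is.na(p)) 0.25 else min(max(p, 0.005), 0.995)
    }, numeric(1))
    out <- c(out, stats::qnorm(1 - pv))
  }
  out
}

## ---- canonicalization: nonnegative leading entries per factor column ----

.canonicalizePars <- function(pars, kind, k) {
  flipCol <- function(v) {
    nz <- which(abs(v) > 1e-10)
    if (length(nz) && v[nz[1]] < 0) -v else v
  }
  if (kind == "uni") {
    pars <- lapply(pars, abs)
  } else if (kind == "chol") {
    for (nm in names(pars)) {
      L <- pars[[nm]]
      for (j in seq_len(ncol(L))) L[, j] <- flipCol(L[, j])
      pars[[nm]] <- L
    }
  } else if (kind == "ip") {
    for (nm in names(pars)) {
      if (startsWith(nm, "c")) pars[[nm]] <- flipCol(pars[[nm]])
      else pars[[nm]] <- abs(pars[[nm]])
    }
  } else {
    pars$latent <- abs(pars$latent)
    pars$lambda <- flipCol(pars$lambda)
    for (nm in names(pars))
      if (startsWith(nm, "s")) pars[[nm]] <- abs(pars[[nm]])
  }
  pars
}

## ---- the fitter ----

#' Fit a liability-threshold twin model by full-information ML
#'
#' Maximizes the joint pattern likelihood over standardized path loadings
#' and per-sex thresholds. Unit liability variance per trait and sex is
#' imposed by exact rescaling inside the likelihood (plus a vanishing
#' quadratic penalty that removes the resulting flat directions), so
#' variance components enter as squared loadings and are nonnegative by
#' construction. Multiple starts are used: a correlation-informed start
#' derived from tetrachoric correlation matrices, plus deterministically
#' jittered copies.
#'
#' Univariate families use all five zygosity groups (sex-specific
#' parameters unless equated; opposite-sex pairs anchor the cross-sex
#' relatedness at \code{rAos}/\code{rDos}). Multivariate families are
#' fitted per sex on MZ + same-sex DZ pairs; a joint two-sex multivariate
#' fit is available with \code{sex = "both"} and
#' \code{constraints = list(sexEqual = TRUE)} (optionally including DZ_OS
#' pairs via \code{options$includeOS}).
#'
#' @param family \code{"univariate_ADE"} (alias \code{"ADE"}), ...,
#'   \code{"cholesky"}, \code{"independent_pathway"},
#'   \code{"common_pathway"}, or \code{"saturated"} (univariate only: free
#'   correlation and thresholds per group).
#' @param cohort a \linkS4class{TwinCohort}. For univariate families the
#'   cohort must contain exactly one trait (or pass \code{trait}).
#' @param sex \code{"both"} (default for univariate), \code{"F"} or
#'   \code{"M"} (multivariate default is per-sex).
#' @param trait for univariate families on a multi-trait cohort: which
#'   trait to fit.
#' @param constraints list with optional entries \code{sexEqual} (equate
#'   all loadings across sexes; thresholds stay sex-specific),
#'   \code{components} (e.g. \code{c("A", "E")} to drop D from a
#'   multivariate family) and \code{dropD} (trait names whose dominance
#'   loadings are fixed to zero).
#' @param options list with optional entries \code{nStarts} (default 5),
#'   \code{maxit}, \code{relTol} (relative convergence tolerance on the
#'   objective, default 1e-7), \code{engine} (quadrature settings overriding
#'   \code{nOuter}/\code{nInner}/\code{deltaMin}), \code{includeOS},
#'   \code{bicUnits} (\code{"pairs"}, the default, or
#'   \code{"individuals"}).
#' @return A \linkS4class{TwinFit}.
#' @examples
#' sp <- biometricSpec("univariate_ADE", "CMD",
#'                     paramsF = list(a = sqrt(0.5), d = sqrt(0.2),
#'                                    e = sqrt(0.3)),
#'                     prevalencesF = 0.3)
#' co <- simulateCohort(sp, c(MZ_F = 2000, DZ_F = 2000), seed = 7)
#' fit <- fitBiometric("AE", co, sex = "F")
#' fitStats(fit)
#' @export
fitBiometric <- function(family, cohort, sex = NULL, trait = NULL,
                         constraints = list(), options = list()) {
  stopifnot(methods::is(cohort, "TwinCohort"))
  fi <- .familyKind(family)
  family <- fi$family
  kind <- fi$kind

  opts <- utils::modifyList(
    list(nStarts = 5, maxit = 300, relTol = 1e-7, engine = list(),
         includeOS = FALSE, bicUnits = "pairs", verbose = FALSE), options)
  eng <- utils::modifyList(.engineDefaults(), opts$engine)

  if (kind == "saturated")
    return(.fitSaturated(cohort, trait, opts))

  if (kind == "uni") {
    traits <- if (!is.null(trait)) trait else traitNames(cohort)
    if (length(traits) != 1)
      stop("univariate families need a single trait; pass 'trait'")
    if (!is.null(trait) && !identical(traitNames(cohort), trait)) {
      keep <- c("pairId", "zygosity", "sex1", "sex2", "cohortLabel",
                paste0(trait, c("_1", "_2")))
      cohort <- twinCohort(pairData(cohort)[, keep], trait)
    }
    comps <- .uniComponents(family)
    if (is.null(sex)) sex <- "both"
  } else {
    traits <- traitNames(cohort)
    if (length(traits) < 2)
      stop("multivariate families need at least two traits")
    comps <- constraints$components
    if (is.null(comps)) comps <- c("A", "D", "E")
    if (!"E" %in% comps) stop("the E component is always present")
    if (all(c("C", "D") %in% comps))
      stop("C and D are not jointly identified from twins reared together")
    if (is.null(sex)) sex <- "F"
  }
  sex <- match.arg(sex, c("both", "F", "M"))
  sexEqual <- isTRUE(constraints$sexEqual)
  dropD <- constraints$dropD
  if (is.null(dropD)) dropD <- character(0)

  if (kind != "uni" && sex == "both" && !sexEqual)
    stop("multivariate fits are per sex; use sex='F'/'M', or set ",
         "constraints$sexEqual=TRUE for a joint two-sex fit")

  k <- length(traits)
  groups <- .groupsForSex(sex, includeOS = (kind == "uni") || opts$includeOS)
  dat <- .fitData(cohort, traits, groups)
  if (!length(dat)) stop("no complete pairs in the requested groups")
  dataSexes <- unique(unlist(lapply(dat, function(d) d$sexes)))
  dataSexes <- intersect(c("F", "M"), dataSexes)

  ## parameter sets: one when equated or single-sex, else one per sex
  setSexes <- if (sexEqual || length(dataSexes) == 1)
    list(FM = dataSexes) else list(F = "F", M = "M")
  skel <- .skeleton(kind, k, comps, dropD, traits)
  nSets <- length(setSexes)
  nLoad <- skel$nFree

  thetaStart <- numeric(0)
  corStart <- tryCatch({
    s0 <- numeric(0)
    for (i in seq_len(nSets)) {
      sx <- if (nSets == 2) names(setSexes)[i] else
        if (length(dataSexes) == 1) dataSexes else "both"
      s0 <- c(s0, .startFromCorrelations(skel, cohort, sx, traits))
    }
    s0
  }, error = function(e) NULL)
  defStart <- rep(.packInit(skel), nSets)
  if (is.null(corStart) || length(corStart) != length(defStart))
    corStart <- defStart
  tauStart <- .thresholdStart(cohort, traits, dataSexes)
  thetaStart <- c(corStart, tauStart)
  nTheta <- length(thetaStart)
  tauIdx <- nSets * nLoad + seq_along(tauStart)

  sexToSet <- function(s) {
    if (nSets == 1) 1L else match(s, names(setSexes))
  }
  tauFor <- function(s, tau) {
    i <- match(s, dataSexes)
    tau[(i - 1) * k + seq_len(k)]
  }

  engCoarse <- utils::modifyList(eng, list(nOuter = 5, nInner = 5))

  evalModel <- function(theta, engineOpts) {
    tau <- theta[tauIdx]
    sets <- vector("list", nSets)
    penalty <- 0
    for (i in seq_len(nSets)) {
      seg <- theta[(i - 1) * nLoad + seq_len(nLoad)]
      st <- .standardizeSet(.unpackSet(seg, skel), skel, traits)
      penalty <- penalty + st$penalty
      sets[[i]] <- .loadingsFromPars(st$pars, kind, k, comps)
    }
    nll <- 0
    for (d in dat) {
      L1 <- sets[[sexToSet(d$sexes[1])]]
      L2 <- sets[[sexToSet(d$sexes[2])]]
      r <- .relatedness(d$group)
      Sx <- r[["A"]] * tcrossprod(L1$A, L2$A) +
        r[["D"]] * tcrossprod(L1$D, L2$D) +
        r[["C"]] * tcrossprod(L1$C, L2$C)
      tau1 <- tauFor(d$sexes[1], tau)
      tau2 <- tauFor(d$sexes[2], tau)
      if (k == 1) {
        p <- .bivPatternProbs(tau1, tau2, Sx[1, 1])
      } else {
        Sw <- Reduce(`+`, lapply(L1, tcrossprod))
        p <- .pairEngine(Sw, (Sx + t(Sx)) / 2, tau1, tau2, engineOpts)
      }
      use <- d$counts > 0
      nll <- nll - sum(d$counts[use] * log(pmax(p[use], 1e-300)))
    }
    list(nll = nll, penalty = penalty)
  }
  ## unit-variance penalty scaled to the likelihood's curvature so the
  ## rescaling ray is well-conditioned (it vanishes at the optimum)
  penaltyW <- 100
  mkObjective <- function(engineOpts) function(theta) {
    em <- evalModel(theta, engineOpts)
    em$nll + penaltyW * em$penalty
  }
  fdGradient <- function(fn) function(theta) {
    f0 <- fn(theta)
    h <- 1e-6 * pmax(abs(theta), 1)
    vapply(seq_along(theta), function(i) {
      th <- theta
      th[i] <- th[i] + h[i]
      (fn(th) - f0) / h[i]
    }, numeric(1))
  }
  objCoarse <- mkObjective(engCoarse)
  objFine <- mkObjective(eng)

  lower <- c(rep(-3, nSets * nLoad), rep(-5, length(tauStart)))
  upper <- c(rep(3, nSets * nLoad), rep(5, length(tauStart)))

  runStart <- function(theta0) {
    if (k > 1) {
      p1 <- stats::optim(theta0, objCoarse, gr = fdGradient(objCoarse),
                         method = "L-BFGS-B", lower = lower, upper = upper,
                         control = list(maxit = opts$maxit, factr = 1e9))
      theta0 <- p1$par
    }
    ## univariate likelihoods are cheap and exact: converge them tightly so
    ## nested-model differences are numerically clean
    factr <- if (k > 1) opts$relTol / 2.2e-16 else 1e7
    p2 <- stats::optim(theta0, objFine, gr = fdGradient(objFine),
                       method = "L-BFGS-B", lower = lower, upper = upper,
                       control = list(maxit = if (k > 1) 80 else opts$maxit,
                                      factr = factr))
    list(par = p2$par, objective = p2$value,
         convergence = p2$convergence, message = p2$message)
  }

  starts <- list(thetaStart)
  if (opts$nStarts > 1) {
    for (s in 2:opts$nStarts) {
      jit <- .withSeed(97 + 131 * s + nTheta, {
        th <- thetaStart
        th[seq_len(nSets * nLoad)] <-
          th[seq_len(nSets * nLoad)] * exp(stats::rnorm(nSets * nLoad, 0, 0.2)) +
          stats::rnorm(nSets * nLoad, 0, 0.03)
        th[tauIdx] <- th[tauIdx] + stats::rnorm(length(tauIdx), 0, 0.05)
        th
      })
      starts[[s]] <- jit
    }
  }

  best <- NULL
  startLog <- data.frame(start = integer(), objective = numeric(),
                         convergence = integer(), stringsAsFactors = FALSE)
  for (s in seq_along(starts)) {
    opt <- tryCatch(runStart(starts[[s]]), error = function(e) NULL)
    if (is.null(opt)) next
    startLog <- rbind(startLog,
                      data.frame(start = s, objective = opt$objective,
                                 convergence = opt$convergence,
                                 stringsAsFactors = FALSE))
    if (is.null(best) || opt$objective < best$objective) best <- opt
  }
  if (is.null(best))
    stop("all optimization starts failed")

  em <- evalModel(best$par, eng)
  minus2LnL <- 2 * em$nll
  flags <- character()
  if (best$convergence != 0)
    flags <- c(flags, paste0("optimizer:", best$message))

  ## standardized, canonicalized parameters per set
  tau <- best$par[tauIdx]
  setPars <- list()
  for (i in seq_len(nSets)) {
    seg <- best$par[(i - 1) * nLoad + seq_len(nLoad)]
    st <- .standardizeSet(.unpackSet(seg, skel), skel, traits)
    setPars[[i]] <- .canonicalizePars(st$pars, kind, k)
  }

  ## boundary flags: any component variance of a trait below 5e-3
  for (i in seq_len(nSets)) {
    lm <- .loadingsFromPars(setPars[[i]], kind, k, comps)
    for (comp in comps) {
      vc <- rowSums(lm[[comp]]^2)
      if (any(vc < 5e-3)) {
        flags <- c(flags, "boundary")
        break
      }
    }
  }
  flags <- unique(flags)

  parsBySex <- function(s) {
    if (!s %in% dataSexes) return(setPars[[1]])
    setPars[[sexToSet(s)]]
  }
  tauBySex <- function(s) {
    if (!s %in% dataSexes) return(tauFor(dataSexes[1], tau))
    tauFor(s, tau)
  }
  specOut <- biometricSpec(family, traits,
                           paramsF = .parsAsFamily(parsBySex("F"), kind, k),
                           paramsM = .parsAsFamily(parsBySex("M"), kind, k),
                           thresholdsF = tauBySex("F"),
                           thresholdsM = tauBySex("M"))

  est <- numeric(0)
  for (i in seq_len(nSets)) {
    prefix <- names(setSexes)[i]
    flat <- .flattenPars(setPars[[i]], kind, k, traits)
    names(flat) <- paste0(prefix, ".", names(flat))
    est <- c(est, flat)
  }
  for (s in dataSexes)
    est <- c(est, stats::setNames(tauFor(s, tau),
                                  paste0("tau.", s, ".", traits)))

  nUnits <- sum(vapply(dat, function(d) d$n, numeric(1)))
  if (opts$bicUnits == "individuals") nUnits <- 2 * nUnits
  nParams <- nSets * (skel$nFree - skel$nConstraints) + length(tauStart)

  methods::new("TwinFit", spec = specOut, sex = sex, estimates = est,
               minus2LnL = minus2LnL, nParams = nParams,
               aic = minus2LnL + 2 * nParams,
               bic = minus2LnL + nParams * log(nUnits),
               nUnits = nUnits, convergedFlag = best$convergence == 0,
               flags = flags,
               details = list(starts = startLog,
                              digest = .dataDigest(dat, traits),
                              sexEqual = sexEqual, comps = comps,
                              kind = kind, penalty = em$penalty))
}

## standardized set -> family parameter list as stored in BiometricSpec
.parsAsFamily <- function(pars, kind, k) {
  pars
}

.flattenPars <- function(pars, kind, k, traits) {
  out <- numeric(0)
  for (nm in names(pars)) {
    v <- pars[[nm]]
    if (is.matrix(v)) {
      idx <- .ltriIndex(k)
      labs <- paste0(nm, "[", row(v)[idx], ",", col(v)[idx], "]")
      out <- c(out, stats::setNames(v[idx], labs))
    } else if (nm == "latent") {
      out <- c(out, stats::setNames(v, paste0("latent.", names(v))))
    } else {
      out <- c(out, stats::setNames(v, paste0(nm, "[", seq_along(v), "]")))
    }
  }
  out
}

## Saturated univariate model: free correlation + free thresholds per group.
.fitSaturated <- function(cohort, trait, opts) {
  traits <- if (!is.null(trait)) trait else traitNames(cohort)
  if (length(traits) != 1)
    stop("the saturated family is available for a single trait")
  dat <- .fitData(cohort, traits, .zygosityLevels)
  if (!length(dat)) stop("no complete pairs")
  m2ll <- 0
  est <- numeric(0)
  nPar <- 0
  nUnits <- 0
  for (d in dat) {
    tab <- matrix(c(d$counts[["0|0"]], d$counts[["1|0"]],
                    d$counts[["0|1"]], d$counts[["1|1"]]), 2, 2)
    fit <- tetrachoricMLE(tab)
    rho <- if (is.na(fit@rho)) 0 else fit@rho
    p <- pmax(.cellProbs(rho, fit@tauRow, fit@tauCol), 1e-300)
    ll <- tab[1, 1] * log(p[1, 1]) + tab[2, 1] * log(p[2, 1]) +
      tab[1, 2] * log(p[1, 2]) + tab[2, 2] * log(p[2, 2])
    m2ll <- m2ll - 2 * ll
    est <- c(est, stats::setNames(c(rho, fit@tauRow, fit@tauCol),
                                  paste0(d$group, c(".rho", ".tau1", ".tau2"))))
    nPar <- nPar + 3
    nUnits <- nUnits + d$n
  }
  spec <- methods::new("BiometricSpec", family = "saturated",
                       traits = traits, paramsF = list(), paramsM = list(),
                       thresholdsF = 0, thresholdsM = 0)
  methods::new("TwinFit", spec = spec, sex = "both", estimates = est,
               minus2LnL = m2ll, nParams = nPar,
               aic = m2ll + 2 * nPar, bic = m2ll + nPar * log(nUnits),
               nUnits = nUnits, convergedFlag = TRUE, flags = character(),
               details = list(digest = .dataDigest(dat, traits),
                              kind = "saturated"))
}

#' Rank fitted models by information criteria
#'
#' @param ... \linkS4class{TwinFit} objects (or a single list of them)
#'   fitted to the same cohort and trait set.
#' @return data.frame sorted by AIC with columns \code{model}, \code{sex},
#'   \code{minus2LnL}, \code{nParams}, \code{aic}, \code{bic},
#'   \code{dAIC}, \code{dBIC}, \code{dMinus2LnL} and \code{dDf} (against
#'   the least-constrained model supplied). The attribute
#'   \code{criterionDisagreement} is \code{TRUE} when AIC and BIC disagree
#'   on the winner; attributes \code{aicWinner}/\code{bicWinner} name them.
#' @export
compareFits <- function(...) {
  fits <- list(...)
  if (length(fits) == 1 && is.list(fits[[1]]) &&
      !methods::is(fits[[1]], "TwinFit"))
    fits <- fits[[1]]
  stopifnot(length(fits) >= 1)
  for (f in fits) stopifnot(methods::is(f, "TwinFit"))
  d0 <- fits[[1]]@details$digest
  for (f in fits)
    if (!identical(f@details$digest, d0))
      stop("fits were not computed on the same cohort/trait set")
  ref <- which.max(vapply(fits, function(f) f@nParams, numeric(1)))
  df <- data.frame(
    model = vapply(fits, function(f) f@spec@family, character(1)),
    sex = vapply(fits, function(f) f@sex, character(1)),
    sexEqual = vapply(fits, function(f)
      isTRUE(f@details$sexEqual), logical(1)),
    minus2LnL = vapply(fits, function(f) f@minus2LnL, numeric(1)),
    nParams = vapply(fits, function(f) f@nParams, numeric(1)),
    aic = vapply(fits, function(f) f@aic, numeric(1)),
    bic = vapply(fits, function(f) f@bic, numeric(1)),
    converged = vapply(fits, function(f) f@convergedFlag, logical(1)),
    stringsAsFactors = FALSE)
  df$dMinus2LnL <- df$minus2LnL - df$minus2LnL[ref]
  df$dDf <- df$nParams[ref] - df$nParams
  df$dAIC <- df$aic - min(df$aic)
  df$dBIC <- df$bic - min(df$bic)
  ord <- order(df$aic, df$nParams)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  aw <- df$model[1]
  bw <- df$model[which.min(df$bic)]
  attr(df, "aicWinner") <- aw
  attr(df, "bicWinner") <- bw
  attr(df, "criterionDisagreement") <- !identical(aw, bw)
  df
}

#' Test equality of genetic and environmental effects across sexes
#'
#' Fits a univariate model twice - once with sex-specific loadings, once
#' with loadings equated across sexes (thresholds remain sex-specific) -
#' and compares them by likelihood-ratio test and information criteria.
#' Opposite-sex DZ pairs provide the cross-sex information (relatedness
#' fixed at 0.5 for A and 0.25 for D).
#'
#' @param family univariate model family (e.g. \code{"ADE"}, \code{"AE"}).
#' @param cohort a \linkS4class{TwinCohort} containing both sexes.
#' @param trait trait to analyse (for multi-trait cohorts).
#' @param options passed to \code{\link{fitBiometric}}.
#' @return List of class \code{"sexEqualityTest"} with elements
#'   \code{sexSpecific}, \code{equated} (\linkS4class{TwinFit}),
#'   \code{lrt}, \code{df}, \code{pValue}, \code{aicPreferred},
#'   \code{bicPreferred}.
#' @export
sexEqualityTest <- function(family, cohort, trait = NULL, options = list()) {
  fi <- .familyKind(family)
  if (fi$kind != "uni")
    stop("sex-equality testing is defined for univariate families")
  zc <- zygosityCounts(cohort)
  hasF <- zc[["MZ_F"]] + zc[["DZ_F"]] > 0
  hasM <- zc[["MZ_M"]] + zc[["DZ_M"]] > 0
  if (!(hasF && hasM))
    if (zc[["DZ_OS"]] == 0)
      warning("only one sex represented and no DZ_OS pairs: ",
              "sex differences are under-identified")
  free <- fitBiometric(family, cohort, sex = "both", trait = trait,
                       constraints = list(sexEqual = FALSE),
                       options = options)
  eq <- fitBiometric(family, cohort, sex = "both", trait = trait,
                     constraints = list(sexEqual = TRUE), options = options)
  lrt <- max(eq@minus2LnL - free@minus2LnL, 0)
  df <- free@nParams - eq@nParams
  out <- list(sexSpecific = free, equated = eq, lrt = lrt, df = df,
              pValue = stats::pchisq(lrt, df, lower.tail = FALSE),
              aicPreferred = if (free@aic < eq@aic) "sex-specific" else "equated",
              bicPreferred = if (free@bic < eq@bic) "sex-specific" else "equated")
  class(out) <- "sexEqualityTest"
  out
}

#' @export
print.sexEqualityTest <- function(x, ...) {
  cat("Sex-equality test (", x$sexSpecific@spec@family, ")\n", sep = "")
  cat(sprintf("  LRT = %.3f on %d df, p = %.4g\n", x$lrt, x$df, x$pValue))
  cat(sprintf("  AIC prefers %s; BIC prefers %s\n",
              x$aicPreferred, x$bicPreferred))
  invisible(x)
}
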