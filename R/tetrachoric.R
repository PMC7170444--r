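#' @include simulate.R
NULL

.phi2 <- function(h, k, r) .phi2Cpp(as.numeric(h), as.numeric(k), as.numeric(r))

## 2x2 cell probabilities under the bivariate liability model.
## tab[i, j] = P(rowVar = i-1, colVar = j-1)
.cellProbs <- function(rho, tauR, tauC) {
  p00 <- .phi2(tauR, tauC, rho)
  pR <- stats::pnorm(tauR)
  pC <- stats::pnorm(tauC)
  matrix(c(p00, pC - p00, pR - p00, 1 - pR - pC + p00), 2, 2)
}

#' Maximum-likelihood tetrachoric correlation from a 2x2 table
#'
#' Estimates the latent bivariate-normal correlation and both thresholds by
#' full maximum likelihood over the multinomial cell probabilities (the
#' thresholds are estimated jointly with the correlation, not fixed at the
#' margin quantiles). The correlation is constrained to [-0.999, 0.999]
#' during optimization; estimates beyond 0.995 in absolute value are flagged
#' \code{"boundary"}. A table with an empty cell leaves a flat ridge in the
#' joint parameter space, so the constrained convention is used there:
#' thresholds at the margin quantiles, the correlation profiled along the
#' allowed interval (settling at the boundary when the profile is flat).
#' A table with an all-zero row or column has no defined
#' correlation: \code{rho} is \code{NA} with flag \code{"degenerate"} and
#' the remaining threshold(s) are still reported.
#'
#' @param tab 2x2 nonnegative count matrix; \code{tab[i, j]} counts
#'   observations with row variable \code{i - 1} and column variable
#'   \code{j - 1}.
#' @param symmetric constrain the two thresholds to be equal (used for
#'   double-entered intraclass tables).
#' @param doubleEntered the table holds each pair twice (both orders); the
#'   observed information is halved accordingly, widening the standard
#'   error by \code{sqrt(2)}.
#' @param nEff number of independent units to report (defaults to
#'   \code{sum(tab)}; for double-entered tables pass the pair count).
#' @return A \linkS4class{TetrachoricEstimate}.
#' @examples
#' tetrachoricMLE(matrix(c(25, 25, 25, 25), 2))   # rho = 0
#' @export
tetrachoricMLE <- function(tab, symmetric = FALSE, doubleEntered = FALSE,
                           nEff = NULL) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == 2), all(tab >= 0))
  n <- sum(tab)
  if (n <= 0) stop("table has no observations")
  if (is.null(nEff)) nEff <- n
  flags <- character()
  if (doubleEntered) flags <- c(flags, "double-entry")

  rowMarg <- rowSums(tab)
  colMarg <- colSums(tab)
  if (any(rowMarg == 0) || any(colMarg == 0)) {
    tauR <- if (all(rowMarg > 0)) stats::qnorm(rowMarg[1] / n) else
      if (rowMarg[1] == 0) -Inf else Inf
    tauC <- if (all(colMarg > 0)) stats::qnorm(colMarg[1] / n) else
      if (colMarg[1] == 0) -Inf else Inf
    return(methods::new("TetrachoricEstimate", rho = NA_real_,
                        tauRow = unname(tauR), tauCol = unname(tauC),
                        seRho = NA_real_, n = nEff,
                        flags = c(flags, "degenerate")))
  }

  negll <- function(theta) {
    rho <- theta[1]
    tauR <- theta[2]
    tauC <- if (symmetric) theta[2] else theta[3]
    p <- pmax(.cellProbs(rho, tauR, tauC), 1e-12)
    -sum(tab * log(p))
  }
  tauR0 <- stats::qnorm(rowMarg[1] / n)
  tauC0 <- stats::qnorm(colMarg[1] / n)
  a <- tab[1, 1] + 0.5; b <- tab[1, 2] + 0.5
  cc <- tab[2, 1] + 0.5; d <- tab[2, 2] + 0.5
  rho0 <- cos(pi / (1 + sqrt(a * d / (b * cc))))  # odds-ratio approximation
  rho0 <- max(min(rho0, 0.99), -0.99)
  taus0 <- if (symmetric) (tauR0 + tauC0) / 2 else c(tauR0, tauC0)
  if (any(tab == 0)) {
    ## an empty cell leaves a flat ridge in (rho, tau) space: adopt the
    ## constrained convention - thresholds at the margin quantiles, the
    ## correlation profiled along [-0.999, 0.999]
    prof <- stats::optimize(function(r)
      negll(c(r, taus0)), interval = c(-0.999, 0.999), tol = 1e-9)
    rhoHat <- max(min(prof$minimum, 0.999), -0.999)
    ## on a numerically flat tail, settle at the boundary itself
    for (rb in c(-0.999, 0.999))
      if (negll(c(rb, taus0)) <= prof$objective + 1e-6) rhoHat <- rb
    opt <- list(par = c(rhoHat, taus0))
  } else {
    lower <- c(-0.999, rep(-6, length(taus0)))
    upper <- c(0.999, rep(6, length(taus0)))
    ## several correlation starts guard against flat or near-boundary
    ## likelihood surfaces
    opt <- NULL
    for (r0 in unique(c(rho0, 0, 0.95, -0.95))) {
      o <- stats::nlminb(c(r0, taus0), negll, lower = lower, upper = upper,
                         control = list(rel.tol = 1e-12, iter.max = 500))
      if (is.null(opt) || o$objective < opt$objective) opt <- o
    }
  }
  rho <- opt$par[1]
  tauR <- opt$par[2]
  tauC <- if (symmetric) opt$par[2] else opt$par[3]
  if (abs(rho) > 0.995) flags <- c(flags, "boundary")

  se <- NA_real_
  if (abs(rho) < 0.995) {
    h <- 1e-4
    m <- length(opt$par)
    H <- matrix(0, m, m)
    f0 <- negll(opt$par)
    for (i in seq_len(m)) {
      for (j in i:m) {
        ei <- ej <- rep(0, m); ei[i] <- h; ej[j] <- h
        H[i, j] <- H[j, i] <-
          (negll(opt$par + ei + ej) - negll(opt$par + ei) -
             negll(opt$par + ej) + f0) / h^2
      }
    }
    V <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(V) && V[1, 1] > 0) se <- sqrt(V[1, 1])
    if (doubleEntered && !is.na(se)) se <- se * sqrt(2)
  }
  methods::new("TetrachoricEstimate", rho = unname(rho),
               tauRow = unname(tauR), tauCol = unname(tauC),
               seRho = unname(se), n = nEff, flags = flags)
}

## 2x2 cross-twin table from a contingency table over one trait:
## rows = twin 1, cols = twin 2.
.pairTable <- function(ct) {
  cnt <- ct@counts
  matrix(c(cnt[["0|0"]], cnt[["1|0"]], cnt[["0|1"]], cnt[["1|1"]]), 2, 2)
}

#' Intraclass (cross-twin same-trait) tetrachoric correlation
#'
#' For same-sex groups the cross-twin table is double-entered (each pair in
#' both orders) before estimation, which forces the two thresholds to be
#' equal; the standard error is corrected for the doubled record count. For
#' opposite-sex pairs no double entry is applied: the female twin is always
#' the row variable (the cohort's ordering convention) and the thresholds
#' are sex-specific.
#'
#' @param cohort a \linkS4class{TwinCohort}.
#' @param trait trait name.
#' @param group zygosity group code.
#' @param doubleEntry use double entry for same-sex groups (default TRUE; a
#'   casewise convention is available by switching it off).
#' @return A \linkS4class{TetrachoricEstimate} with \code{n} = number of
#'   complete pairs.
#' @export
intraclassTetrachoric <- function(cohort, trait, group, doubleEntry = TRUE) {
  group <- match.arg(group, .zygosityLevels)
  ct <- contingencyTable(cohort, trait, group)
  tab <- .pairTable(ct)
  if (group == "DZ_OS")
    return(tetrachoricMLE(tab, symmetric = FALSE, nEff = ct@nComplete))
  if (doubleEntry)
    tetrachoricMLE(tab + t(tab), symmetric = TRUE, doubleEntered = TRUE,
                   nEff = ct@nComplete)
  else
    tetrachoricMLE(tab, symmetric = FALSE, nEff = ct@nComplete)
}

.crossTable <- function(p, traitA, traitB, first, second) {
  x <- p[[paste0(traitA, "_", first)]]
  y <- p[[paste0(traitB, "_", second)]]
  ok <- !is.na(x) & !is.na(y)
  tab <- matrix(0, 2, 2)
  if (any(ok))
    tab <- unclass(table(factor(x[ok], levels = 0:1),
                         factor(y[ok], levels = 0:1)))
  list(tab = tab, n = sum(ok))
}

#' Cross-twin cross-trait tetrachoric correlation
#'
#' Correlates one twin's \code{traitA} with the co-twin's \code{traitB}.
#' Same-sex groups pool both twin orders (double entry); for opposite-sex
#' pairs the two orientations are distinct estimands under sex-specific
#' parameters, so both are returned: \code{femaleA_maleB} (female twin's
#' \code{traitA} against male twin's \code{traitB}) and
#' \code{maleA_femaleB}.
#'
#' @param cohort a \linkS4class{TwinCohort}.
#' @param traitA,traitB distinct trait names.
#' @param group zygosity group code.
#' @return A \linkS4class{TetrachoricEstimate}, or for \code{DZ_OS} a named
#'   list of two.
#' @export
crossTwinCrossTrait <- function(cohort, traitA, traitB, group) {
  group <- match.arg(group, .zygosityLevels)
  if (identical(traitA, traitB))
    stop("traits must be distinct (use intraclassTetrachoric)")
  p <- cohort@pairs[cohort@pairs$zygosity == group, , drop = FALSE]
  t12 <- .crossTable(p, traitA, traitB, 1, 2)
  t21 <- .crossTable(p, traitA, traitB, 2, 1)
  if (group == "DZ_OS") {
    return(list(
      femaleA_maleB = tetrachoricMLE(t12$tab, nEff = t12$n),
      maleA_femaleB = tetrachoricMLE(t21$tab, nEff = t21$n)))
  }
  tetrachoricMLE(t12$tab + t21$tab, doubleEntered = TRUE,
                 nEff = round((t12$n + t21$n) / 2))
}

#' Within-individual (phenotypic) tetrachoric correlation
#'
#' Correlates two traits within individuals, pooling both twins of every
#' pair. The standard error uses the individual count without any
#' within-pair clustering correction and is flagged \code{"naive-se"}.
#'
#' @param cohort a \linkS4class{TwinCohort}.
#' @param traitA,traitB distinct trait names.
#' @return A \linkS4class{TetrachoricEstimate} with \code{n} = individuals.
#' @export
phenotypicCorrelation <- function(cohort, traitA, traitB) {
  if (identical(traitA, traitB)) stop("traits must be distinct")
  p <- cohort@pairs
  x <- c(p[[paste0(traitA, "_1")]], p[[paste0(traitA, "_2")]])
  y <- c(p[[paste0(traitB, "_1")]], p[[paste0(traitB, "_2")]])
  ok <- !is.na(x) & !is.na(y)
  tab <- unclass(table(factor(x[ok], levels = 0:1),
                       factor(y[ok], levels = 0:1)))
  est <- tetrachoricMLE(tab, nEff = sum(ok))
  est@flags <- c(est@flags, "naive-se")
  est
}

#' Tidy table of all twin correlations
#'
#' Computes the full correlation layout for a cohort: intraclass and
#' cross-twin cross-trait tetrachorics for every zygosity group present,
#' plus the within-individual phenotypic correlations.
#'
#' @param cohort a \linkS4class{TwinCohort}.
#' @param doubleEntry passed to \code{\link{intraclassTetrachoric}}.
#' @return data.frame with columns \code{group}, \code{traitA},
#'   \code{traitB}, \code{kind}, \code{orientation}, \code{rho}, \code{se},
#'   \code{n}, \code{flags}.
#' @export
correlationTable <- function(cohort, doubleEntry = TRUE) {
  traits <- traitNames(cohort)
  rows <- list()
  add <- function(group, a, b, kind, orientation, est) {
    rows[[length(rows) + 1]] <<- data.frame(
      group = group, traitA = a, traitB = b, kind = kind,
      orientation = orientation, rho = est@rho, se = est@seRho, n = est@n,
      flags = paste(est@flags, collapse = ";"), stringsAsFactors = FALSE)
  }
  present <- names(which(zygosityCounts(cohort) > 0))
  for (g in present) {
    for (tr in traits)
      add(g, tr, tr, "intraclass", "symmetric",
          intraclassTetrachoric(cohort, tr, g, doubleEntry))
    if (length(traits) < 2) next
    combs <- utils::combn(traits, 2)
    for (j in seq_len(ncol(combs))) {
      a <- combs[1, j]; b <- combs[2, j]
      est <- crossTwinCrossTrait(cohort, a, b, g)
      if (g == "DZ_OS") {
        add(g, a, b, "cross-twin-cross-trait", "femaleA_maleB",
            est$femaleA_maleB)
        add(g, a, b, "cross-twin-cross-trait", "maleA_femaleB",
            est$maleA_femaleB)
      } else {
        add(g, a, b, "cross-twin-cross-trait", "pooled", est)
      }
    }
  }
  if (length(traits) >= 2) {
    combs <- utils::combn(traits, 2)
    for (j in seq_len(ncol(combs))) {
      a <- combs[1, j]; b <- combs[2, j]
      add("all", a, b, "phenotypic", "within-individual",
          phenotypicCorrelation(cohort, a, b))
    }
  }
  do.call(rbind, rows)
}
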