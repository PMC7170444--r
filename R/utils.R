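#' @include AllClasses.R
NULL

## Run code with a temporary RNG state; leaves the caller's stream untouched.
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed %% 2147483647L))
  force(expr)
}

## Probabilists' Gauss-Hermite rule (weight = standard normal density);
## weights sum to 1. Golub-Welsch on the Jacobi matrix.
.gaussHermite <- function(n) {
  if (n == 1) return(list(nodes = 0, weights = 1))
  J <- matrix(0, n, n)
  off <- sqrt(seq_len(n - 1))
  J[cbind(seq_len(n - 1), seq_len(n - 1) + 1L)] <- off
  J[cbind(seq_len(n - 1) + 1L, seq_len(n - 1))] <- off
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord], weights = (e$vectors[1, ]^2)[ord])
}

## Tensor product grid over q dimensions with small-weight pruning;
## weights renormalized to sum 1 so pattern probabilities sum exactly to 1.
.ghGrid <- function(n, q, prune = 1e-9) {
  if (q == 0) return(list(nodes = matrix(0, 1, 0), weights = 1))
  gh <- .gaussHermite(n)
  idx <- as.matrix(expand.grid(rep(list(seq_len(n)), q)))
  nodes <- matrix(gh$nodes[idx], ncol = q)
  w <- gh$weights[idx[, 1]]
  if (q > 1) for (j in 2:q) w <- w * gh$weights[idx[, j]]
  keep <- w > prune
  nodes <- nodes[keep, , drop = FALSE]
  w <- w[keep]
  list(nodes = nodes, weights = w / sum(w))
}

.ghGridCache <- new.env(parent = emptyenv())

.ghGridCached <- function(n, q, prune = 1e-9) {
  key <- paste(n, q, format(prune), sep = "_")
  g <- .ghGridCache[[key]]
  if (is.null(g)) {
    g <- .ghGrid(n, q, prune)
    .ghGridCache[[key]] <- g
  }
  g
}

#' Round half away from zero
#'
#' Report-formatting rule for percentages: 0.5 rounds to 1, -0.5 to -1
#' (base \code{round} rounds to even).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return Rounded numeric vector.
#' @export
roundHalfAway <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

## All joint pattern names for k traits, in the index order used by the
## C++ kernel: index = twin1 bits + 2^k * twin2 bits, trait j -> bit j-1.
.patternNames <- function(k) {
  K <- 2^k
  bits <- function(i) paste(as.integer(intToBits(i))[seq_len(k)], collapse = "")
  tw <- vapply(0:(K - 1), bits, character(1))
  out <- character(K * K)
  for (i2 in 0:(K - 1))
    for (i1 in 0:(K - 1))
      out[i1 + K * i2 + 1] <- paste0(tw[i1 + 1], "|", tw[i2 + 1])
  out
}

## Parse a pattern name back to the 0/1 vector (twin1 traits, twin2 traits).
.parsePattern <- function(name) {
  parts <- strsplit(name, "|", fixed = TRUE)[[1]]
  as.integer(strsplit(paste0(parts[1], parts[2]), "")[[1]])
}

## Deterministic MVN rectangle probability via mvtnorm; used as the general
## fall-back (marginal rectangles, opposite-sex multivariate structures).
## GenzBretz is randomized QMC, so the RNG is pinned for reproducibility.
.mvnRect <- function(lower, upper, sigma, abseps = 1e-8) {
  d <- length(lower)
  if (d == 1) {
    s <- sqrt(sigma[1, 1])
    return(stats::pnorm(upper / s) - stats::pnorm(lower / s))
  }
  corr <- stats::cov2cor(sigma)
  s <- sqrt(diag(sigma))
  .withSeed(20201601, {
    as.numeric(mvtnorm::pmvnorm(lower = lower / s, upper = upper / s,
                                corr = corr,
                                algorithm = mvtnorm::GenzBretz(
                                  abseps = abseps, maxpts = 500000L)))
  })
}
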