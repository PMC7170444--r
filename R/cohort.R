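#' @include utils.R
NULL

#' Construct a TwinCohort from pair-level data
#'
#' Builds and validates a \linkS4class{TwinCohort}. Opposite-sex pairs given
#' male-first are reordered so that the female twin is twin 1 (the fixed
#' orientation all opposite-sex statistics rely on).
#'
#' @param pairs data.frame with columns \code{pairId}, \code{zygosity}
#'   (codes \code{MZ_F}, \code{MZ_M}, \code{DZ_F}, \code{DZ_M},
#'   \code{DZ_OS}), \code{sex1}, \code{sex2} (\code{"F"}/\code{"M"}),
#'   optional \code{cohortLabel}, and columns \code{<trait>_1},
#'   \code{<trait>_2} coded 0/1/\code{NA}.
#' @param traits ordered character vector of trait names.
#' @return A validated \linkS4class{TwinCohort}.
#' @examples
#' df <- data.frame(pairId = c("p1", "p2"), zygosity = c("MZ_F", "DZ_OS"),
#'                  sex1 = c("F", "F"), sex2 = c("F", "M"),
#'                  CMD_1 = c(1, 0), CMD_2 = c(1, NA))
#' twinCohort(df, traits = "CMD")
#' @export
twinCohort <- function(pairs, traits) {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  if (is.null(pairs$cohortLabel)) pairs$cohortLabel <- NA_character_
  pairs$pairId <- as.character(pairs$pairId)
  pairs$zygosity <- as.character(pairs$zygosity)
  pairs$sex1 <- as.character(pairs$sex1)
  pairs$sex2 <- as.character(pairs$sex2)
  bad <- setdiff(unique(pairs$zygosity), .zygosityLevels)
  if (length(bad))
    stop("unknown zygosity code(s): ", paste(bad, collapse = ", "))
  ## enforce the female-first convention for opposite-sex pairs
  swap <- pairs$zygosity == "DZ_OS" & pairs$sex1 == "M" & pairs$sex2 == "F"
  if (any(swap)) {
    for (tr in traits) {
      c1 <- paste0(tr, "_1"); c2 <- paste0(tr, "_2")
      tmp <- pairs[[c1]][swap]
      pairs[[c1]][swap] <- pairs[[c2]][swap]
      pairs[[c2]][swap] <- tmp
    }
    pairs$sex1[swap] <- "F"
    pairs$sex2[swap] <- "M"
  }
  contra <- (pairs$zygosity %in% c("MZ_F", "DZ_F") &
               (pairs$sex1 != "F" | pairs$sex2 != "F")) |
    (pairs$zygosity %in% c("MZ_M", "DZ_M") &
       (pairs$sex1 != "M" | pairs$sex2 != "M")) |
    (pairs$zygosity == "DZ_OS" & (pairs$sex1 != "F" | pairs$sex2 != "M"))
  if (any(contra))
    stop("sex/zygosity contradiction in pair(s): ",
         paste(utils::head(pairs$pairId[contra], 5), collapse = ", "))
  keep <- c("pairId", "zygosity", "sex1", "sex2", "cohortLabel",
            as.vector(t(outer(traits, c("_1", "_2"), paste0))))
  miss <- setdiff(keep, names(pairs))
  if (length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "))
  methods::new("TwinCohort", pairs = pairs[, keep, drop = FALSE],
               traits = traits)
}

#' Read a twin cohort from a CSV file
#'
#' Expected columns: \code{pair_id}, \code{zygosity}, \code{sex1},
#' \code{sex2}, optional \code{cohort_label}, and one column per twin per
#' trait named \code{<trait>_1} / \code{<trait>_2}. Missing phenotypes are
#' empty fields or \code{NA}. Unknown zygosity codes and sex/zygosity
#' contradictions are hard errors; rows with phenotype values outside
#' \{0, 1, missing\} or duplicated pair IDs are rejected and reported in the
#' \code{rejected} slot (with a warning).
#'
#' @param path CSV file path.
#' @param format only \code{"csv"}.
#' @param traits trait names; if \code{NULL}, inferred from paired
#'   \code{*_1}/\code{*_2} columns.
#' @return A \linkS4class{TwinCohort}; rejected rows (if any) are recorded in
#'   its \code{rejected} slot.
#' @seealso \code{\link{writeCohort}}
#' @export
readCohort <- function(path, format = c("csv"), traits = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", na.strings = c("", "NA"))
  need <- c("pair_id", "zygosity", "sex1", "sex2")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (is.null(traits)) {
    t1 <- sub("_1$", "", grep("_1$", names(raw), value = TRUE))
    t2 <- sub("_2$", "", grep("_2$", names(raw), value = TRUE))
    traits <- setdiff(intersect(t1, t2), c("sex", "pair"))
  }
  if (!length(traits)) stop("no trait columns found")
  bad <- setdiff(unique(raw$zygosity), .zygosityLevels)
  if (length(bad))
    stop("unknown zygosity code(s): ", paste(bad, collapse = ", "))

  rejected <- data.frame(row = integer(), reason = character(),
                         stringsAsFactors = FALSE)
  reject <- function(rows, reason) {
    if (any(rows))
      rejected <<- rbind(rejected,
                         data.frame(row = which(rows), reason = reason,
                                    stringsAsFactors = FALSE))
  }
  phenoOK <- rep(TRUE, nrow(raw))
  for (tr in traits) {
    for (suf in c("_1", "_2")) {
      v <- raw[[paste0(tr, suf)]]
      phenoOK <- phenoOK & (is.na(v) | v %in% c("0", "1"))
    }
  }
  reject(!phenoOK, "phenotype value outside {0, 1, missing}")
  dup <- duplicated(raw$pair_id) | duplicated(raw$pair_id, fromLast = TRUE)
  firstOfDup <- duplicated(raw$pair_id, fromLast = TRUE) & !duplicated(raw$pair_id)
  reject(dup & !firstOfDup, "duplicate pair_id")
  drop <- !phenoOK | (dup & !firstOfDup)
  if (any(drop))
    warning(sum(drop), " row(s) rejected; see the 'rejected' slot")
  raw <- raw[!drop, , drop = FALSE]

  df <- data.frame(pairId = raw$pair_id, zygosity = raw$zygosity,
                   sex1 = raw$sex1, sex2 = raw$sex2,
                   cohortLabel = if ("cohort_label" %in% names(raw))
                     raw$cohort_label else NA_character_,
                   stringsAsFactors = FALSE)
  for (tr in traits)
    for (suf in c("_1", "_2"))
      df[[paste0(tr, suf)]] <- as.numeric(raw[[paste0(tr, suf)]])
  out <- twinCohort(df, traits)
  out@rejected <- rejected
  out
}

#' Write a twin cohort to CSV
#'
#' Inverse of \code{\link{readCohort}}: missing phenotypes become empty
#' fields.
#'
#' @param cohort a \linkS4class{TwinCohort}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeCohort <- function(cohort, path) {
  stopifnot(methods::is(cohort, "TwinCohort"))
  p <- cohort@pairs
  out <- data.frame(pair_id = p$pairId, zygosity = p$zygosity,
                    sex1 = p$sex1, sex2 = p$sex2,
                    cohort_label = p$cohortLabel, stringsAsFactors = FALSE)
  for (tr in cohort@traits)
    for (suf in c("_1", "_2"))
      out[[paste0(tr, suf)]] <- p[[paste0(tr, suf)]]
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Merge twin cohorts
#'
#' @param ... \linkS4class{TwinCohort} objects sharing the same trait set.
#' @return A single \linkS4class{TwinCohort}. Pair IDs must remain unique.
#' @export
mergeCohorts <- function(...) {
  xs <- list(...)
  stopifnot(length(xs) >= 1)
  traits <- traitNames(xs[[1]])
  for (x in xs)
    if (!identical(traitNames(x), traits))
      stop("cohorts have different trait sets")
  twinCohort(do.call(rbind, lapply(xs, pairData)), traits)
}

#' Subset a cohort
#'
#' @param cohort a \linkS4class{TwinCohort}.
#' @param groups optional zygosity group codes to keep.
#' @param cohortLabel optional cohort label to keep.
#' @return The filtered \linkS4class{TwinCohort}.
#' @export
subsetCohort <- function(cohort, groups = NULL, cohortLabel = NULL) {
  p <- cohort@pairs
  keep <- rep(TRUE, nrow(p))
  if (!is.null(groups)) keep <- keep & p$zygosity %in% groups
  if (!is.null(cohortLabel)) keep <- keep & p$cohortLabel %in% cohortLabel
  methods::new("TwinCohort", pairs = p[keep, , drop = FALSE],
               traits = cohort@traits, rejected = cohort@rejected[0, ])
}

#' Joint response-pattern counts for one zygosity group
#'
#' Tabulates every joint binary outcome pattern (one value per twin per
#' selected trait) among the group's pairs. Pairs with any missing value on
#' the selected traits are counted as incomplete and excluded from the
#' pattern counts. An empty group gives an all-zero table.
#'
#' @param cohort a \linkS4class{TwinCohort}.
#' @param traits non-empty subset of \code{traitNames(cohort)}, in the order
#'   patterns should be labelled.
#' @param group zygosity group code.
#' @return A \linkS4class{ContingencyTable}.
#' @examples
#' df <- data.frame(pairId = 1:2, zygosity = "MZ_F", sex1 = "F", sex2 = "F",
#'                  CMD_1 = c(1, 0), CMD_2 = c(1, 1))
#' contingencyTable(twinCohort(df, "CMD"), "CMD", "MZ_F")
#' @export
contingencyTable <- function(cohort, traits, group) {
  stopifnot(methods::is(cohort, "TwinCohort"))
  if (!length(traits) || !all(traits %in% cohort@traits))
    stop("traits must be a non-empty subset of the cohort's traits")
  group <- match.arg(group, .zygosityLevels)
  p <- cohort@pairs[cohort@pairs$zygosity == group, , drop = FALSE]
  k <- length(traits)
  nm <- .patternNames(k)
  counts <- stats::setNames(numeric(4^k), nm)
  nInc <- 0
  if (nrow(p)) {
    m1 <- as.matrix(p[, paste0(traits, "_1"), drop = FALSE])
    m2 <- as.matrix(p[, paste0(traits, "_2"), drop = FALSE])
    complete <- stats::complete.cases(cbind(m1, m2))
    nInc <- sum(!complete)
    if (any(complete)) {
      m1 <- m1[complete, , drop = FALSE]
      m2 <- m2[complete, , drop = FALSE]
      i1 <- as.integer(m1 %*% 2^(0:(k - 1)))
      i2 <- as.integer(m2 %*% 2^(0:(k - 1)))
      idx <- i1 + 2^k * i2
      tab <- tabulate(idx + 1L, nbins = 4^k)
      counts[] <- tab
    }
  }
  methods::new("ContingencyTable", group = group, traits = traits,
               counts = counts, nComplete = sum(counts), nIncomplete = nInc)
}

#' Export a contingency table as JSON
#'
#' Patterns are keyed \code{"101|110"} (twin 1 | twin 2, trait order as in
#' the table).
#'
#' @param table a \linkS4class{ContingencyTable}.
#' @param path optional file path; if \code{NULL} the JSON string is
#'   returned.
#' @return JSON string (invisibly when written to a file).
#' @export
contingencyJSON <- function(table, path = NULL) {
  stopifnot(methods::is(table, "ContingencyTable"))
  obj <- list(group = table@group, traits = table@traits,
              counts = as.list(table@counts),
              n_complete = table@nComplete,
              n_incomplete = table@nIncomplete)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Individual-level prevalence of a trait
#'
#' Proportion of affected individuals among non-missing observations of the
#' given sex, pooling both twins of each pair.
#'
#' @param cohort a \linkS4class{TwinCohort}.
#' @param trait trait name.
#' @param sex \code{"F"} or \code{"M"}.
#' @return Proportion in [0, 1]; \code{NA} (with a warning) when no
#'   non-missing observation exists.
#' @export
prevalence <- function(cohort, trait, sex = c("F", "M")) {
  stopifnot(methods::is(cohort, "TwinCohort"))
  sex <- match.arg(sex)
  if (!trait %in% cohort@traits) stop("unknown trait: ", trait)
  p <- cohort@pairs
  v <- c(p[[paste0(trait, "_1")]][p$sex1 == sex],
         p[[paste0(trait, "_2")]][p$sex2 == sex])
  v <- v[!is.na(v)]
  if (!length(v)) {
    warning("no non-missing observations for ", trait, " (", sex, ")")
    return(NA_real_)
  }
  mean(v)
}

#' Pairs per zygosity group
#'
#' @param cohort a \linkS4class{TwinCohort}.
#' @return Named integer vector over the five zygosity groups.
#' @export
zygosityCounts <- function(cohort) {
  stopifnot(methods::is(cohort, "TwinCohort"))
  tab <- table(factor(cohort@pairs$zygosity, levels = .zygosityLevels))
  stats::setNames(as.integer(tab), names(tab))
}
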