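#' Family-aware stratified cross-validation folds
#'
#' Assigns whole families to folds (members of one family never straddle a
#' fold boundary) while balancing the distribution of family-average
#' target scores across folds: families are sorted by their average
#' target, grouped into consecutive strata of \code{nFolds} families, and
#' dealt to folds by a seeded random permutation within each stratum.
#'
#' @param familyId Character/factor family id per subject.
#' @param target Numeric target score per subject.
#' @param nFolds Number of folds (>= 2).
#' @param seed Integer seed.
#' @return List of class \code{foldAssignment}: \code{fold} (integer per
#'   subject), \code{nFolds}, \code{seed}.
#' @export
makeFolds <- function(familyId, target, nFolds = 5, seed = 1) {
  if (nFolds < 2) stop("'nFolds' must be at least 2")
  n <- length(familyId)
  stopifnot(length(target) == n, !anyNA(familyId), !anyNA(target))
  famAvg <- tapply(target, familyId, mean)
  famSize <- tapply(rep(1, n), familyId, sum)
  if (any(famSize > ceiling(n / nFolds)))
    warning("a family is larger than n/nFolds; fold sizes will be uneven")
  fold <- .withSeed(seed, {
    ord <- order(famAvg, stats::runif(length(famAvg)))  # seeded tie-shuffle
    famFold <- integer(length(famAvg))
    pos <- 1L
    while (pos <= length(ord)) {
      block <- ord[pos:min(pos + nFolds - 1L, length(ord))]
      famFold[block] <- sample(nFolds)[seq_along(block)]
      pos <- pos + nFolds
    }
    famFold[match(familyId, names(famAvg))]
  })
  structure(list(fold = fold, nFolds = as.integer(nFolds),
                 seed = as.integer(seed)), class = "foldAssignment")
}

#' Family-aware validation split within a training set
#'
#' Samples whole families into a validation subset of roughly the given
#' fraction, used for early stopping. Seeded and deterministic.
#'
#' @param familyId Family ids of the training subjects.
#' @param fraction Validation fraction (0.2 in outer folds, 0.3 in the
#'   inner hyperparameter loop).
#' @param seed Integer seed.
#' @return Logical vector, TRUE for validation subjects.
#' @export
validationSplit <- function(familyId, fraction = 0.2, seed = 1) {
  stopifnot(fraction > 0, fraction < 1)
  .withSeed(seed, {
    fams <- unique(familyId)
    fams <- fams[sample.int(length(fams))]
    sizes <- tapply(rep(1, length(familyId)), familyId, sum)[fams]
    cum <- cumsum(sizes)
    nVal <- max(min(which(cum >= fraction * length(familyId))), 1L)
    familyId %in% fams[seq_len(nVal)]
  })
}

#' Family-aware lockbox split
#'
#' Splits a cohort into a main and a lockbox sample without splitting any
#' family: families are shuffled (seeded) and moved to the lockbox until
#' it reaches the requested fraction of subjects.
#'
#' @param cohortTable Cohort data.frame with a \code{family_id} column.
#' @param fraction Lockbox fraction (0 < fraction < 1); e.g. 196 / 806.
#' @param seed Integer seed.
#' @return List with data.frames \code{main} and \code{lockbox} (subject
#'   order preserved within each).
#' @export
splitLockbox <- function(cohortTable, fraction = 196 / 806, seed = 1) {
  if (fraction <= 0 || fraction >= 1) stop("'fraction' must be in (0, 1)")
  inLockbox <- validationSplit(cohortTable$family_id, fraction, seed)
  list(main = cohortTable[!inLockbox, , drop = FALSE],
       lockbox = cohortTable[inLockbox, , drop = FALSE])
}
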