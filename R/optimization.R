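# Parameter-selection protocols: (k, p) grid search under the three
# reference scenarios, 10-fold cross-validation, and the sweep over the
# number of top components.

#' Randomly partition samples into cross-validation folds
#'
#' Shuffles the sample IDs with the given seed and assigns fold indices by
#' position modulo \code{nFolds}, so fold sizes differ by at most one. The
#' caller's RNG state is left untouched; the assignment is reproducible from
#' the seed.
#'
#' @param sampleIDs character vector of unique sample IDs.
#' @param nFolds number of folds (default 10), \code{2 <= nFolds <= n}.
#' @param seed integer RNG seed.
#' @return A [FoldAssignment-class].
#' @examples
#' f <- makeFolds(paste0("s", 1:10), nFolds = 3, seed = 1)
#' table(foldOf(f))  # sizes 4, 3, 3 in some order
#' @export
makeFolds <- function(sampleIDs, nFolds = 10, seed = 1) {
  sampleIDs <- as.character(sampleIDs)
  n <- length(sampleIDs)
  if (anyDuplicated(sampleIDs)) stop("sample IDs must be unique")
  if (length(nFolds) != 1L || nFolds < 2L || nFolds > n)
    stop(sprintf("nFolds must lie in 2..%d; got %s", n,
                 paste(nFolds, collapse = ",")))
  perm <- with_local_seed(seed, sample.int(n))
  fold <- integer(n)
  fold[perm] <- (seq_len(n) - 1L) %% as.integer(nFolds)
  names(fold) <- sampleIDs
  new("FoldAssignment", foldOf = fold, nFolds = as.integer(nFolds),
      seed = as.integer(seed))
}

#' Cross-validated out-of-fold profile estimation
#'
#' Each fold in turn is the query set and the union of the remaining folds
#' the reference set; the concatenated out-of-fold estimates for every
#' sample are evaluated against the supplied profiles. A sample can never
#' appear among its own references — self-exclusion is structural through
#' the fold partition. Deterministic given the fold assignment.
#'
#' @param components [ComponentMatrix-class] covering all partitioned
#'   samples.
#' @param profiles [ProfileMatrix-class] of known profiles for the same
#'   samples (both reference input and evaluation truth).
#' @param folds a [FoldAssignment-class] partitioning the profile sample
#'   IDs.
#' @param params a [KnnParams-class]; \code{k} must not exceed the smallest
#'   training-fold-union size.
#' @return An [EvaluationSummary-class] over the full sample set.
#' @export
crossValidate <- function(components, profiles, folds,
                          params = knnParams()) {
  stopifnot(is(components, "ComponentMatrix"), is(profiles, "ProfileMatrix"),
            is(folds, "FoldAssignment"), is(params, "KnnParams"))
  ids <- sampleIDs(profiles)
  fids <- names(folds@foldOf)
  if (!setequal(ids, fids))
    stop("fold assignment must partition exactly the profile sample IDs")
  missingScores <- setdiff(ids, sampleIDs(components))
  if (length(missingScores))
    stop("components lack samples: ",
         paste(utils::head(missingScores, 5), collapse = ", "))
  estList <- vector("list", folds@nFolds)
  for (f in seq_len(folds@nFolds) - 1L) {
    qIDs <- fids[folds@foldOf == f]
    rIDs <- fids[folds@foldOf != f]
    if (params@k > length(rIDs))
      stop(sprintf("k = %d infeasible for fold %d: only %d reference samples",
                   params@k, f, length(rIDs)))
    est <- estimateProfiles(components[qIDs, ], components[rIDs, ],
                            profiles[rIDs, ], params, selfExclude = TRUE)
    estList[[f + 1L]] <- est@proportions
  }
  all <- do.call(rbind, estList)
  evaluateProfiles(ProfileMatrix(all), profiles[rownames(all), ])
}

#' Grid search over (k, p) for one reference scenario
#'
#' Runs the estimator at every (k, p) cell and records the mean TVD and mean
#' per-population correlation against the truth. For DISCRETE and CONTINUOUS
#' scenarios the scenario's reference/query split is used directly; for
#' CONTINUOUSALL the mean TVD of each cell is the cross-validated
#' out-of-fold value over the whole panel (see [crossValidate()]). The best
#' cell minimizes mean TVD, ties broken by smaller k, then smaller p.
#' Cells whose k is infeasible for the reference count are recorded as
#' skipped with a reason, not silently dropped; duplicated (k, p) pairs are
#' deduplicated with a warning.
#'
#' @param scenario a [Scenario-class].
#' @param components [ComponentMatrix-class] covering reference and query
#'   samples.
#' @param truth [ProfileMatrix-class] the estimates are scored against
#'   (must cover the query IDs; for CONTINUOUSALL, all panel IDs).
#' @param kGrid integer vector of neighbor counts.
#' @param pGrid numeric vector of inverse-distance exponents.
#' @param paramsBase [KnnParams-class] supplying \code{epsilon} and
#'   \code{nComponents}.
#' @param folds optional [FoldAssignment-class] for CONTINUOUSALL; built
#'   from \code{nFolds}/\code{seed} when omitted.
#' @param nFolds,seed fold construction for CONTINUOUSALL when \code{folds}
#'   is missing.
#' @return A [GridResult-class].
#' @export
gridSearch <- function(scenario, components, truth, kGrid, pGrid,
                       paramsBase = knnParams(), folds = NULL,
                       nFolds = 10, seed = 1) {
  stopifnot(is(scenario, "Scenario"), is(components, "ComponentMatrix"),
            is(truth, "ProfileMatrix"), is(paramsBase, "KnnParams"))
  if (!length(kGrid) || !length(pGrid))
    stop("kGrid and pGrid must be nonempty")
  cells <- expand.grid(k = as.integer(kGrid), p = as.numeric(pGrid),
                       KEEP.OUT.ATTRS = FALSE)
  if (anyDuplicated(cells)) {
    warning("duplicate (k, p) grid cells removed")
    cells <- unique(cells)
  }
  cells <- cells[order(cells$k, cells$p), , drop = FALSE]

  caAll <- scenario@name == "CONTINUOUSALL"
  if (caAll) {
    ids <- scenario@referenceIDs
    if (is.null(folds)) folds <- makeFolds(ids, nFolds = nFolds, seed = seed)
    trainMin <- length(ids) - max(tabulate(folds@foldOf + 1L,
                                           nbins = folds@nFolds))
    panelProfiles <- scenario@profileSource[ids, ]
    kMax <- trainMin
  } else {
    rIDs <- scenario@referenceIDs
    qIDs <- scenario@queryIDs
    missingQ <- setdiff(qIDs, sampleIDs(truth))
    if (length(missingQ))
      stop("truth lacks query samples: ",
           paste(utils::head(missingQ, 5), collapse = ", "))
    ref <- components[rIDs, ]
    qry <- components[qIDs, ]
    refProf <- scenario@profileSource[rIDs, ]
    qTruth <- truth[qIDs, ]
    kMax <- length(rIDs)
  }

  n <- nrow(cells)
  mt <- rep(NA_real_, n)
  mc <- rep(NA_real_, n)
  skipped <- logical(n)
  reason <- character(n)
  for (i in seq_len(n)) {
    k <- cells$k[i]
    p <- cells$p[i]
    if (k > kMax) {
      skipped[i] <- TRUE
      reason[i] <- sprintf("k = %d exceeds feasible maximum %d", k, kMax)
      next
    }
    pars <- knnParams(k = k, p = p, epsilon = paramsBase@epsilon,
                       nComponents = paramsBase@nComponents)
    ev <- if (caAll)
      crossValidate(components, panelProfiles, folds, pars)
    else
      evaluateProfiles(estimateProfiles(qry, ref, refProf, pars), qTruth)
    mt[i] <- ev@meanTVD
    mc[i] <- ev@meanCorrelation
  }
  if (all(skipped)) stop("every grid cell was infeasible")
  grid <- data.frame(k = cells$k, p = cells$p, mean_tvd = mt,
                     mean_correlation = mc, skipped = skipped,
                     reason = reason, stringsAsFactors = FALSE)
  ok <- which(!skipped)
  best <- ok[order(mt[ok], grid$k[ok], grid$p[ok])][1]
  new("GridResult", grid = grid, bestK = as.integer(grid$k[best]),
      bestP = grid$p[best],
      nComponents = min(paramsBase@nComponents,
                        as.integer(nComponents(components))))
}

#' Sweep the number of top components used by the estimator
#'
#' Repeats [gridSearch()] while varying the number of top components M and
#' reports the per-M optimum, exposing how estimation accuracy saturates as
#' components beyond the population structure are added.
#'
#' @param scenario,components,truth,kGrid,pGrid,paramsBase,folds,nFolds,seed
#'   as in [gridSearch()]; for CONTINUOUSALL the same fold assignment is
#'   reused across all M.
#' @param mValues integer vector of component counts to try (each >= 1 and
#'   <= the available components).
#' @return data.frame with columns \code{M}, \code{best_k}, \code{best_p},
#'   \code{best_mean_tvd}.
#' @export
componentSweep <- function(scenario, components, truth, mValues, kGrid,
                           pGrid, paramsBase = knnParams(), folds = NULL,
                           nFolds = 10, seed = 1) {
  avail <- nComponents(components)
  if (!length(mValues) || any(mValues < 1) || any(mValues > avail))
    stop(sprintf("mValues must lie in 1..%d", avail))
  if (scenario@name == "CONTINUOUSALL" && is.null(folds))
    folds <- makeFolds(scenario@referenceIDs, nFolds = nFolds, seed = seed)
  rows <- lapply(as.integer(mValues), function(M) {
    pars <- knnParams(k = paramsBase@k, p = paramsBase@p,
                       epsilon = paramsBase@epsilon, nComponents = M)
    gr <- gridSearch(scenario, components, truth, kGrid, pGrid, pars,
                     folds = folds, nFolds = nFolds, seed = seed)
    ok <- !gr@grid$skipped
    data.frame(M = M, best_k = gr@bestK, best_p = gr@bestP,
               best_mean_tvd = min(gr@grid$mean_tvd[ok]))
  })
  do.call(rbind, rows)
}
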