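#' Sample identifiers
#' @param object a [ComponentMatrix-class] or [ProfileMatrix-class].
#' @return character vector of sample IDs, in row order.
#' @export
setGeneric("sampleIDs", function(object) standardGeneric("sampleIDs"))

#' @export
setMethod("sampleIDs", "ComponentMatrix", function(object)
  rownames(object@scores))

#' @export
setMethod("sampleIDs", "ProfileMatrix", function(object)
  rownames(object@proportions))

#' Score matrix of a ComponentMatrix
#' @param object a [ComponentMatrix-class].
#' @return the numeric n x M score matrix.
#' @export
setGeneric("componentScores", function(object)
  standardGeneric("componentScores"))

#' @export
setMethod("componentScores", "ComponentMatrix", function(object) object@scores)

#' Eigenvalues of a ComponentMatrix
#' @param object a [ComponentMatrix-class].
#' @return numeric vector of per-component eigenvalues (raw, not normalized).
#' @export
setGeneric("eigenValues", function(object) standardGeneric("eigenValues"))

#' @export
setMethod("eigenValues", "ComponentMatrix", function(object)
  object@eigenvalues)

#' Number of components carried by a ComponentMatrix
#' @param object a [ComponentMatrix-class].
#' @export
setGeneric("nComponents", function(object) standardGeneric("nComponents"))

#' @export
setMethod("nComponents", "ComponentMatrix", function(object)
  ncol(object@scores))

#' Has a ComponentMatrix been standardized?
#' @param object a [ComponentMatrix-class].
#' @export
setGeneric("isStandardized", function(object)
  standardGeneric("isStandardized"))

#' @export
setMethod("isStandardized", "ComponentMatrix", function(object)
  object@standardized)

#' Proportion matrix of a ProfileMatrix
#' @param object a [ProfileMatrix-class].
#' @return the numeric n x S matrix of ancestry proportions.
#' @export
setGeneric("ancestryProportions", function(object)
  standardGeneric("ancestryProportions"))

#' @export
setMethod("ancestryProportions", "ProfileMatrix", function(object)
  object@proportions)

#' Source-population labels of a ProfileMatrix
#' @param object a [ProfileMatrix-class].
#' @export
setGeneric("populationLabels", function(object)
  standardGeneric("populationLabels"))

#' @export
setMethod("populationLabels", "ProfileMatrix", function(object)
  colnames(object@proportions))

#' @export
setMethod("[", "ComponentMatrix", function(x, i, j, ..., drop = FALSE) {
  sc <- x@scores
  if (missing(i)) i <- seq_len(nrow(sc))
  if (missing(j)) j <- seq_len(ncol(sc))
  jj <- seq_len(ncol(sc))
  names(jj) <- colnames(sc)
  jidx <- if (is.character(j)) jj[j] else jj[j]
  ComponentMatrix(sc[i, j, drop = FALSE], x@eigenvalues[jidx],
                  standardized = x@standardized)
})

#' @export
setMethod("[", "ProfileMatrix", function(x, i, j, ..., drop = FALSE) {
  pr <- x@proportions
  if (missing(i)) i <- seq_len(nrow(pr))
  ProfileMatrix(pr[i, , drop = FALSE])
})

setMethod("show", "ComponentMatrix", function(object) {
  cat(sprintf("ComponentMatrix: %d samples x %d components%s\n",
              nrow(object@scores), ncol(object@scores),
              if (object@standardized) " (standardized)" else ""))
  ev <- object@eigenvalues
  cat("eigenvalues:", paste(signif(utils::head(ev, 6), 4), collapse = " "),
      if (length(ev) > 6) "..." else "", "\n")
})

setMethod("show", "ProfileMatrix", function(object) {
  pr <- object@proportions
  cat(sprintf("ProfileMatrix: %d samples x %d populations\n",
              nrow(pr), ncol(pr)))
  cat("populations:", paste(utils::head(colnames(pr), 8), collapse = " "),
      if (ncol(pr) > 8) "..." else "", "\n")
})

setMethod("show", "KnnParams", function(object) {
  cat(sprintf("KnnParams: k = %d, p = %g, epsilon = %g, nComponents = %d\n",
              object@k, object@p, object@epsilon, object@nComponents))
})

setMethod("show", "EvaluationSummary", function(object) {
  cat(sprintf("EvaluationSummary over %d samples\n",
              length(object@perSampleTVD)))
  cat(sprintf("  mean TVD: %.4f (95%% CI %.4f, %.4f)\n", object@meanTVD,
              object@meanTVDCI95[1], object@meanTVDCI95[2]))
  cat(sprintf("  mean per-population correlation: %.4f\n",
              object@meanCorrelation))
})

setMethod("show", "GridResult", function(object) {
  done <- sum(!object@grid$skipped)
  cat(sprintf("GridResult: %d cells computed (%d skipped), M = %d\n",
              done, nrow(object@grid) - done, object@nComponents))
  cat(sprintf("  best: k = %d, p = %g (mean TVD %.4f)\n", object@bestK,
              object@bestP,
              object@grid$mean_tvd[!object@grid$skipped &
                object@grid$k == object@bestK &
                object@grid$p == object@bestP][1]))
})

setMethod("show", "FoldAssignment", function(object) {
  cat(sprintf("FoldAssignment: %d samples in %d folds (seed %d)\n",
              length(object@foldOf), object@nFolds, object@seed))
})

setMethod("show", "MixupReport", function(object) {
  cat(sprintf("MixupReport (threshold %.3g): %d target/sign groups, %d nonempty\n",
              object@threshold, nrow(object@groups),
              sum(object@groups$group_size > 0)))
})

setMethod("show", "Scenario", function(object) {
  cat(sprintf("Scenario %s: %d reference, %d query samples\n", object@name,
              length(object@referenceIDs), length(object@queryIDs)))
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(
    "SimConfig: S = %d, M = %d (structure in %d), nRef = %d, nQuery = %d\n",
    object@S, object@M, object@structureDims, object@nReference,
    object@nQuery))
  cat(sprintf(
    "  separation = %g, noiseSD = %g, decay = %g, fracPure = %g, seed = %d\n",
    object@centroidSeparation, object@noiseSD, object@eigenvalueDecay,
    object@fracPure, object@seed))
})

#' Accessors for EvaluationSummary
#' @param object an [EvaluationSummary-class].
#' @return \code{meanTVD}: the mean per-sample total variation distance;
#'   \code{perSampleTVD}: named vector of per-sample TVDs; \code{meanTVDCI95}:
#'   the (low, high) normal-approximation 95\% CI; \code{meanCorrelation}:
#'   mean per-population Pearson correlation over defined components;
#'   \code{perComponentCorrelation}: the per-population correlations.
#' @name EvaluationSummary-accessors
NULL

#' @rdname EvaluationSummary-accessors
#' @export
setGeneric("meanTVD", function(object) standardGeneric("meanTVD"))
#' @export
setMethod("meanTVD", "EvaluationSummary", function(object) object@meanTVD)

#' @rdname EvaluationSummary-accessors
#' @export
setGeneric("perSampleTVD", function(object) standardGeneric("perSampleTVD"))
#' @export
setMethod("perSampleTVD", "EvaluationSummary", function(object)
  object@perSampleTVD)

#' @rdname EvaluationSummary-accessors
#' @export
setGeneric("meanTVDCI95", function(object) standardGeneric("meanTVDCI95"))
#' @export
setMethod("meanTVDCI95", "EvaluationSummary", function(object)
  object@meanTVDCI95)

#' @rdname EvaluationSummary-accessors
#' @export
setGeneric("meanCorrelation", function(object)
  standardGeneric("meanCorrelation"))
#' @export
setMethod("meanCorrelation", "EvaluationSummary", function(object)
  object@meanCorrelation)

#' @rdname EvaluationSummary-accessors
#' @export
setGeneric("perComponentCorrelation", function(object)
  standardGeneric("perComponentCorrelation"))
#' @export
setMethod("perComponentCorrelation", "EvaluationSummary", function(object)
  object@perComponentCorrelation)

#' Accessors for GridResult
#' @param object a [GridResult-class].
#' @return \code{bestParams}: named numeric \code{c(k =, p =)};
#'   \code{gridTable}: the per-cell data.frame.
#' @name GridResult-accessors
NULL

#' @rdname GridResult-accessors
#' @export
setGeneric("bestParams", function(object) standardGeneric("bestParams"))
#' @export
setMethod("bestParams", "GridResult", function(object)
  c(k = as.numeric(object@bestK), p = object@bestP))

#' @rdname GridResult-accessors
#' @export
setGeneric("gridTable", function(object) standardGeneric("gridTable"))
#' @export
setMethod("gridTable", "GridResult", function(object) object@grid)

#' Fold map of a FoldAssignment
#' @param object a [FoldAssignment-class].
#' @return named integer vector: sample ID -> fold index (0-based).
#' @export
setGeneric("foldOf", function(object) standardGeneric("foldOf"))
#' @export
setMethod("foldOf", "FoldAssignment", function(object) object@foldOf)

#' Accessors for MixupReport
#' @param object a [MixupReport-class].
#' @return \code{mixupGroups}: data.frame of group sizes per target
#'   population and sign; \code{mixupAttribution}: long data.frame of
#'   normalized opposite-direction attributions.
#' @name MixupReport-accessors
NULL

#' @rdname MixupReport-accessors
#' @export
setGeneric("mixupGroups", function(object) standardGeneric("mixupGroups"))
#' @export
setMethod("mixupGroups", "MixupReport", function(object) object@groups)

#' @rdname MixupReport-accessors
#' @export
setGeneric("mixupAttribution", function(object)
  standardGeneric("mixupAttribution"))
#' @export
setMethod("mixupAttribution", "MixupReport", function(object)
  object@attribution)
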