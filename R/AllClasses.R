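#' @import methods
NULL

#' ComponentMatrix: sample scores on principal or haplotype components
#'
#' Holds an n x M matrix of component scores (rows are samples, columns are
#' components such as PCs or HCs), the M eigenvalues of the decomposition in
#' column order, and a flag recording whether the columns have been
#' standardized to zero mean and unit variance. This is the geometric space
#' in which nearest-neighbor ancestry estimation operates: the squared
#' distance along component m is weighted by its (normalized) eigenvalue.
#'
#' @slot scores numeric matrix, rownames are unique sample identifiers,
#'   colnames name the components.
#' @slot eigenvalues nonnegative numeric vector, one per score column, in
#'   the same order as the columns (variance units of the decomposition).
#' @slot standardized logical flag; \code{TRUE} once columns have zero mean
#'   and unit variance (see [standardizeComponents()]).
#' @seealso [ComponentMatrix()], [readComponentMatrix()], [pairwiseDistances()]
#' @export
setClass("ComponentMatrix",
  slots = c(scores = "matrix", eigenvalues = "numeric",
            standardized = "logical"))

setValidity("ComponentMatrix", function(object) {
  msg <- character(0)
  sc <- object@scores
  if (!is.numeric(sc))
    msg <- c(msg, "scores must be a numeric matrix")
  if (is.null(rownames(sc)))
    msg <- c(msg, "scores must have rownames (sample identifiers)")
  else if (anyDuplicated(rownames(sc)))
    msg <- c(msg, sprintf("duplicate sample identifiers: %s",
      paste(unique(rownames(sc)[duplicated(rownames(sc))]), collapse = ", ")))
  if (length(object@eigenvalues) != ncol(sc))
    msg <- c(msg, sprintf(
      "number of eigenvalues (%d) must equal number of score columns (%d)",
      length(object@eigenvalues), ncol(sc)))
  if (any(!is.finite(object@eigenvalues)) || any(object@eigenvalues < 0))
    msg <- c(msg, "eigenvalues must be finite and nonnegative")
  if (length(object@standardized) != 1L)
    msg <- c(msg, "standardized must be a single logical")
  if (length(msg)) msg else TRUE
})

#' Construct a ComponentMatrix
#'
#' @param scores numeric matrix of component scores; rownames are the sample
#'   identifiers (required, unique). Columns are named \code{C1..CM} when
#'   unnamed.
#' @param eigenvalues nonnegative numeric vector, one entry per score column.
#' @param standardized logical; whether columns already have zero mean and
#'   unit variance. Default \code{FALSE}.
#' @return A [ComponentMatrix-class] object.
#' @examples
#' sc <- matrix(rnorm(12), 4, 3, dimnames = list(paste0("s", 1:4), NULL))
#' cm <- ComponentMatrix(sc, eigenvalues = c(4, 2, 1))
#' nComponents(cm)
#' @export
ComponentMatrix <- function(scores, eigenvalues, standardized = FALSE) {
  scores <- as.matrix(scores)
  storage.mode(scores) <- "double"
  if (is.null(colnames(scores)) && ncol(scores) > 0)
    colnames(scores) <- paste0("C", seq_len(ncol(scores)))
  new("ComponentMatrix", scores = scores,
      eigenvalues = as.numeric(eigenvalues),
      standardized = isTRUE(standardized))
}

#' ProfileMatrix: ancestry profiles on the probability simplex
#'
#' An n x S matrix of ancestry proportions: row i gives the fraction of
#' sample i's genome attributed to each of S predefined source populations.
#' Every row lies on the probability simplex (entries in \[0, 1\], summing to
#' one). A discrete profile is the special case where each row is one-hot.
#' ProfileMatrix is both the reference input to the estimator (known
#' profiles, e.g. reshaped SOURCEFIND or ADMIXTURE output) and its output.
#'
#' @slot proportions numeric matrix in \[0, 1\]; rownames are unique sample
#'   identifiers, colnames are the S unique source-population labels; each
#'   row sums to 1 within 1e-3.
#' @seealso [ProfileMatrix()], [readProfileMatrix()], [estimateProfiles()]
#' @export
setClass("ProfileMatrix", slots = c(proportions = "matrix"))

setValidity("ProfileMatrix", function(object) {
  msg <- character(0)
  pr <- object@proportions
  if (!is.numeric(pr))
    msg <- c(msg, "proportions must be a numeric matrix")
  if (nrow(pr) > 0 && is.null(rownames(pr)))
    msg <- c(msg, "proportions must have rownames (sample identifiers)")
  else if (anyDuplicated(rownames(pr)))
    msg <- c(msg, "duplicate sample identifiers")
  if (is.null(colnames(pr)) || anyDuplicated(colnames(pr)))
    msg <- c(msg, "proportions must have unique population labels as colnames")
  if (nrow(pr) > 0 && ncol(pr) > 0) {
    tol <- 1e-9
    if (any(pr < -tol) || any(pr > 1 + tol))
      msg <- c(msg, "all proportions must lie in [0, 1]")
    rs <- rowSums(pr)
    bad <- abs(rs - 1) > 1e-3
    if (any(bad))
      msg <- c(msg, sprintf("rows must sum to 1 within 1e-3; offending: %s",
                            paste(utils::head(rownames(pr)[bad], 5),
                                  collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a ProfileMatrix
#'
#' @param proportions numeric matrix of ancestry proportions; rownames are
#'   sample identifiers, colnames the source-population labels. Rows must lie
#'   on the probability simplex (sum to 1 within 1e-3).
#' @return A [ProfileMatrix-class] object.
#' @examples
#' pr <- matrix(c(0.7, 0.3, 0.2, 0.8), 2, byrow = TRUE,
#'              dimnames = list(c("s1", "s2"), c("POP1", "POP2")))
#' ProfileMatrix(pr)
#' @export
ProfileMatrix <- function(proportions) {
  proportions <- as.matrix(proportions)
  storage.mode(proportions) <- "double"
  new("ProfileMatrix", proportions = proportions)
}

#' KnnParams: tuning parameters of the nearest-neighbor estimator
#'
#' @slot k positive integer; number of nearest reference neighbors averaged.
#' @slot p nonnegative real; inverse-distance-weighting exponent. \code{p = 0}
#'   gives the unweighted arithmetic mean.
#' @slot epsilon positive real; minimum-distance floor substituted for
#'   distances below it before raising to the power \code{-p} (guards against
#'   exploding weights at tiny distances). Ignored when \code{p = 0}.
#' @slot nComponents positive integer; number of top components M used in the
#'   distance.
#' @seealso [knnParams()], [estimateProfiles()]
#' @export
setClass("KnnParams",
  slots = c(k = "integer", p = "numeric", epsilon = "numeric",
            nComponents = "integer"))

setValidity("KnnParams", function(object) {
  msg <- character(0)
  if (length(object@k) != 1L || is.na(object@k) || object@k < 1L)
    msg <- c(msg, "k must be a single integer >= 1")
  if (length(object@p) != 1L || !is.finite(object@p) || object@p < 0)
    msg <- c(msg, "p must be a single finite number >= 0")
  if (length(object@epsilon) != 1L || !is.finite(object@epsilon))
    msg <- c(msg, "epsilon must be a single finite number")
  else if (object@p > 0 && object@epsilon <= 0)
    msg <- c(msg, "epsilon must be > 0 when p > 0")
  if (length(object@nComponents) != 1L || is.na(object@nComponents) ||
      object@nComponents < 1L)
    msg <- c(msg, "nComponents must be a single integer >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct estimator parameters
#'
#' Defaults are the recommended operating point for large reference panels:
#' \code{k = 25} neighbors, inverse-distance exponent \code{p = 3}, distance
#' floor \code{epsilon = 0.1}, and the top \code{nComponents = 10} components.
#'
#' @param k number of nearest neighbors (integer >= 1).
#' @param p inverse-distance-weighting exponent (>= 0); 0 disables weighting.
#' @param epsilon minimum distance floor (> 0 when \code{p > 0}).
#' @param nComponents number of top components used in the distance.
#' @return A [KnnParams-class] object.
#' @examples
#' knnParams(k = 50, p = 4)
#' @export
knnParams <- function(k = 25, p = 3, epsilon = 0.1, nComponents = 10) {
  new("KnnParams", k = as.integer(k), p = as.numeric(p),
      epsilon = as.numeric(epsilon), nComponents = as.integer(nComponents))
}

#' NeighborSet: the k nearest reference samples of one query
#'
#' @slot queryIndex integer index of the query row (NA when the distances row
#'   was supplied without context).
#' @slot neighborIndices integer vector of k distinct reference row indices,
#'   ordered by nondecreasing distance, ties broken by ascending index.
#' @slot neighborDistances the matching nonnegative distances, nondecreasing.
#' @export
setClass("NeighborSet",
  slots = c(queryIndex = "integer", neighborIndices = "integer",
            neighborDistances = "numeric"))

setValidity("NeighborSet", function(object) {
  msg <- character(0)
  if (length(object@neighborIndices) != length(object@neighborDistances))
    msg <- c(msg, "indices and distances must have equal length")
  if (anyDuplicated(object@neighborIndices))
    msg <- c(msg, "neighbor indices must be distinct")
  if (is.unsorted(object@neighborDistances))
    msg <- c(msg, "neighbor distances must be nondecreasing")
  if (any(object@neighborDistances < 0))
    msg <- c(msg, "distances must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' EvaluationSummary: agreement metrics between two profile sets
#'
#' @slot perSampleTVD named numeric vector of per-sample total variation
#'   distances in \[0, 1\].
#' @slot meanTVD arithmetic mean of \code{perSampleTVD}.
#' @slot meanTVDCI95 length-2 numeric (low, high): normal-approximation 95\%
#'   confidence interval for the mean TVD.
#' @slot perComponentCorrelation named numeric vector of per-population
#'   Pearson correlations across samples; \code{NA} where undefined
#'   (zero variance).
#' @slot meanCorrelation unweighted mean over the defined correlations.
#' @seealso [evaluateProfiles()]
#' @export
setClass("EvaluationSummary",
  slots = c(perSampleTVD = "numeric", meanTVD = "numeric",
            meanTVDCI95 = "numeric", perComponentCorrelation = "numeric",
            meanCorrelation = "numeric"))

#' GridResult: (k, p) grid-search outcome
#'
#' @slot grid data.frame with one row per requested (k, p) cell: columns
#'   \code{k}, \code{p}, \code{mean_tvd}, \code{mean_correlation},
#'   \code{skipped} (logical), \code{reason} (why a cell was infeasible).
#' @slot bestK,bestP the pair minimizing mean TVD over computed cells; ties
#'   broken by smaller k, then smaller p.
#' @slot nComponents number of top components the search was run with.
#' @seealso [gridSearch()]
#' @export
setClass("GridResult",
  slots = c(grid = "data.frame", bestK = "integer", bestP = "numeric",
            nComponents = "integer"))

#' FoldAssignment: a cross-validation partition
#'
#' @slot foldOf named integer vector mapping sample ID to fold index in
#'   \code{0..nFolds-1}; fold sizes differ by at most one.
#' @slot nFolds number of folds.
#' @slot seed RNG seed the assignment was drawn with.
#' @seealso [makeFolds()], [crossValidate()]
#' @export
setClass("FoldAssignment",
  slots = c(foldOf = "integer", nFolds = "integer", seed = "integer"))

setValidity("FoldAssignment", function(object) {
  msg <- character(0)
  if (is.null(names(object@foldOf)) || anyDuplicated(names(object@foldOf)))
    msg <- c(msg, "foldOf must be named by unique sample IDs")
  if (length(object@foldOf)) {
    if (any(object@foldOf < 0L) || any(object@foldOf >= object@nFolds))
      msg <- c(msg, "fold indices must lie in 0..nFolds-1")
    sizes <- tabulate(object@foldOf + 1L, nbins = object@nFolds)
    if (max(sizes) - min(sizes) > 1L)
      msg <- c(msg, "fold sizes must differ by at most 1")
  }
  if (length(msg)) msg else TRUE
})

#' Scenario: how the reference panel and queries are defined
#'
#' Three reference-profile scenarios are supported. DISCRETE: the reference
#' samples carry one-hot profiles (100\% of ancestry in a single source
#' population) and the queries are a disjoint sample set. CONTINUOUS: the
#' same reference/query split, but references carry continuous profiles.
#' CONTINUOUSALL: every available sample is a reference with a continuous
#' profile, and queries are derived by cross-validation folds.
#'
#' @slot name one of \code{"DISCRETE"}, \code{"CONTINUOUS"},
#'   \code{"CONTINUOUSALL"}.
#' @slot referenceIDs sample IDs of the reference panel.
#' @slot queryIDs sample IDs of the query set (empty for CONTINUOUSALL).
#' @slot profileSource [ProfileMatrix-class] supplying the reference profiles
#'   (one-hot rows for DISCRETE).
#' @seealso [referenceScenario()], [gridSearch()]
#' @export
setClass("Scenario",
  slots = c(name = "character", referenceIDs = "character",
            queryIDs = "character", profileSource = "ProfileMatrix"))

setValidity("Scenario", function(object) {
  msg <- character(0)
  if (!object@name %in% c("DISCRETE", "CONTINUOUS", "CONTINUOUSALL"))
    msg <- c(msg, "name must be DISCRETE, CONTINUOUS or CONTINUOUSALL")
  prof <- object@profileSource
  missing <- setdiff(object@referenceIDs, rownames(prof@proportions))
  if (length(missing))
    msg <- c(msg, sprintf("profileSource lacks reference IDs: %s",
                          paste(utils::head(missing, 5), collapse = ", ")))
  if (object@name == "CONTINUOUSALL") {
    if (length(object@queryIDs))
      msg <- c(msg, "CONTINUOUSALL derives queries from folds; queryIDs must be empty")
  } else {
    if (!length(object@queryIDs))
      msg <- c(msg, sprintf("%s requires a nonempty query set", object@name))
    if (length(intersect(object@referenceIDs, object@queryIDs)))
      msg <- c(msg, "reference and query IDs must be disjoint")
    if (object@name == "DISCRETE") {
      pr <- prof@proportions[object@referenceIDs, , drop = FALSE]
      onehot <- apply(pr, 1L, function(r)
        sum(abs(r - 1) < 1e-9) == 1L && sum(abs(r) < 1e-9) == length(r) - 1L)
      if (!all(onehot))
        msg <- c(msg, "DISCRETE reference profiles must be one-hot")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a reference/query scenario
#'
#' @param name \code{"DISCRETE"}, \code{"CONTINUOUS"} or
#'   \code{"CONTINUOUSALL"}.
#' @param referenceIDs character vector of reference sample IDs.
#' @param profileSource [ProfileMatrix-class] holding (at least) the
#'   reference samples' profiles; rows must be one-hot for DISCRETE.
#' @param queryIDs character vector of query sample IDs (omit for
#'   CONTINUOUSALL, whose queries come from cross-validation folds).
#' @return A [Scenario-class] object.
#' @export
referenceScenario <- function(name, referenceIDs, profileSource,
                         queryIDs = character(0)) {
  new("Scenario", name = name, referenceIDs = as.character(referenceIDs),
      queryIDs = as.character(queryIDs), profileSource = profileSource)
}

#' MixupReport: which populations two profile sets swap ancestry between
#'
#' For each target population and sign of the marginal difference
#' (estimated minus truth), samples whose difference magnitude reaches the
#' threshold form a group; the group's mean differences in the other
#' populations that run in the opposite direction are normalized to sum to
#' one, attributing the disagreement to specific population pairs.
#'
#' @slot groups data.frame with columns \code{target}, \code{sign},
#'   \code{group_size}.
#' @slot attribution data.frame with columns \code{target}, \code{sign},
#'   \code{other_population}, \code{attribution} (rows present only for
#'   nonempty groups with at least one opposite-direction population;
#'   same-sign populations appear with attribution 0).
#' @slot threshold the marginal-difference magnitude defining "high".
#' @seealso [mixupAnalysis()]
#' @export
setClass("MixupReport",
  slots = c(groups = "data.frame", attribution = "data.frame",
            threshold = "numeric"))

#' SimConfig: parameters of the synthetic admixture simulator
#'
#' @slot S number of source populations.
#' @slot M number of components.
#' @slot nReference,nQuery sample counts.
#' @slot centroidSeparation minimum pairwise distance between population
#'   centroids, in raw component units.
#' @slot noiseSD isotropic per-component noise SD (scaled per component by
#'   the eigenvalue decay).
#' @slot dirichletAlpha length-S positive concentration of the Dirichlet the
#'   admixture proportions are drawn from.
#' @slot eigenvalueDecay geometric decay rate in (0, 1\]: raw component
#'   variance scale_m^2 is proportional to decay^(m-1).
#' @slot fracPure fraction of reference samples forced to one-hot profiles
#'   (assigned round-robin over populations).
#' @slot structureDims number of leading components in which the centroids
#'   differ; components beyond carry pure noise.
#' @slot seed integer RNG seed; all randomness derives from it.
#' @seealso [simConfig()], [simulateAdmixture()]
#' @export
setClass("SimConfig",
  slots = c(S = "integer", M = "integer", nReference = "integer",
            nQuery = "integer", centroidSeparation = "numeric",
            noiseSD = "numeric", dirichletAlpha = "numeric",
            eigenvalueDecay = "numeric", fracPure = "numeric",
            structureDims = "integer", seed = "integer"))

setValidity("SimConfig", function(object) {
  msg <- character(0)
  if (object@S < 1L) msg <- c(msg, "S must be >= 1")
  if (object@M < 1L) msg <- c(msg, "M must be >= 1")
  if (object@nReference < 1L || object@nQuery < 1L)
    msg <- c(msg, "sample counts must be positive")
  if (!is.finite(object@centroidSeparation) || object@centroidSeparation <= 0)
    msg <- c(msg, "centroidSeparation must be > 0")
  if (!is.finite(object@noiseSD) || object@noiseSD < 0)
    msg <- c(msg, "noiseSD must be >= 0")
  if (length(object@dirichletAlpha) != object@S ||
      any(object@dirichletAlpha <= 0))
    msg <- c(msg, "dirichletAlpha must be S positive reals")
  if (object@eigenvalueDecay <= 0 || object@eigenvalueDecay > 1)
    msg <- c(msg, "eigenvalueDecay must lie in (0, 1]")
  if (object@fracPure < 0 || object@fracPure > 1)
    msg <- c(msg, "fracPure must lie in [0, 1]")
  if (object@structureDims < 1L || object@structureDims > object@M)
    msg <- c(msg, "structureDims must lie in 1..M")
  if (length(msg)) msg else TRUE
})
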