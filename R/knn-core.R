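# Geometric engine: eigenvalue-weighted Euclidean distances in component
# space, column standardization, and exact k-nearest-neighbor selection.

#' Standardize component columns to zero mean and unit variance
#'
#' Each score column is transformed to \code{(x - mean) / sd} where the mean
#' and SD come from \code{statsSource}: the matrix itself (\code{"self"}) or
#' an external [ComponentMatrix-class] (e.g. the reference panel, when query
#' samples arrive after the reference statistics were fixed). The SD is the
#' population SD (divide by n), so that a self-standardized column has unit
#' variance as a property of the stored values; this convention is used
#' throughout the package. Eigenvalues are carried through unchanged.
#'
#' @param components a [ComponentMatrix-class].
#' @param statsSource \code{"self"} or a [ComponentMatrix-class] supplying
#'   the per-column statistics (its component count must be >= that of
#'   \code{components}).
#' @return A standardized [ComponentMatrix-class].
#' @examples
#' cm <- ComponentMatrix(matrix(1:3, 3, 1, dimnames = list(letters[1:3], NULL)), 1)
#' componentScores(standardizeComponents(cm))  # -1.2247, 0, 1.2247
#' @export
standardizeComponents <- function(components, statsSource = "self") {
  stopifnot(is(components, "ComponentMatrix"))
  src <- if (identical(statsSource, "self")) components else statsSource
  if (!is(src, "ComponentMatrix"))
    stop("statsSource must be \"self\" or a ComponentMatrix")
  ssc <- src@scores
  M <- ncol(components@scores)
  if (ncol(ssc) < M)
    stop("statsSource carries fewer components than the matrix to standardize")
  mu <- colMeans(ssc[, seq_len(M), drop = FALSE])
  cent <- sweep(ssc[, seq_len(M), drop = FALSE], 2, mu)
  sd_pop <- sqrt(colMeans(cent^2))
  if (any(sd_pop == 0)) {
    j <- which(sd_pop == 0)[1]
    nm <- colnames(components@scores)[j]
    stop(sprintf("cannot standardize: column %s has zero standard deviation",
                 if (is.null(nm)) as.character(j) else nm))
  }
  out <- sweep(sweep(components@scores, 2, mu), 2, sd_pop, "/")
  ComponentMatrix(out, components@eigenvalues, standardized = TRUE)
}

#' Normalize eigenvalues to sum to one
#'
#' The distance weights the squared difference along component m by its
#' eigenvalue; the M eigenvalues in use are normalized to sum to one, so the
#' distance is invariant to the overall scale of the eigenvalue spectrum.
#' Call this after subsetting to the top M components actually in use.
#'
#' @param eigenvalues nonnegative numeric vector with at least one strictly
#'   positive entry.
#' @return numeric vector proportional to the input, summing to 1.
#' @examples
#' normalizeEigenvalues(c(4, 1))  # 0.8 0.2
#' @export
normalizeEigenvalues <- function(eigenvalues) {
  if (!length(eigenvalues) || any(!is.finite(eigenvalues)) ||
      any(eigenvalues < 0))
    stop("eigenvalues must be finite and nonnegative")
  s <- sum(eigenvalues)
  if (s <= 0) stop("cannot normalize: all eigenvalues are zero")
  eigenvalues / s
}

#' Eigenvalue-weighted pairwise distances between query and reference
#'
#' Computes the n_Q x n_R matrix of distances
#' \deqn{d(i,j) = \sqrt{\sum_{m=1}^{M} \hat\lambda_m (x_{i,m} - x_{j,m})^2}}
#' where \eqn{\hat\lambda} are the top-M eigenvalues normalized to sum to
#' one. Query and reference must share the same eigenvalue spectrum and
#' standardization provenance. Runs in O(n_Q n_R M) via matrix products.
#'
#' @param query,reference [ComponentMatrix-class] objects sharing
#'   eigenvalues (and standardization state).
#' @param M number of top components to use; defaults to all shared
#'   components.
#' @return n_Q x n_R numeric matrix with query/reference sample IDs as
#'   dimnames; symmetric when \code{query} and \code{reference} coincide.
#' @examples
#' sc <- matrix(c(0, 0, 2, 2), 2, 2, byrow = TRUE,
#'              dimnames = list(c("a", "b"), NULL))
#' cm <- ComponentMatrix(sc, c(3, 1))
#' pairwiseDistances(cm, cm)["a", "b"]  # 2
#' @export
pairwiseDistances <- function(query, reference, M = NULL) {
  stopifnot(is(query, "ComponentMatrix"), is(reference, "ComponentMatrix"))
  shared <- min(nComponents(query), nComponents(reference))
  if (is.null(M)) M <- shared
  if (length(M) != 1L || M < 1L || M > shared)
    stop(sprintf("M must lie in 1..%d (shared component count); got %s",
                 shared, paste(M, collapse = ",")))
  evq <- query@eigenvalues[seq_len(M)]
  evr <- reference@eigenvalues[seq_len(M)]
  if (!isTRUE(all.equal(evq, evr, tolerance = 1e-8)))
    stop("query and reference eigenvalues differ over the top-", M,
         " components")
  if (query@standardized != reference@standardized)
    warning("query and reference differ in standardization state")
  lam <- normalizeEigenvalues(evr)
  w <- sqrt(lam)
  A <- sweep(query@scores[, seq_len(M), drop = FALSE], 2, w, "*")
  B <- sweep(reference@scores[, seq_len(M), drop = FALSE], 2, w, "*")
  # explicit differences rather than the |a|^2+|b|^2-2ab expansion: the
  # expansion loses ~8 digits to cancellation near coincident samples, and
  # identical rows must give exactly 0
  Bt <- t(B)
  d <- matrix(0, nrow(A), nrow(B))
  for (i in seq_len(nrow(A)))
    d[i, ] <- sqrt(colSums((Bt - A[i, ])^2))
  dimnames(d) <- list(rownames(query@scores), rownames(reference@scores))
  d
}

#' Select the k nearest reference samples from one row of distances
#'
#' Returns the k smallest admissible distances and their reference row
#' indices. The result equals a full stable sort of (distance, index) pairs
#' truncated at k: ties at the cutoff are broken by ascending reference row
#' index, making the selection a deterministic total order.
#'
#' @param distancesRow numeric vector of nonnegative distances to every
#'   reference sample.
#' @param k number of neighbors (after exclusions).
#' @param exclude integer indices of reference rows barred from selection
#'   (e.g. the query itself under leave-one-out).
#' @param queryIndex optional integer recorded in the result.
#' @return A [NeighborSet-class].
#' @examples
#' ns <- nearestNeighbors(c(5, 1, 3), k = 2)
#' ns@neighborIndices   # 2 3
#' ns@neighborDistances # 1 3
#' @export
nearestNeighbors <- function(distancesRow, k, exclude = integer(0),
                             queryIndex = NA_integer_) {
  n <- length(distancesRow)
  admissible <- setdiff(seq_len(n), exclude)
  if (length(k) != 1L || k < 1L || k > length(admissible))
    stop(sprintf("k must lie in 1..%d (admissible references after exclusion); got %s",
                 length(admissible), paste(k, collapse = ",")))
  ord <- admissible[order(distancesRow[admissible], admissible)]
  sel <- ord[seq_len(k)]
  new("NeighborSet", queryIndex = as.integer(queryIndex),
      neighborIndices = as.integer(sel),
      neighborDistances = as.numeric(distancesRow[sel]))
}
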