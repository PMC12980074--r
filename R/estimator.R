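#' Estimate ancestry profiles by k-nearest-neighbor regression
#'
#' For each query sample, finds its k nearest reference samples under the
#' eigenvalue-weighted component distance (see [pairwiseDistances()]) and
#' returns a weighted average of their ancestry profiles. With \code{p = 0}
#' the average is unweighted,
#' \deqn{q_{i,s} = \frac{1}{k} \sum_{j \in J_i^{(k)}} r_{j,s},}
#' and with \code{p > 0} the neighbors are inverse-distance weighted,
#' \eqn{w(i,j) = d'(i,j)^{-p}} where \eqn{d' = \max(d, \varepsilon)}
#' substitutes the floor \eqn{\varepsilon} for smaller distances so that
#' near-coincident samples cannot produce unbounded weights:
#' \deqn{q_{i,s} = \frac{\sum_j w(i,j)\, r_{j,s}}{\sum_j w(i,j)}.}
#' Each output row is a convex combination of reference rows and therefore
#' lies on the probability simplex.
#'
#' When a query sample ID also occurs in the reference panel and
#' \code{selfExclude = TRUE} (default), that reference row is barred from
#' the query's own neighbor set — leave-one-out semantics, as used when a
#' panel is evaluated against itself.
#'
#' @param query [ComponentMatrix-class] of query samples.
#' @param reference [ComponentMatrix-class] of reference samples, sharing
#'   eigenvalues/standardization with \code{query}.
#' @param refProfiles [ProfileMatrix-class] of known reference profiles;
#'   its sample IDs must match the reference panel's exactly (joined by ID,
#'   order-independent).
#' @param params a [KnnParams-class]; see [knnParams()]. If
#'   \code{nComponents} exceeds the components available, all available
#'   components are used with a warning.
#' @param selfExclude logical; exclude a reference sample from its own
#'   neighbor set when IDs coincide. Default \code{TRUE}.
#' @return A [ProfileMatrix-class] for the query samples, with the reference
#'   population labels.
#' @examples
#' refsc <- matrix(c(0, 3), 2, 1, dimnames = list(c("r1", "r2"), NULL))
#' qsc <- matrix(1, 1, 1, dimnames = list("q1", NULL))
#' ref <- ComponentMatrix(refsc, 1)
#' qry <- ComponentMatrix(qsc, 1)
#' prof <- ProfileMatrix(matrix(c(1, 0, 0, 1), 2, byrow = TRUE,
#'   dimnames = list(c("r1", "r2"), c("A", "B"))))
#' est <- estimateProfiles(qry, ref, prof, knnParams(k = 2, p = 1,
#'   nComponents = 1))
#' ancestryProportions(est)  # weights 1 and 1/2 -> (2/3, 1/3)
#' @export
estimateProfiles <- function(query, reference, refProfiles,
                             params = knnParams(), selfExclude = TRUE) {
  stopifnot(is(query, "ComponentMatrix"), is(reference, "ComponentMatrix"),
            is(refProfiles, "ProfileMatrix"), is(params, "KnnParams"))
  refIDs <- sampleIDs(reference)
  profIDs <- sampleIDs(refProfiles)
  onlyRef <- setdiff(refIDs, profIDs)
  onlyProf <- setdiff(profIDs, refIDs)
  if (length(onlyRef) || length(onlyProf))
    stop("reference panel and reference profiles must cover the same samples; ",
         "missing profiles: [",
         paste(utils::head(onlyRef, 5), collapse = ", "),
         "]; missing scores: [",
         paste(utils::head(onlyProf, 5), collapse = ", "), "]")
  P <- refProfiles@proportions[refIDs, , drop = FALSE]

  shared <- min(nComponents(query), nComponents(reference))
  M <- params@nComponents
  if (M > shared) {
    warning(sprintf("nComponents = %d exceeds the %d available components; using %d",
                    M, shared, shared))
    M <- shared
  }
  D <- pairwiseDistances(query, reference, M = M)

  k <- params@k
  p <- params@p
  eps <- params@epsilon
  qIDs <- sampleIDs(query)
  S <- ncol(P)
  out <- matrix(NA_real_, nrow(D), S,
                dimnames = list(qIDs, colnames(P)))
  refPos <- seq_along(refIDs)
  names(refPos) <- refIDs
  for (i in seq_len(nrow(D))) {
    excl <- integer(0)
    if (selfExclude && !is.na(refPos[qIDs[i]]))
      excl <- unname(refPos[qIDs[i]])
    ns <- tryCatch(nearestNeighbors(D[i, ], k, exclude = excl,
                                    queryIndex = i),
                   error = function(e)
                     stop("query ", qIDs[i], ": ", conditionMessage(e),
                          call. = FALSE))
    J <- ns@neighborIndices
    if (p == 0) {
      out[i, ] <- colMeans(P[J, , drop = FALSE])
    } else {
      w <- pmax(ns@neighborDistances, eps)^(-p)
      if (any(!is.finite(w)))
        stop("non-finite inverse-distance weight for query ", qIDs[i],
             "; increase epsilon or decrease p")
      sw <- sum(w)
      if (sw == 0)
        stop("all inverse-distance weights underflowed to zero for query ",
             qIDs[i], "; decrease p or rescale the components")
      out[i, ] <- as.numeric(crossprod(w, P[J, , drop = FALSE])) / sw
    }
  }
  ProfileMatrix(out)
}
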