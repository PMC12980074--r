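#' Total variation distance between two ancestry profiles
#'
#' \deqn{\mathrm{TVD}(q^{(1)}, q^{(2)}) = \frac{1}{2} \sum_{s=1}^{S}
#'   |q^{(1)}_s - q^{(2)}_s|}
#' On the probability simplex this is the fraction of ancestry mass assigned
#' differently by the two profiles: 0 iff they are identical, 1 iff their
#' supports are disjoint. Equivalently (for simplex vectors)
#' \eqn{1 - \sum_s \min(q^{(1)}_s, q^{(2)}_s)}.
#'
#' @param q1,q2 numeric vectors of equal length on the probability simplex.
#' @return a number in \[0, 1\].
#' @examples
#' tvd(c(0.6, 0.4), c(0.5, 0.5))  # 0.1
#' @export
tvd <- function(q1, q2) {
  if (length(q1) != length(q2))
    stop(sprintf("profile lengths differ: %d vs %d", length(q1), length(q2)))
  0.5 * sum(abs(q1 - q2))
}

# align two profile matrices by sample ID and population label; errors list
# the symmetric differences
align_profiles <- function(estimated, truth) {
  stopifnot(is(estimated, "ProfileMatrix"), is(truth, "ProfileMatrix"))
  idE <- sampleIDs(estimated)
  idT <- sampleIDs(truth)
  dId <- c(setdiff(idE, idT), setdiff(idT, idE))
  if (length(dId))
    stop("sample ID sets differ; symmetric difference: ",
         paste(utils::head(dId, 10), collapse = ", "))
  labE <- populationLabels(estimated)
  labT <- populationLabels(truth)
  dLab <- c(setdiff(labE, labT), setdiff(labT, labE))
  if (length(dLab))
    stop("population label sets differ; symmetric difference: ",
         paste(dLab, collapse = ", "))
  list(E = estimated@proportions,
       T = truth@proportions[idE, labE, drop = FALSE])
}

#' Compare an estimated profile set against a reference profile set
#'
#' Joins the two sets by sample ID and population label (order-independent)
#' and computes the per-sample total variation distance, its mean with a
#' normal-approximation 95\% confidence interval (mean +/- 1.96 sd/sqrt(n)),
#' and the Pearson correlation across samples between the estimated and
#' reference proportions of each population. Populations with zero variance
#' on either side have undefined correlation; they are recorded as \code{NA}
#' and excluded from the mean correlation, with a warning.
#'
#' @param estimated,truth [ProfileMatrix-class] objects over the same sample
#'   IDs and population labels.
#' @return An [EvaluationSummary-class].
#' @examples
#' pr <- ProfileMatrix(matrix(c(0.6, 0.4, 0.2, 0.8), 2, byrow = TRUE,
#'   dimnames = list(c("a", "b"), c("P1", "P2"))))
#' meanTVD(evaluateProfiles(pr, pr))  # 0
#' @export
evaluateProfiles <- function(estimated, truth) {
  al <- align_profiles(estimated, truth)
  E <- al$E
  Tr <- al$T
  perTVD <- 0.5 * rowSums(abs(E - Tr))
  names(perTVD) <- rownames(E)
  m <- mean(perTVD)
  n <- length(perTVD)
  se <- if (n > 1) stats::sd(perTVD) / sqrt(n) else NA_real_
  ci <- c(m - 1.96 * se, m + 1.96 * se)
  corS <- vapply(seq_len(ncol(E)), function(s) {
    if (stats::sd(E[, s]) == 0 || stats::sd(Tr[, s]) == 0) NA_real_
    else stats::cor(E[, s], Tr[, s])
  }, numeric(1))
  names(corS) <- colnames(E)
  if (anyNA(corS))
    warning("correlation undefined (zero variance) for population(s): ",
            paste(names(corS)[is.na(corS)], collapse = ", "),
            "; excluded from the mean")
  meanCor <- if (all(is.na(corS))) NA_real_ else mean(corS, na.rm = TRUE)
  new("EvaluationSummary", perSampleTVD = perTVD, meanTVD = m,
      meanTVDCI95 = ci, perComponentCorrelation = corS,
      meanCorrelation = meanCor)
}
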