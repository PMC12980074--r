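# Mix-up diagnostic: where do two profile sets move ancestry mass between
# populations for the same individuals?

#' Signed per-population marginal differences between two profile sets
#'
#' Entry (i, s) is \code{estimated[i, s] - truth[i, s]} after joining by
#' sample ID and population label. Because both rows lie on the simplex,
#' each row of the result sums to zero: mass overestimated in one
#' population must be taken from others.
#'
#' @param estimated,truth [ProfileMatrix-class] objects over the same
#'   samples and populations.
#' @return n x S numeric matrix of signed differences with sample IDs and
#'   population labels as dimnames.
#' @export
marginalDifferences <- function(estimated, truth) {
  al <- align_profiles(estimated, truth)
  al$E - al$T
}

#' Population mix-up analysis of marginal differences
#'
#' Taking each population in turn as the target, samples whose signed
#' marginal difference in the target reaches \code{threshold} in magnitude
#' are split by sign into a positive group (target overestimated) and a
#' negative group (underestimated). Within each group the arithmetic mean
#' of the differences in every other population is computed; only
#' populations whose mean runs in the opposite direction to the target
#' difference can have absorbed (or supplied) the mass, so their absolute
#' means are normalized to sum to one, giving the attribution of the
#' disagreement to specific population pairs. Populations whose mean has
#' the same sign as the target contribute 0. Zero differences belong to
#' neither group.
#'
#' @param differences n x S matrix from [marginalDifferences()] (rows sum
#'   to ~0, population labels as colnames).
#' @param threshold positive magnitude defining a "high" marginal
#'   difference; default 0.05.
#' @return A [MixupReport-class]. Empty groups get \code{group_size} 0 and
#'   no attribution rows; a nonempty group where every other population's
#'   mean is same-sign gets no attribution rows and a warning.
#' @examples
#' d <- matrix(c(0.10, -0.06, -0.04), 1,
#'             dimnames = list("s1", c("A", "B", "C")))
#' mixupAttribution(mixupAnalysis(d))  # A-positive: B 0.6, C 0.4
#' @export
mixupAnalysis <- function(differences, threshold = 0.05) {
  differences <- as.matrix(differences)
  if (length(threshold) != 1L || !is.finite(threshold) || threshold <= 0)
    stop("threshold must be a single positive number")
  if (is.null(colnames(differences)))
    colnames(differences) <- paste0("P", seq_len(ncol(differences)))
  if (nrow(differences) && any(abs(rowSums(differences)) > 1e-6))
    warning("difference rows do not sum to 0; input may not be a simplex difference")
  pops <- colnames(differences)
  S <- length(pops)
  groups <- list()
  attrib <- list()
  for (s in seq_len(S)) {
    for (g in c("positive", "negative")) {
      dCol <- differences[, s]
      sel <- if (g == "positive") dCol >= threshold else dCol <= -threshold
      size <- sum(sel)
      groups[[length(groups) + 1L]] <-
        data.frame(target = pops[s], sign = g, group_size = size,
                   stringsAsFactors = FALSE)
      if (size == 0L) next
      means <- colMeans(differences[sel, -s, drop = FALSE])
      opp <- if (g == "positive") means < 0 else means > 0
      if (!any(opp)) {
        warning(sprintf(
          "target %s (%s): no opposite-direction population; attribution undefined",
          pops[s], g))
        next
      }
      a <- ifelse(opp, abs(means), 0)
      a <- a / sum(a[opp])
      attrib[[length(attrib) + 1L]] <-
        data.frame(target = pops[s], sign = g,
                   other_population = pops[-s], attribution = unname(a),
                   stringsAsFactors = FALSE)
    }
  }
  groupsDF <- do.call(rbind, groups)
  attribDF <- if (length(attrib)) do.call(rbind, attrib) else
    data.frame(target = character(0), sign = character(0),
               other_population = character(0), attribution = numeric(0),
               stringsAsFactors = FALSE)
  rownames(groupsDF) <- NULL
  rownames(attribDF) <- NULL
  new("MixupReport", groups = groupsDF, attribution = attribDF,
      threshold = threshold)
}
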