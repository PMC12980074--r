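# Synthetic admixture simulator: component-space data with known
# ground-truth admixture profiles, so the estimator is testable end-to-end
# without any external dataset.
#
# Model: S source-population centroids in M-dimensional component space;
# each individual draws admixture proportions pi ~ Dirichlet(alpha) (or a
# one-hot profile for the "pure" reference subset) and sits at the
# profile-weighted average of the centroids plus isotropic per-component
# Gaussian noise. The linear-mixture placement encodes the standard
# first-order behaviour of admixed samples in PC space — the modelling
# assumption that makes nearest-neighbor ancestry regression sensible.
# Component variances decay geometrically (eigenvalue-like spectrum); the
# eigenvalues reported to the estimator are the theoretical per-component
# variances, so runs are exactly reproducible from the configuration.

#' Configure the synthetic admixture simulator
#'
#' Defaults describe a moderately hard, clearly clustered setting: 4 source
#' populations in 6 components, 800 reference and 200 query samples, sparse
#' admixture (Dirichlet concentration 0.5 per population), centroid
#' separation 8x the noise SD, geometric eigenvalue decay 0.7.
#'
#' @param S number of source populations.
#' @param M number of components.
#' @param nReference,nQuery sample counts.
#' @param centroidSeparation minimum pairwise centroid distance in raw
#'   component units.
#' @param noiseSD per-component noise SD before eigenvalue-decay scaling.
#' @param dirichletAlpha length-S positive vector (scalar is recycled).
#' @param eigenvalueDecay geometric decay in (0, 1\]; component m is scaled
#'   by \code{sqrt(decay^(m-1))}.
#' @param fracPure fraction of reference samples forced one-hot, assigned
#'   round-robin over populations.
#' @param structureDims number of leading components in which the centroids
#'   differ (default all M); later components are pure noise.
#' @param seed integer seed driving all randomness.
#' @return A [SimConfig-class].
#' @export
simConfig <- function(S = 4, M = 6, nReference = 800, nQuery = 200,
                      centroidSeparation = 8, noiseSD = 1,
                      dirichletAlpha = 0.5, eigenvalueDecay = 0.7,
                      fracPure = 0, structureDims = M, seed = 1) {
  if (length(dirichletAlpha) == 1L) dirichletAlpha <- rep(dirichletAlpha, S)
  new("SimConfig", S = as.integer(S), M = as.integer(M),
      nReference = as.integer(nReference), nQuery = as.integer(nQuery),
      centroidSeparation = as.numeric(centroidSeparation),
      noiseSD = as.numeric(noiseSD),
      dirichletAlpha = as.numeric(dirichletAlpha),
      eigenvalueDecay = as.numeric(eigenvalueDecay),
      fracPure = as.numeric(fracPure),
      structureDims = as.integer(structureDims), seed = as.integer(seed))
}

rdirichlet_mat <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = rep(alpha, each = n)),
              nrow = n)
  g / rowSums(g)
}

# E[pi pi'] and E[pi] for the mixture of round-robin one-hot (fraction f)
# and Dirichlet(alpha) profiles; used for the theoretical eigenvalues
profile_moments <- function(alpha, f) {
  S <- length(alpha)
  a0 <- sum(alpha)
  meanD <- alpha / a0
  m2D <- outer(alpha, alpha) / (a0 * (a0 + 1))
  diag(m2D) <- alpha * (alpha + 1) / (a0 * (a0 + 1))
  meanH <- rep(1 / S, S)
  m2H <- diag(1 / S, S)
  mean <- f * meanH + (1 - f) * meanD
  m2 <- f * m2H + (1 - f) * m2D
  list(mean = mean, cov = m2 - outer(mean, mean))
}

#' Simulate component-space data with known admixture ground truth
#'
#' Draws S centroids (scaled so their minimum pairwise distance equals
#' \code{centroidSeparation}), per-individual admixture profiles, and
#' coordinates as profile-weighted centroid mixtures plus Gaussian noise.
#' The reported eigenvalues are the theoretical per-component variances of
#' the generated coordinates. All randomness derives from
#' \code{config@seed} through per-stage substreams, so outputs are
#' bit-identical across calls with the same configuration, and adding draws
#' to one stage does not shift another.
#'
#' @param config a [SimConfig-class]; see [simConfig()].
#' @return named list with elements \code{reference}, \code{query}
#'   ([ComponentMatrix-class]) and \code{referenceProfiles},
#'   \code{queryProfiles} ([ProfileMatrix-class] ground truth).
#' @examples
#' sim <- simulateAdmixture(simConfig(nReference = 50, nQuery = 10, seed = 7))
#' nComponents(sim$reference)
#' @export
simulateAdmixture <- function(config) {
  stopifnot(is(config, "SimConfig"))
  S <- config@S
  M <- config@M
  scale_m <- sqrt(config@eigenvalueDecay^(seq_len(M) - 1))

  # centroids: standard normal directions scaled per component, then the
  # whole configuration rescaled so the minimum pairwise distance equals
  # centroidSeparation; bounded retries guard against degenerate draws
  centroids <- with_local_seed(substream_seed(config@seed, "centroids"), {
    for (try in 1:100) {
      C <- matrix(stats::rnorm(S * M), S, M)
      if (config@structureDims < M)
        C[, (config@structureDims + 1L):M] <- 0
      C <- sweep(C, 2, scale_m, "*")
      if (S == 1L) break
      d0 <- min(stats::dist(C))
      if (d0 > 1e-8) {
        C <- C * config@centroidSeparation / d0
        break
      }
      if (try == 100)
        stop("centroid placement failed: could not separate ", S,
             " centroids in ", config@structureDims, " dimensions")
    }
    C
  })

  nPure <- round(config@fracPure * config@nReference)
  nFree <- config@nReference - nPure
  refProf <- matrix(0, config@nReference, S)
  if (nPure > 0)
    refProf[cbind(seq_len(nPure), (seq_len(nPure) - 1L) %% S + 1L)] <- 1
  if (nFree > 0)
    refProf[(nPure + 1L):config@nReference, ] <-
      with_local_seed(substream_seed(config@seed, "profiles-ref"),
                      rdirichlet_mat(nFree, config@dirichletAlpha))
  qryProf <- with_local_seed(substream_seed(config@seed, "profiles-query"),
                             rdirichlet_mat(config@nQuery,
                                            config@dirichletAlpha))

  noise <- function(n, tag) {
    z <- with_local_seed(substream_seed(config@seed, tag),
                         matrix(stats::rnorm(n * M), n, M))
    sweep(z, 2, config@noiseSD * scale_m, "*")
  }
  refScores <- refProf %*% centroids + noise(config@nReference, "noise-ref")
  qryScores <- qryProf %*% centroids + noise(config@nQuery, "noise-query")

  # theoretical per-component variance over the pooled generated samples
  fPooled <- nPure / (config@nReference + config@nQuery)
  mom <- profile_moments(config@dirichletAlpha, fPooled)
  lambda <- vapply(seq_len(M), function(m)
    drop(crossprod(centroids[, m], mom$cov %*% centroids[, m])) +
      (config@noiseSD * scale_m[m])^2, numeric(1))
  lambda <- pmax(lambda, 0)  # guard against -1e-17 from the quadratic form

  refIDs <- sprintf("REF%04d", seq_len(config@nReference))
  qryIDs <- sprintf("QRY%04d", seq_len(config@nQuery))
  pops <- sprintf("POP%d", seq_len(S))
  dimnames(refScores) <- list(refIDs, paste0("C", seq_len(M)))
  dimnames(qryScores) <- list(qryIDs, paste0("C", seq_len(M)))
  dimnames(refProf) <- list(refIDs, pops)
  dimnames(qryProf) <- list(qryIDs, pops)
  list(reference = ComponentMatrix(refScores, lambda),
       referenceProfiles = ProfileMatrix(refProf),
       query = ComponentMatrix(qryScores, lambda),
       queryProfiles = ProfileMatrix(qryProf))
}

#' Collapse continuous profiles to one-hot (discrete) profiles
#'
#' Replaces each row by the one-hot indicator of its largest component;
#' ties go to the first (leftmost) label. Useful for building a DISCRETE
#' reference panel from continuous profiles, e.g. to compare discrete vs
#' continuous reference information on the same samples.
#'
#' @param profiles a [ProfileMatrix-class].
#' @return A [ProfileMatrix-class] of one-hot rows.
#' @examples
#' pr <- ProfileMatrix(matrix(c(0.7, 0.3), 1,
#'   dimnames = list("s1", c("A", "B"))))
#' ancestryProportions(thresholdToDiscrete(pr))  # 1 0
#' @export
thresholdToDiscrete <- function(profiles) {
  stopifnot(is(profiles, "ProfileMatrix"))
  pr <- profiles@proportions
  out <- matrix(0, nrow(pr), ncol(pr), dimnames = dimnames(pr))
  if (nrow(pr))
    out[cbind(seq_len(nrow(pr)), apply(pr, 1L, which.max))] <- 1
  ProfileMatrix(out)
}
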