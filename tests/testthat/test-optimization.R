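sim_small <- function(seed = 101, nRef = 120, nQry = 40) {
  simulateAdmixture(simConfig(S = 3, M = 4, nReference = nRef,
                              nQuery = nQry, seed = seed))
}

test_that("fold assignment is a seeded, balanced partition", {
  f <- makeFolds(paste0("s", 1:10), nFolds = 10, seed = 5)
  expect_equal(as.integer(table(foldOf(f))), rep(1L, 10))

  f3 <- makeFolds(paste0("s", 1:10), nFolds = 3, seed = 5)
  expect_setequal(as.integer(table(foldOf(f3))), c(4L, 3L))
  expect_setequal(names(foldOf(f3)), paste0("s", 1:10))

  expect_identical(foldOf(makeFolds(paste0("s", 1:50), 10, seed = 9)),
                   foldOf(makeFolds(paste0("s", 1:50), 10, seed = 9)))

  expect_error(makeFolds(paste0("s", 1:5), nFolds = 1), "2\\.\\.5")
  expect_error(makeFolds(paste0("s", 1:5), nFolds = 6), "2\\.\\.5")
})

test_that("fold construction leaves the caller's RNG stream untouched", {
  set.seed(77)
  a <- runif(1)
  set.seed(77)
  invisible(makeFolds(paste0("s", 1:20), 4, seed = 123))
  b <- runif(1)
  expect_identical(a, b)
})

test_that("cross-validation equals an independent per-fold loop and never self-references", {
  sim <- sim_small()
  ids <- sampleIDs(sim$referenceProfiles)
  folds <- makeFolds(ids, nFolds = 5, seed = 3)
  pars <- knnParams(k = 10, p = 3, nComponents = 4)
  cv <- crossValidate(sim$reference, sim$referenceProfiles, folds, pars)

  # naive per-fold loop with the brute-force estimator
  fmap <- foldOf(folds)
  allTVD <- c()
  for (f in 0:4) {
    qIDs <- names(fmap)[fmap == f]
    rIDs <- names(fmap)[fmap != f]
    expect_length(intersect(qIDs, rIDs), 0)
    est <- naive_estimate(
      componentScores(sim$reference)[qIDs, , drop = FALSE],
      componentScores(sim$reference)[rIDs, , drop = FALSE],
      eigenValues(sim$reference),
      ancestryProportions(sim$referenceProfiles)[rIDs, , drop = FALSE],
      k = 10, p = 3, eps = 0.1)
    truth <- ancestryProportions(sim$referenceProfiles)[qIDs, , drop = FALSE]
    allTVD <- c(allTVD, 0.5 * rowSums(abs(est - truth)))
  }
  expect_equal(meanTVD(cv), mean(allTVD), tolerance = 1e-12)
  expect_equal(sort(names(perSampleTVD(cv))), sort(ids))

  # fold sizes differ by at most one
  sizes <- as.integer(table(fmap))
  expect_lte(max(sizes) - min(sizes), 1L)
})

test_that("infeasible k errors name the offending fold", {
  sim <- sim_small(nRef = 12, nQry = 5)
  folds <- makeFolds(sampleIDs(sim$referenceProfiles), nFolds = 3, seed = 1)
  expect_error(crossValidate(sim$reference, sim$referenceProfiles, folds,
                             knnParams(k = 11, nComponents = 4)),
               "fold")
})

test_that("grid search records cells, skips infeasible k, and picks the argmin", {
  sim <- sim_small()
  ids <- sampleIDs(sim$referenceProfiles)
  refIDs <- ids[1:80]
  qryIDs <- ids[81:120]
  sc <- referenceScenario("CONTINUOUS", refIDs, sim$referenceProfiles, qryIDs)
  gr <- gridSearch(sc, sim$reference, sim$referenceProfiles,
                   kGrid = c(5, 10, 200), pGrid = c(0, 3),
                   paramsBase = knnParams(nComponents = 4))
  g <- gridTable(gr)
  expect_equal(nrow(g), 6)
  expect_true(all(g$skipped[g$k == 200]))
  expect_match(g$reason[g$k == 200][1], "80")
  ok <- !g$skipped
  best <- bestParams(gr)
  expect_equal(min(g$mean_tvd[ok]),
               g$mean_tvd[ok][g$k[ok] == best["k"] & g$p[ok] == best["p"]])

  # single cell grid: best is that cell
  g1 <- gridSearch(sc, sim$reference, sim$referenceProfiles, 7, 2,
                   knnParams(nComponents = 4))
  expect_equal(unname(bestParams(g1)), c(7, 2))

  # duplicated cells are deduplicated with a warning
  expect_warning(gd <- gridSearch(sc, sim$reference, sim$referenceProfiles,
                                  c(5, 5), 0, knnParams(nComponents = 4)),
                 "duplicate")
  expect_equal(nrow(gridTable(gd)), 1)

  expect_error(gridSearch(sc, sim$reference, sim$referenceProfiles,
                          integer(0), 1, knnParams(nComponents = 4)),
               "nonempty")
})

test_that("well-separated clusters favor k = 1 over k = n_R at p = 0", {
  sim <- simulateAdmixture(simConfig(S = 3, M = 4, nReference = 90,
                                     nQuery = 30, fracPure = 1,
                                     dirichletAlpha = 0.05,
                                     centroidSeparation = 20, seed = 7))
  ids <- sampleIDs(sim$reference)
  # queries drawn near single clusters: use the simulated query set
  qids <- sampleIDs(sim$query)
  comp <- ComponentMatrix(rbind(componentScores(sim$reference),
                                componentScores(sim$query)),
                          eigenValues(sim$reference))
  truthAll <- ProfileMatrix(rbind(
    ancestryProportions(sim$referenceProfiles),
    ancestryProportions(sim$queryProfiles)))
  sc <- referenceScenario("CONTINUOUS", ids, truthAll, qids)
  # the k = 90 (= n_R), p = 0 cell estimates one shared profile, leaving
  # per-population correlations undefined there
  gr <- suppressWarnings(
    gridSearch(sc, comp, truthAll, kGrid = c(1, 90), pGrid = 0,
               paramsBase = knnParams(nComponents = 4)))
  g <- gridTable(gr)
  expect_equal(unname(bestParams(gr)["k"]), 1)
  expect_lt(g$mean_tvd[g$k == 1], g$mean_tvd[g$k == 90])
})

test_that("CONTINUOUSALL grid search cross-validates with shared folds", {
  sim <- sim_small(nRef = 60, nQry = 5)
  ids <- sampleIDs(sim$referenceProfiles)
  sc <- referenceScenario("CONTINUOUSALL", ids, sim$referenceProfiles)
  folds <- makeFolds(ids, nFolds = 4, seed = 2)
  gr <- gridSearch(sc, sim$reference, sim$referenceProfiles,
                   kGrid = c(5, 10), pGrid = c(0, 3),
                   paramsBase = knnParams(nComponents = 4), folds = folds)
  g <- gridTable(gr)
  # each cell equals a direct crossValidate call with the same folds
  for (i in seq_len(nrow(g))) {
    cv <- crossValidate(sim$reference, sim$referenceProfiles, folds,
                        knnParams(k = g$k[i], p = g$p[i], nComponents = 4))
    expect_equal(g$mean_tvd[i], meanTVD(cv), tolerance = 1e-12)
  }
})

test_that("scenario validity enforces one-hot DISCRETE profiles and disjoint splits", {
  sim <- sim_small(nRef = 20, nQry = 5)
  ids <- sampleIDs(sim$referenceProfiles)
  expect_error(referenceScenario("DISCRETE", ids[1:10], sim$referenceProfiles,
                            ids[11:20]),
               "one-hot")
  disc <- thresholdToDiscrete(sim$referenceProfiles)
  expect_s4_class(referenceScenario("DISCRETE", ids[1:10], disc, ids[11:20]),
                  "Scenario")
  expect_error(referenceScenario("DISCRETE", ids[1:10], disc, ids[10:15]),
               "disjoint")
  expect_error(referenceScenario("CONTINUOUSALL", ids, disc, ids[1:2]), "empty")
})

test_that("component sweep returns one optimum per M and validates its range", {
  sim <- sim_small(nRef = 60, nQry = 20)
  ids <- sampleIDs(sim$referenceProfiles)
  sc <- referenceScenario("CONTINUOUS", ids[1:40], sim$referenceProfiles,
                     ids[41:60])
  sw <- componentSweep(sc, sim$reference, sim$referenceProfiles,
                       mValues = c(1, 4), kGrid = c(5, 10), pGrid = c(0, 3),
                       paramsBase = knnParams())
  expect_equal(sw$M, c(1, 4))
  expect_true(all(is.finite(sw$best_mean_tvd)))

  # single full-M sweep reduces to one grid search
  gr <- gridSearch(sc, sim$reference, sim$referenceProfiles, c(5, 10),
                   c(0, 3), knnParams(nComponents = 4))
  sw4 <- componentSweep(sc, sim$reference, sim$referenceProfiles, 4,
                        c(5, 10), c(0, 3), knnParams())
  expect_equal(sw4$best_mean_tvd,
               min(gridTable(gr)$mean_tvd[!gridTable(gr)$skipped]))

  expect_error(componentSweep(sc, sim$reference, sim$referenceProfiles,
                              c(0, 2), c(5), c(0), knnParams()),
               "1\\.\\.4")
})
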