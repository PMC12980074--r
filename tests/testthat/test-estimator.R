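test_that("hand-computable estimator anchors hold exactly", {
  # two references on a line, query at 1: distances 1 and 2
  r <- make_ref(matrix(c(0, 3), 2, 1), 1, matrix(c(1, 0, 0, 1), 2,
                                                 byrow = TRUE))
  q <- ComponentMatrix(matrix(1, 1, 1, dimnames = list("q1", NULL)), 1)

  # k = 1: nearest reference's profile verbatim, any p
  for (p in c(0, 1, 3)) {
    est <- estimateProfiles(q, r$cm, r$pm,
                            knnParams(k = 1, p = p, nComponents = 1))
    expect_equal(unname(ancestryProportions(est)[1, ]), c(1, 0))
  }

  # k = 2, p = 1, eps = 0.1: weights 1 and 1/2 -> (2/3, 1/3)
  est <- estimateProfiles(q, r$cm, r$pm,
                          knnParams(k = 2, p = 1, nComponents = 1))
  expect_equal(unname(ancestryProportions(est)[1, ]), c(2 / 3, 1 / 3),
               tolerance = 1e-12)

  # k = n_R, p = 0: unweighted mean of all reference profiles
  est0 <- estimateProfiles(q, r$cm, r$pm,
                           knnParams(k = 2, p = 0, nComponents = 1))
  expect_equal(unname(ancestryProportions(est0)[1, ]), c(0.5, 0.5))
})

test_that("epsilon floor substitutes for sub-threshold distances before exponentiation", {
  # references at distances 0.05 and 1; eps = 0.1, p = 2:
  # near weight is 0.1^-2 = 100 (not 0.05^-2 = 400), far weight 1
  r <- make_ref(matrix(c(0.05, 1), 2, 1), 1,
                matrix(c(1, 0, 0, 1), 2, byrow = TRUE))
  q <- ComponentMatrix(matrix(0, 1, 1, dimnames = list("q1", NULL)), 1)
  est <- estimateProfiles(q, r$cm, r$pm,
                          knnParams(k = 2, p = 2, epsilon = 0.1,
                                     nComponents = 1))
  expect_equal(unname(ancestryProportions(est)[1, ]),
               c(100, 1) / 101, tolerance = 1e-12)
})

test_that("k = n_R with p = 0 yields the same (global mean) profile for every query", {
  set.seed(21)
  pr <- rand_simplex(20, 3)
  r <- make_ref(matrix(rnorm(40), 20, 2), c(2, 1), pr)
  q <- ComponentMatrix(matrix(rnorm(10), 5, 2,
                              dimnames = list(paste0("q", 1:5), NULL)),
                       c(2, 1))
  est <- ancestryProportions(
    estimateProfiles(q, r$cm, r$pm, knnParams(k = 20, p = 0,
                                               nComponents = 2)))
  for (i in 2:5) expect_equal(unname(est[i, ]), unname(est[1, ]))
  expect_equal(unname(est[1, ]), unname(colMeans(pr)), tolerance = 1e-12)
})

test_that("estimates match the per-query loop oracle on random instances", {
  set.seed(22)
  for (rep in 1:60) {
    nR <- sample(5:60, 1)
    nQ <- sample(1:5, 1)
    M <- sample(1:6, 1)
    S <- sample(2:5, 1)
    k <- sample(seq_len(nR), 1)
    p <- sample(0:6, 1)
    ev <- runif(M, 0.1, 4)
    rs <- matrix(rnorm(nR * M), nR, M, dimnames = list(paste0("r", 1:nR),
                                                       NULL))
    qs <- matrix(rnorm(nQ * M), nQ, M, dimnames = list(paste0("q", 1:nQ),
                                                       NULL))
    pr <- rand_simplex(nR, S)
    dimnames(pr) <- list(rownames(rs), paste0("P", 1:S))
    est <- estimateProfiles(ComponentMatrix(qs, ev), ComponentMatrix(rs, ev),
                            ProfileMatrix(pr),
                            knnParams(k = k, p = p, nComponents = M))
    want <- naive_estimate(qs, rs, ev, pr, k, p, 0.1, M)
    expect_lt(max(abs(ancestryProportions(est) - want)), 1e-10)
    # simplex conservation
    expect_lt(max(abs(rowSums(ancestryProportions(est)) - 1)), 1e-9)
    expect_true(all(ancestryProportions(est) >= -1e-12 &
                    ancestryProportions(est) <= 1 + 1e-12))
  }
})

test_that("discrete references with p = 0 give neighbor label fractions", {
  set.seed(23)
  rs <- matrix(rnorm(30), 15, 2, dimnames = list(paste0("r", 1:15), NULL))
  lab <- sample(1:3, 15, replace = TRUE)
  pr <- matrix(0, 15, 3, dimnames = list(rownames(rs), c("A", "B", "C")))
  pr[cbind(1:15, lab)] <- 1
  qs <- matrix(rnorm(4), 2, 2, dimnames = list(c("q1", "q2"), NULL))
  ev <- c(1, 1)
  k <- 5
  est <- ancestryProportions(
    estimateProfiles(ComponentMatrix(qs, ev), ComponentMatrix(rs, ev),
                     ProfileMatrix(pr), knnParams(k = k, p = 0,
                                                   nComponents = 2)))
  D <- pairwiseDistances(ComponentMatrix(qs, ev), ComponentMatrix(rs, ev))
  for (i in 1:2) {
    J <- nearestNeighbors(D[i, ], k)@neighborIndices
    expect_equal(unname(est[i, ]),
                 unname(tabulate(lab[J], 3) / k))
  }
})

test_that("self-exclusion removes a query's own reference row; off, k=1 returns itself", {
  set.seed(24)
  rs <- matrix(rnorm(20), 10, 2, dimnames = list(paste0("s", 1:10), NULL))
  pr <- rand_simplex(10, 3)
  dimnames(pr) <- list(rownames(rs), c("A", "B", "C"))
  ref <- ComponentMatrix(rs, c(1, 1))
  prof <- ProfileMatrix(pr)

  # query IS a reference sample: with exclusion off, k=1 returns its own row
  q <- ref["s4", ]
  estOff <- estimateProfiles(q, ref, prof, knnParams(k = 1, p = 3,
                                                      nComponents = 2),
                             selfExclude = FALSE)
  expect_equal(unname(ancestryProportions(estOff)[1, ]), unname(pr[4, ]))

  # with exclusion on (default), its own row cannot be returned
  estOn <- estimateProfiles(q, ref, prof, knnParams(k = 1, p = 3,
                                                     nComponents = 2))
  D <- pairwiseDistances(q, ref)
  nn <- nearestNeighbors(D[1, ], 1, exclude = 4L)
  expect_equal(unname(ancestryProportions(estOn)[1, ]),
               unname(pr[nn@neighborIndices, ]))

  # k = n_R only feasible with exclusion off
  expect_error(estimateProfiles(q, ref, prof,
                                knnParams(k = 10, p = 0, nComponents = 2)),
               "1\\.\\.9")
})

test_that("a coincident reference dominates as p grows; influence is monotone in p", {
  set.seed(25)
  # query exactly on one reference, all others far: large p reproduces it
  rs <- rbind(c(0, 0), matrix(rnorm(18, sd = 1) + 5, 9, 2))
  rownames(rs) <- paste0("r", 1:10)
  pr <- rand_simplex(10, 3)
  dimnames(pr) <- list(rownames(rs), c("A", "B", "C"))
  q <- ComponentMatrix(matrix(c(0, 0), 1, 2, dimnames = list("q1", NULL)),
                       c(1, 1))
  est <- estimateProfiles(q, ComponentMatrix(rs, c(1, 1)), ProfileMatrix(pr),
                          knnParams(k = 10, p = 12, nComponents = 2))
  expect_lt(tvd(ancestryProportions(est)[1, ], pr[1, ]), 1e-6)

  # increasing p concentrates influence on the nearest reference: its
  # weight share is nondecreasing in p, and by the time p is large the
  # estimate has moved (from the p = 0 mean) essentially onto its profile.
  # Note the *path* is not TVD-monotone: mid-distance neighbors can gain
  # weight relative to far ones at small p before the nearest dominates.
  for (rep in 1:10) {
    rs <- matrix(rnorm(16), 8, 2, dimnames = list(paste0("r", 1:8), NULL))
    pr <- rand_simplex(8, 3)
    dimnames(pr) <- list(rownames(rs), c("A", "B", "C"))
    q <- ComponentMatrix(matrix(rnorm(2), 1, 2, dimnames = list("q1", NULL)),
                         c(1, 1))
    ref <- ComponentMatrix(rs, c(1, 1))
    D <- pairwiseDistances(q, ref)
    ds <- sort(D[1, ])
    if (ds[1] < 0.1 || ds[2] / ds[1] < 1.3) next  # need a clear nearest
    nearest <- pr[nearestNeighbors(D[1, ], 1)@neighborIndices, ]
    shares <- vapply(0:12, function(p) {
      w <- pmax(D[1, ], 0.1)^(-p)
      max(w) / sum(w)
    }, numeric(1))
    expect_true(all(diff(shares) >= -1e-12))
    tvdAt <- function(p) {
      est <- estimateProfiles(q, ref, ProfileMatrix(pr),
                              knnParams(k = 8, p = p, nComponents = 2))
      tvd(ancestryProportions(est)[1, ], nearest)
    }
    expect_lte(tvdAt(12), tvdAt(0) + 1e-12)
    expect_lt(tvdAt(25), 0.02)
  }
})

test_that("reference/profile ID misalignment and infeasible k are hard errors", {
  r <- make_ref(matrix(c(0, 3), 2, 1), 1, matrix(c(1, 0, 0, 1), 2,
                                                 byrow = TRUE))
  q <- ComponentMatrix(matrix(1, 1, 1, dimnames = list("q1", NULL)), 1)
  badProf <- ProfileMatrix(matrix(c(1, 0, 0, 1), 2, byrow = TRUE,
                                  dimnames = list(c("r1", "rX"),
                                                  c("P1", "P2"))))
  expect_error(estimateProfiles(q, r$cm, badProf, knnParams(k = 1)),
               "r2.*rX|rX.*r2")
  expect_error(estimateProfiles(q, r$cm, r$pm,
                                knnParams(k = 5, nComponents = 1)),
               "1\\.\\.2")
})

test_that("requesting more components than available falls back with a warning", {
  r <- make_ref(matrix(c(0, 3), 2, 1), 1, matrix(c(1, 0, 0, 1), 2,
                                                 byrow = TRUE))
  q <- ComponentMatrix(matrix(1, 1, 1, dimnames = list("q1", NULL)), 1)
  expect_warning(est <- estimateProfiles(q, r$cm, r$pm,
                                         knnParams(k = 1, nComponents = 10)),
                 "available")
  expect_equal(unname(ancestryProportions(est)[1, ]), c(1, 0))
})
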