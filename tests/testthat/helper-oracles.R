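# Independent brute-force oracles: plain double loops over the defining
# formulas, deliberately sharing no code with the package implementation.

# eigenvalue-weighted distance, explicit summation
naive_distance <- function(xi, xj, lambda_hat) {
  s <- 0
  for (m in seq_along(lambda_hat))
    s <- s + lambda_hat[m] * (xi[m] - xj[m])^2
  unname(sqrt(s))
}

# full stable sort of (distance, index) pairs truncated at k
naive_knn <- function(d, k, exclude = integer(0)) {
  keep <- setdiff(seq_along(d), exclude)
  pairs <- data.frame(d = d[keep], i = keep)
  pairs <- pairs[order(pairs$d, pairs$i), ]
  list(indices = pairs$i[seq_len(k)], distances = pairs$d[seq_len(k)])
}

# per-query loop estimator straight from the formulas
naive_estimate <- function(qScores, rScores, rawEigen, profiles, k, p, eps,
                           M = ncol(qScores), selfExclude = TRUE) {
  lam <- rawEigen[seq_len(M)] / sum(rawEigen[seq_len(M)])
  nQ <- nrow(qScores)
  out <- matrix(NA_real_, nQ, ncol(profiles),
                dimnames = list(rownames(qScores), colnames(profiles)))
  for (i in seq_len(nQ)) {
    d <- numeric(nrow(rScores))
    for (j in seq_len(nrow(rScores)))
      d[j] <- naive_distance(qScores[i, seq_len(M)], rScores[j, seq_len(M)],
                             lam)
    excl <- if (selfExclude)
      which(rownames(rScores) == rownames(qScores)[i]) else integer(0)
    nn <- naive_knn(d, k, excl)
    if (p == 0) {
      acc <- rep(0, ncol(profiles))
      for (j in nn$indices) acc <- acc + profiles[j, ]
      out[i, ] <- acc / k
    } else {
      w <- pmax(nn$distances, eps)^(-p)
      num <- rep(0, ncol(profiles))
      for (t in seq_along(nn$indices))
        num <- num + w[t] * profiles[nn$indices[t], ]
      out[i, ] <- num / sum(w)
    }
  }
  out
}

# closed-form TVD for simplex vectors
tvd_minform <- function(q1, q2) 1 - sum(pmin(q1, q2))

# random simplex rows via normalized exponentials
rand_simplex <- function(n, S) {
  g <- matrix(stats::rexp(n * S), n, S)
  g / rowSums(g)
}

# small labelled ComponentMatrix/ProfileMatrix pair for hand-built cases
make_ref <- function(scores, eigen, profiles, ids = NULL,
                     pops = paste0("P", seq_len(ncol(profiles)))) {
  if (is.null(ids)) ids <- paste0("r", seq_len(nrow(scores)))
  rownames(scores) <- ids
  rownames(profiles) <- ids
  colnames(profiles) <- pops
  list(cm = ComponentMatrix(scores, eigen), pm = ProfileMatrix(profiles))
}
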