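# shared fixtures and independent oracles for the test suite

# seeded random full-column-rank matched pair
random_pair <- function(seed, K1 = NULL, K2 = NULL, L = NULL, sd = 1) {
  set.seed(seed)
  if (is.null(L)) L <- sample(2:10, 1)
  if (is.null(K1)) K1 <- sample(L:50, 1)
  if (is.null(K2)) K2 <- sample(L:50, 1)
  matched_pair_from_matrices(matrix(rnorm(K1 * L, sd = sd), K1),
                             matrix(rnorm(K2 * L, sd = sd), K2))
}

# brute-force oracle: squared generalized-singular-value ratios are the
# eigenvalues of (D2'D2)^-1 (D1'D1)
ratio_sq_oracle <- function(pair) {
  D1 <- pair$tumor$values; D2 <- pair$normal$values
  sort(Re(eigen(solve(crossprod(D2)) %*% crossprod(D1))$values))
}

relative_error <- function(x, ref) norm(x - ref, "F") / norm(ref, "F")

max_orth_dev <- function(U) max(abs(crossprod(U) - diag(ncol(U))))

balanced_accuracy <- function(pred, truth) {
  (mean(pred[truth]) + mean(!pred[!truth])) / 2
}

# hand computation of the Kaplan-Meier product-limit estimator
km_oracle <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  surv <- numeric(length(ts))
  s <- 1
  for (i in seq_along(ts)) {
    n_risk <- sum(time >= ts[i])
    d <- sum(time == ts[i] & event == 1)
    s <- s * (1 - d / n_risk)
    surv[i] <- s
  }
  list(time = ts, surv = surv)
}

# hand computation of the two-group log-rank O-E table and statistic
logrank_oracle <- function(time, event, grp) {
  labs <- sort(unique(grp))
  ts <- sort(unique(time[event == 1]))
  O <- 0; E <- 0; V <- 0
  for (t in ts) {
    n <- sum(time >= t)
    n1 <- sum(time >= t & grp == labs[1])
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & grp == labs[1])
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  list(observed = O, expected = E, var = V, chisq = (O - E)^2 / V)
}
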