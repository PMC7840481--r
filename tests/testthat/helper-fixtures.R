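# shared fixture builders and independent oracles

rand_count_matrix <- function(n_mir = 6, n_samp = 10, seed = 1,
                              lambda = 50) {
  set.seed(seed)
  m <- matrix(rpois(n_mir * n_samp, lambda), nrow = n_mir,
              dimnames = list(sprintf("mir%03d", seq_len(n_mir)),
                              sprintf("S%03d", seq_len(n_samp))))
  count_matrix(m)
}

# brute-force Spearman: explicit mid-ranks, explicit Pearson formula
oracle_spearman <- function(x, y) {
  # mid-rank = average position of equal values in the sorted vector
  rx <- sapply(x, function(xi) mean(which(sort(x) == xi)))
  ry <- sapply(y, function(yi) mean(which(sort(y) == yi)))
  n <- length(x)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# brute-force median-of-ratios size factors per the definition
oracle_size_factors <- function(m) {
  ref <- which(apply(m, 1, function(r) all(r > 0)))
  geo <- exp(rowMeans(log(m[ref, , drop = FALSE])))
  apply(m[ref, , drop = FALSE], 2, function(col) median(col / geo))
}

# hand-coded step-up BH
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# independent iteratively-reweighted least squares logistic fit
oracle_logistic <- function(y, x, tol = 1e-12, maxit = 100) {
  X <- cbind(1, x)
  b <- c(0, 0)
  for (i in seq_len(maxit)) {
    eta <- as.vector(X %*% b)
    mu <- 1 / (1 + exp(-eta))
    W <- mu * (1 - mu)
    z <- eta + (y - mu) / W
    b_new <- solve(t(X) %*% (W * X), t(X) %*% (W * z))
    if (max(abs(b_new - b)) < tol) { b <- as.vector(b_new); break }
    b <- as.vector(b_new)
  }
  eta <- as.vector(X %*% b)
  mu <- 1 / (1 + exp(-eta))
  cov <- solve(t(X) %*% ((mu * (1 - mu)) * X))
  se <- sqrt(diag(cov))
  z_stat <- b[2] / se[2]
  list(coefficient = unname(b[2]), p = unname(2 * pnorm(-abs(z_stat))))
}

meta_groups <- function(meta) {
  setNames(meta$diet_group, meta$subject_id)
}

small_sim <- function(seed = 1, n_per_group = 10, n_mirna = 40,
                      n_nc = 4, planted = list(), ...) {
  generate_cohort(cohort_spec(
    n_per_group = n_per_group, n_mirna = n_mirna, n_nc = n_nc,
    planted_pairs = planted, seed = seed, ...
  ))
}
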