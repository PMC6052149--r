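# Independent brute-force oracles used to validate the fast implementations.
# These deliberately share no code with the package internals.

# Exact two-tailed rank-sum p by full enumeration of case assignments.
brute_force_wilcoxon_p <- function(case, ctrl) {
  vals <- c(case, ctrl)
  n <- length(vals)
  n1 <- length(case)
  rk <- rank(vals)
  ew <- n1 * (n + 1) / 2
  w_obs <- sum(rk[seq_len(n1)])
  sets <- utils::combn(n, n1)
  w_all <- apply(sets, 2, function(ix) sum(rk[ix]))
  mean(abs(w_all - ew) >= abs(w_obs - ew) - 1e-9)
}

# Exact two-tailed permutation p of an arbitrary statistic by enumeration.
brute_force_perm_p <- function(vals, n1, stat) {
  n <- length(vals)
  t_obs <- stat(vals[seq_len(n1)], vals[-seq_len(n1)])
  sets <- utils::combn(n, n1)
  t_all <- apply(sets, 2, function(ix) stat(vals[ix], vals[-ix]))
  mean(abs(t_all) >= abs(t_obs) - 1e-12 * (1 + abs(t_obs)))
}

# Hypergeometric upper-tail P(X >= k) by direct summation of the pmf.
hyper_tail_sum <- function(k, K, N, n) {
  ks <- k:min(K, n)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# Rank-mean quantile normalization by explicit sort-and-average.
brute_force_quantile_normalize <- function(x) {
  ref <- rowMeans(apply(x, 2, sort))
  apply(x, 2, function(col) ref[rank(col, ties.method = "first")])
}

# Closed-form two-sided power of the equal-variance two-sample t-test.
t_test_power <- function(d, n_per_group, alpha = 0.05) {
  df <- 2 * n_per_group - 2
  ncp <- d * sqrt(n_per_group / 2)
  crit <- stats::qt(1 - alpha / 2, df)
  1 - stats::pt(crit, df, ncp) + stats::pt(-crit, df, ncp)
}

# Tiny complete two-group peak table for unit tests.
make_pt <- function(x, n_case = ncol(x) / 2) {
  groups <- rep(c("case", "control"), c(n_case, ncol(x) - n_case))
  if (is.null(rownames(x))) rownames(x) <- sprintf("p%02d", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- sprintf("s%02d", seq_len(ncol(x)))
  peak_table(x, groups)
}
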