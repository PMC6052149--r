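#' Permutation settings for the integrative test
#'
#' @param n_permutations Number of sampled label permutations (`>= 100`);
#'   default 10000. An add-one rule is used for sampled p-values, so they
#'   are never zero.
#' @param seed Integer seed governing the permutation draws.
#' @param exhaustive_threshold When the number of distinct case/control
#'   label assignments `choose(n, n_case)` is at or below this, all
#'   assignments are enumerated and exact permutation p-values are
#'   returned instead of sampled ones. The default (20000) makes designs
#'   up to about 6+6 exhaustive; 10+10 (C(20,10) = 184756) is sampled.
#' @return A list of class `"permutation_config"`.
#' @export
permutation_config <- function(n_permutations = 10000, seed = 1,
                               exhaustive_threshold = 20000) {
  stopifnot(n_permutations >= 100, exhaustive_threshold >= 0)
  structure(list(n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed),
                 exhaustive_threshold = as.numeric(exhaustive_threshold)),
            class = "permutation_config")
}

#' Two-sample Welch t statistic
#'
#' Unequal-variance form; the sign is positive when the case mean exceeds
#' the control mean. Degenerate inputs (zero variance in both groups) give
#' 0 when the means are equal and a signed infinity otherwise, which the
#' permutation machinery handles naturally.
#'
#' @param case,control Numeric vectors of observed values (`>= 2` each).
#' @return The t statistic (a single number).
#' @examples
#' welch_t_stat(c(5, 6, 7), c(1, 2, 3))  # 4.899
#' @export
welch_t_stat <- function(case, control) {
  stopifnot(length(case) >= 2, length(control) >= 2)
  dm <- mean(case) - mean(control)
  se2 <- stats::var(case) / length(case) + stats::var(control) / length(control)
  if (se2 == 0) {
    if (dm == 0) 0 else sign(dm) * Inf
  } else dm / sqrt(se2)
}

#' Log2 median ratio
#'
#' `log2(median(case) / median(control))`; both medians must be positive,
#' which holds for (mTIC-normalized) peak intensities.
#'
#' @inheritParams welch_t_stat
#' @return The log2 ratio of group medians.
#' @examples
#' log2_median_ratio(c(4, 4, 4), c(1, 1, 1))  # 2
#' log2_median_ratio(c(2, 8), c(4, 4))        # log2(5/4)
#' @export
log2_median_ratio <- function(case, control) {
  stopifnot(length(case) >= 1, length(control) >= 1)
  m1 <- stats::median(case)
  m2 <- stats::median(control)
  if (m1 <= 0 || m2 <= 0)
    stop("log2_median_ratio requires positive group medians")
  log2(m1 / m2)
}

#' Two-tailed permutation p-value of an arbitrary statistic
#'
#' Estimates the empirical null of `statistic` by permuting group labels.
#' When the number of distinct label assignments is at or below
#' `config$exhaustive_threshold` every assignment is enumerated and the
#' exact proportion with `|T| >= |T_obs|` is returned; otherwise
#' `config$n_permutations` assignments are sampled and the add-one
#' estimate `(1 + #{|T_b| >= |T_obs|}) / (B + 1)` is returned. Constant
#' data yields p = 1.
#'
#' @param values Numeric vector of observations.
#' @param labels Group label per observation (two distinct labels; the
#'   first factor level plays the role of the case group).
#' @param statistic `function(case, control)` returning a single number.
#' @param config A [permutation_config()].
#' @return The two-tailed permutation p-value in `(0, 1]`.
#' @examples
#' permutation_pvalue(1:6, rep(c("A", "B"), each = 3),
#'                    function(a, b) mean(a) - mean(b))  # 0.1
#' @export
permutation_pvalue <- function(values, labels, statistic,
                               config = permutation_config()) {
  labels <- as.factor(labels)
  if (nlevels(labels) != 2)
    stop("'labels' must contain exactly two groups")
  stopifnot(length(values) == length(labels))
  n <- length(values)
  n1 <- sum(labels == levels(labels)[1])
  safe_stat <- function(a, b) {
    s <- statistic(a, b)
    if (is.nan(s)) 0 else s
  }
  t_obs <- safe_stat(values[labels == levels(labels)[1]],
                     values[labels == levels(labels)[2]])
  set.seed(config$seed)
  pm <- perm_matrix(n, n1, config)
  tb <- apply(pm$idx, 2, function(ix)
    safe_stat(values[ix[seq_len(n1)]], values[ix[-seq_len(n1)]]))
  tail_pvalue(tb, t_obs, pm$exhaustive)
}

#' Two-tailed Wilcoxon rank-sum p-value
#'
#' Exact by enumeration (via the exact rank-sum distribution) when both
#' groups have at most 50 observations and the pooled data is untied;
#' otherwise the normal approximation with tie and continuity correction
#' is used. Fully tied data (all values equal) returns 1.
#'
#' @inheritParams welch_t_stat
#' @param exact `TRUE`/`FALSE` to force a path, or `NULL` (default) for
#'   the size rule above.
#' @return The two-tailed p-value.
#' @export
wilcoxon_ranksum_p <- function(case, control, exact = NULL) {
  stopifnot(length(case) >= 1, length(control) >= 1)
  pooled <- c(case, control)
  if (length(unique(pooled)) == 1) return(1)
  res <- suppressWarnings(
    stats::wilcox.test(case, control, alternative = "two.sided",
                       exact = exact, correct = TRUE))
  p <- res$p.value
  if (!is.finite(p)) 1 else min(p, 1)
}

#' Log2 fold change and pooled standard deviation
#'
#' `fc_log2 = log2(mean(case) / mean(control))` on (normalized) linear
#' intensities, and the pooled standard deviation of the log2 intensities
#' across both groups — the two effect-size columns of the result table.
#'
#' @inheritParams welch_t_stat
#' @return A list with `fc_log2` and `sd`.
#' @examples
#' fold_change_sd(c(1, 4), c(2, 8))  # fc -1, pooled sd of log2 values
#' @export
fold_change_sd <- function(case, control) {
  stopifnot(length(case) >= 2, length(control) >= 2)
  m1 <- mean(case)
  m2 <- mean(control)
  if (m1 <= 0 || m2 <= 0)
    stop("fold_change_sd requires positive group means")
  l1 <- log2(case)
  l2 <- log2(control)
  n1 <- length(case)
  n2 <- length(control)
  pooled_var <- ((n1 - 1) * stats::var(l1) + (n2 - 1) * stats::var(l2)) /
    (n1 + n2 - 2)
  list(fc_log2 = log2(m1 / m2), sd = sqrt(pooled_var))
}

# ---- internal permutation machinery -------------------------------------

# Full label-assignment index matrix (n x B). Each column is an ordering of
# 1..n whose first n1 entries form the case set. Exhaustive enumeration via
# combn when the number of distinct case sets is small enough; otherwise B
# uniform draws (caller is responsible for seeding).
perm_matrix <- function(n, n1, config) {
  n_assign <- choose(n, n1)
  if (n_assign <= config$exhaustive_threshold) {
    cs <- utils::combn(n, n1)
    all_idx <- seq_len(n)
    idx <- apply(cs, 2, function(ci) c(ci, all_idx[-ci]))
    list(idx = idx, exhaustive = TRUE)
  } else {
    B <- config$n_permutations
    idx <- vapply(seq_len(B), function(b) sample.int(n), integer(n))
    list(idx = idx, exhaustive = FALSE)
  }
}

# Two-tailed tail probability of obs within the permutation stats; add-one
# for sampled draws, plain proportion for exhaustive enumeration. A small
# relative tolerance absorbs floating-point noise in analytically tied
# statistics.
tail_pvalue <- function(stats_b, obs, exhaustive) {
  if (is.nan(obs)) obs <- 0
  stats_b[is.nan(stats_b)] <- 0
  tol <- if (is.finite(obs)) 1e-12 * (1 + abs(obs)) else 0
  cnt <- sum(abs(stats_b) >= abs(obs) - tol)
  B <- length(stats_b)
  if (exhaustive) cnt / B else (1 + cnt) / (B + 1)
}

# Vectorized Welch t over permutation columns: case/ctrl are n1 x B and
# n2 x B value matrices.
welch_t_cols <- function(case, ctrl) {
  n1 <- nrow(case)
  n2 <- nrow(ctrl)
  m1 <- colMeans(case)
  m2 <- colMeans(ctrl)
  v1 <- pmax(0, (colSums(case^2) - n1 * m1^2) / (n1 - 1))
  v2 <- pmax(0, (colSums(ctrl^2) - n2 * m2^2) / (n2 - 1))
  dm <- m1 - m2
  se <- sqrt(v1 / n1 + v2 / n2)
  t <- dm / se
  zero <- se == 0
  if (any(zero)) t[zero] <- ifelse(dm[zero] == 0, 0, sign(dm[zero]) * Inf)
  t
}

# Column medians of a small matrix via a single order() call (sort within
# columns, then pick the middle order statistics).
col_medians <- function(m) {
  n <- nrow(m)
  sm <- matrix(m[order(col(m), m)], n)
  if (n %% 2L == 1L) sm[(n + 1L) %/% 2L, ]
  else (sm[n %/% 2L, ] + sm[n %/% 2L + 1L, ]) / 2
}
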