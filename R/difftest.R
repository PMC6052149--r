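#' Stouffer combination of three two-tailed p-values
#'
#' Converts each two-tailed p to a signed z,
#' `z_i = sign_i * qnorm(1 - p_i / 2)`, sums with equal weights and
#' renormalizes by `sqrt(3)`, then maps back to a two-tailed p:
#' `p = 2 * (1 - pnorm(|z_combined|))`, clamped into `(0, 1]`. Signs come
#' from each component test's own effect direction, so concordant tests
#' reinforce and discordant tests cancel.
#'
#' This is the closed-form combination; within [differential_analysis()]
#' the null distribution of the combined z is additionally estimated from
#' the same permutations (see the package vignette), because the three
#' components are computed on the same data and are strongly correlated.
#'
#' @param p_t,p_lmr,p_wilcoxon Two-tailed p-values in `(0, 1]` (vectors of
#'   equal length are combined elementwise). Zero values are clamped to
#'   the smallest positive double with a warning — a permutation p under
#'   the add-one rule can never be 0.
#' @param signs Effect-direction signs for the three components: a
#'   length-3 vector `(sign_t, sign_lmr, sign_wilcoxon)`, or an `n x 3`
#'   matrix for vector input. A sign of 0 (no direction) contributes z = 0.
#' @return A list with `z_combined` and `p_adjusted`.
#' @examples
#' stouffer_combine(0.05, 0.05, 0.05)                 # z = 3.395
#' stouffer_combine(0.05, 0.05, 0.05, c(1, 1, -1))    # z = 1.132
#' @export
stouffer_combine <- function(p_t, p_lmr, p_wilcoxon, signs = c(1, 1, 1)) {
  pm <- cbind(p_t, p_lmr, p_wilcoxon)
  if (any(pm <= 0)) {
    warning("p-value(s) of 0 clamped to the smallest positive double")
    pm[pm <= 0] <- .Machine$double.xmin
  }
  if (any(pm > 1)) stop("p-values must lie in (0, 1]")
  if (is.matrix(signs) || length(signs) == 3) {
    sm <- if (is.matrix(signs)) signs else
      matrix(signs, nrow(pm), 3, byrow = TRUE)
  } else stop("'signs' must be length 3 or an n x 3 matrix")
  z <- sign(sm) * stats::qnorm(1 - pm / 2)
  z_combined <- rowSums(z) / sqrt(3)
  p_adjusted <- pmin(1, pmax(2 * stats::pnorm(-abs(z_combined)),
                             .Machine$double.xmin))
  list(z_combined = unname(z_combined), p_adjusted = unname(p_adjusted))
}

#' Storey q-values
#'
#' Single-lambda Storey estimator of the false discovery rate:
#' `pi0 = min(1, #\{p > lambda\} / ((1 - lambda) * m))` with
#' `lambda = 0.5`, floored at `1/m`; the q-value of the i-th smallest p is
#' `min_{j >= i} pi0 * m * p_(j) / j`, capped at 1. With `pi0 = 1` this
#' reduces exactly to Benjamini-Hochberg adjusted p-values.
#'
#' @param p_values Vector of p-values in `(0, 1]`.
#' @param lambda Tuning point for the pi0 estimate (default 0.5).
#' @param pi0 Optional fixed pi0 overriding the estimate (still floored
#'   at `1/m`).
#' @return Q-values in input order.
#' @examples
#' storey_qvalues(c(0.2, 0.4, 0.6, 0.8))  # all 0.8
#' @export
storey_qvalues <- function(p_values, lambda = 0.5, pi0 = NULL) {
  m <- length(p_values)
  stopifnot(m >= 1, all(p_values > 0), all(p_values <= 1),
            lambda > 0, lambda < 1)
  if (is.null(pi0))
    pi0 <- min(1, sum(p_values > lambda) / ((1 - lambda) * m))
  pi0 <- max(pi0, 1 / m)
  o <- order(p_values)
  q_sorted <- pi0 * m * p_values[o] / seq_len(m)
  q_sorted <- pmin(1, rev(cummin(rev(q_sorted))))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

#' Integrative differential analysis of a peak table
#'
#' For every testable peak (at least two observed values per group), three
#' statistics are computed on the observed values: the Welch t statistic,
#' the log2 median ratio and the (centered) Wilcoxon rank sum. A single
#' set of label permutations per peak provides the empirical null of all
#' three; each statistic's two-tailed permutation p is converted to a
#' signed z and the three are combined by Stouffer's rule. Because the
#' components are computed on the same data, the combined z is then
#' referred to its own permutation null: `p_adjusted` is the two-tailed
#' empirical p of the combined z, which keeps the combined test calibrated
#' (see the vignette). Storey q-values are computed across all tested
#' peaks from `p_adjusted`.
#'
#' Missing values are omitted pairwise: every test runs on the observed
#' values only, and permutations permute the observed-value labels. Peaks
#' with fewer than two observed values in either group are reported as
#' untestable with a reason code, never silently dropped.
#'
#' @param table A [peak_table], already detection-filtered and
#'   mTIC-normalized.
#' @param config A [permutation_config()]; per-peak permutation streams
#'   are derived deterministically from its seed.
#' @param fdr_threshold Significance threshold on the q-value used in the
#'   summary report (default 0.1).
#' @return A data frame (one row per peak, sorted by q-value then
#'   `p_adjusted`, untestable peaks last) with columns `feature_id`,
#'   `n_case_obs`, `n_control_obs`, `p_t`, `p_lmr`, `p_wilcoxon`
#'   (exact/approximate rank-sum p), `z_combined`, `p_adjusted`,
#'   `q_value`, `fc_log2`, `sd`, `testable`, `reason`. A summary list
#'   (funnel counts and the number of peaks below `fdr_threshold`) is
#'   attached as attribute `"summary"`.
#' @export
differential_analysis <- function(table, config = permutation_config(),
                                  fdr_threshold = 0.1) {
  stopifnot(inherits(table, "peak_table"),
            inherits(config, "permutation_config"))
  x <- table$intensities
  is_case <- table$groups == "case"
  m <- nrow(x)
  if (m == 0) stop("empty peak table")

  res <- data.frame(feature_id = rownames(x),
                    n_case_obs = NA_integer_, n_control_obs = NA_integer_,
                    p_t = NA_real_, p_lmr = NA_real_, p_wilcoxon = NA_real_,
                    z_combined = NA_real_, p_adjusted = NA_real_,
                    q_value = NA_real_, fc_log2 = NA_real_, sd = NA_real_,
                    testable = FALSE, reason = NA_character_,
                    stringsAsFactors = FALSE)

  for (i in seq_len(m)) {
    case <- x[i, is_case]
    ctrl <- x[i, !is_case]
    case <- case[!is.na(case)]
    ctrl <- ctrl[!is.na(ctrl)]
    res$n_case_obs[i] <- length(case)
    res$n_control_obs[i] <- length(ctrl)
    if (length(case) < 2 || length(ctrl) < 2) {
      res$reason[i] <- "insufficient_observations"
      next
    }
    set.seed(derive_seed(config$seed, i))
    eng <- diff_test_engine(case, ctrl, config)
    fc <- fold_change_sd(case, ctrl)
    res$p_t[i] <- eng$p_t
    res$p_lmr[i] <- eng$p_lmr
    res$p_wilcoxon[i] <- wilcoxon_ranksum_p(case, ctrl)
    res$z_combined[i] <- eng$z_combined
    res$p_adjusted[i] <- eng$p_adjusted
    res$fc_log2[i] <- fc$fc_log2
    res$sd[i] <- fc$sd
    res$testable[i] <- TRUE
  }

  if (!any(res$testable)) stop("no testable peaks")
  res$q_value[res$testable] <- storey_qvalues(res$p_adjusted[res$testable])

  o <- order(!res$testable, res$q_value, res$p_adjusted)
  res <- res[o, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "summary") <- list(
    n_input = m,
    n_tested = sum(res$testable),
    n_untestable = sum(!res$testable),
    fdr_threshold = fdr_threshold,
    n_significant = sum(res$q_value < fdr_threshold, na.rm = TRUE))
  res
}

#' Write a differential-analysis result table as TSV
#'
#' @param results Data frame from [differential_analysis()] (optionally
#'   annotated).
#' @param path Output path.
#' @param header_lines Optional `#` comment lines (seed, config hash,
#'   version) written above the table.
#' @return `path`, invisibly.
#' @export
write_diff_results <- function(results, path, header_lines = NULL) {
  write_tsv_commented(results, path, header_lines)
}

# ---- internal -----------------------------------------------------------

# Deterministic per-feature sub-seed below 2^31.
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + 1009 * as.numeric(i)) %% 2147483647)
}

# Integrative test for one feature. One permutation set drives all three
# component statistics; component p-values for the permuted data sets are
# rank-based within the same set, so the combined z has a coherent
# empirical null. Caller seeds the RNG.
diff_test_engine <- function(case, ctrl, config) {
  vals <- c(case, ctrl)
  n1 <- length(case)
  n2 <- length(ctrl)
  n <- n1 + n2
  pm <- perm_matrix(n, n1, config)
  B <- ncol(pm$idx)

  vm <- matrix(vals[pm$idx], nrow = n)
  cs <- vm[seq_len(n1), , drop = FALSE]
  ct <- vm[n1 + seq_len(n2), , drop = FALSE]
  tb <- welch_t_cols(cs, ct)
  lb <- log2(col_medians(cs) / col_medians(ct))
  rk <- rank(vals)
  rm_ <- matrix(rk[pm$idx], nrow = n)
  wb <- colSums(rm_[seq_len(n1), , drop = FALSE]) - n1 * (n + 1) / 2

  t_obs <- welch_t_stat(case, ctrl)
  l_obs <- log2_median_ratio(case, ctrl)
  w_obs <- sum(rk[seq_len(n1)]) - n1 * (n + 1) / 2

  p_t <- tail_pvalue(tb, t_obs, pm$exhaustive)
  p_l <- tail_pvalue(lb, l_obs, pm$exhaustive)
  p_w <- tail_pvalue(wb, w_obs, pm$exhaustive)

  # rank-based two-tailed p of each permuted statistic within the set
  rank_p <- function(s) {
    s[is.nan(s)] <- 0
    (B + 1 - rank(abs(s), ties.method = "min")) / B
  }
  z_of <- function(p, s) {
    s[is.nan(s)] <- 0
    sign(s) * stats::qnorm(1 - p / 2)
  }
  zb <- (z_of(rank_p(tb), tb) + z_of(rank_p(lb), lb) +
           z_of(rank_p(wb), wb)) / sqrt(3)
  z_obs <- (z_of(p_t, t_obs) + z_of(p_l, l_obs) + z_of(p_w, w_obs)) / sqrt(3)

  list(p_t = p_t, p_lmr = p_l, p_wilcoxon_perm = p_w,
       z_combined = z_obs,
       p_adjusted = tail_pvalue(zb, z_obs, pm$exhaustive))
}
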