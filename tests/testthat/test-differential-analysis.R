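cfg_small <- function(seed = 1) permutation_config(500, seed = seed)

test_that("result table satisfies the declared invariants", {
  sim <- generate_voc_study(voc_sim_params(n_peaks = 30,
                                           frac_differential = 0.2, seed = 2))
  pt <- mtic_normalize(detection_filter(sim$table))
  res <- differential_analysis(pt, cfg_small())

  ok <- res$testable
  expect_true(all(res$p_t[ok] > 0 & res$p_t[ok] <= 1))
  expect_true(all(res$p_lmr[ok] > 0 & res$p_lmr[ok] <= 1))
  expect_true(all(res$p_wilcoxon[ok] > 0 & res$p_wilcoxon[ok] <= 1))
  expect_true(all(res$p_adjusted[ok] > 0 & res$p_adjusted[ok] <= 1))
  expect_true(all(res$q_value[ok] >= 0 & res$q_value[ok] <= 1))
  # q monotone when ordered by p_adjusted
  o <- order(res$p_adjusted[ok])
  expect_true(all(diff(res$q_value[ok][o]) >= -1e-14))

  s <- attr(res, "summary")
  expect_equal(s$n_tested + s$n_untestable, s$n_input)
  expect_equal(s$n_significant, sum(res$q_value < s$fdr_threshold, na.rm = TRUE))
})

test_that("analysis is deterministic given the configuration seed", {
  sim <- generate_voc_study(voc_sim_params(n_peaks = 20, seed = 6))
  pt <- mtic_normalize(detection_filter(sim$table))
  expect_identical(differential_analysis(pt, cfg_small(9)),
                   differential_analysis(pt, cfg_small(9)))
})

test_that("relabeling case and control flips z and preserves the combined p", {
  # small exhaustive design so the permutation null is exact and symmetric
  set.seed(51)
  x <- matrix(rlnorm(10 * 8, 12, 1), 10, 8)
  rownames(x) <- sprintf("pk%02d", 1:10)
  colnames(x) <- sprintf("s%d", 1:8)
  cfg <- permutation_config(100, seed = 1)  # C(8,4)=70 -> exhaustive
  res_a <- differential_analysis(peak_table(x, rep(c("case", "control"), each = 4)), cfg)
  res_b <- differential_analysis(peak_table(x, rep(c("control", "case"), each = 4)), cfg)
  res_b <- res_b[match(res_a$feature_id, res_b$feature_id), ]
  expect_equal(res_a$z_combined, -res_b$z_combined, tolerance = 1e-9)
  expect_equal(res_a$p_adjusted, res_b$p_adjusted, tolerance = 1e-12)
  expect_equal(res_a$fc_log2, -res_b$fc_log2, tolerance = 1e-12)
})

test_that("component permutation p agrees with the standalone operation", {
  # dual route: vectorized engine vs the generic per-statistic operation,
  # both exhaustive hence exactly equal
  set.seed(53)
  x <- matrix(rlnorm(5 * 10, 12, 1), 5, 10)
  rownames(x) <- sprintf("pk%d", 1:5)
  colnames(x) <- sprintf("s%d", 1:10)
  pt <- peak_table(x, rep(c("case", "control"), each = 5))
  res <- differential_analysis(pt, permutation_config(100, seed = 1))
  for (i in 1:5) {
    vals <- x[res$feature_id[i], ]
    p_t <- permutation_pvalue(vals, pt$groups, welch_t_stat)
    p_l <- permutation_pvalue(vals, pt$groups, log2_median_ratio)
    expect_equal(res$p_t[i], p_t, tolerance = 1e-12)
    expect_equal(res$p_lmr[i], p_l, tolerance = 1e-12)
  }
})

test_that("untestable peaks are reported with a reason, never dropped", {
  set.seed(57)
  x <- matrix(rlnorm(3 * 8, 10, 1), 3, 8)
  x[2, 1:3] <- NA  # one observed case value only
  rownames(x) <- c("ok1", "sparse", "ok2")
  colnames(x) <- sprintf("s%d", 1:8)
  res <- differential_analysis(peak_table(x, rep(c("case", "control"), each = 4)),
                               cfg_small())
  expect_equal(nrow(res), 3)
  row <- res[res$feature_id == "sparse", ]
  expect_false(row$testable)
  expect_equal(row$reason, "insufficient_observations")
  expect_true(is.na(row$p_adjusted))
  # q-values computed over the 2 testable peaks only
  expect_equal(sum(!is.na(res$q_value)), 2)
})

test_that("a single-feature table yields q equal to the combined p", {
  set.seed(59)
  x <- matrix(c(rlnorm(4, 14, 0.3), rlnorm(4, 12, 0.3)), 1)
  rownames(x) <- "solo"
  colnames(x) <- sprintf("s%d", 1:8)
  res <- differential_analysis(peak_table(x, rep(c("case", "control"), each = 4)),
                               cfg_small())
  expect_equal(res$q_value, res$p_adjusted)
})
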