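test_that("VOC generator is deterministic and honours the planted design", {
  p <- voc_sim_params(n_peaks = 100, frac_differential = 0.1,
                      effect_log2 = -1.467, sigma_log2 = 1.381, seed = 1)
  sim1 <- generate_voc_study(p)
  sim2 <- generate_voc_study(p)
  expect_identical(sim1, sim2)

  expect_equal(sum(sim1$truth$is_differential), 10)
  expect_true(all(sim1$truth$effect_log2[sim1$truth$is_differential] == -1.467))
  expect_true(all(sim1$truth$effect_log2[!sim1$truth$is_differential] == 0))

  null_sim <- generate_voc_study(voc_sim_params(n_peaks = 40,
                                                frac_differential = 0, seed = 3))
  expect_false(any(null_sim$truth$is_differential))
  expect_true(all(null_sim$table$intensities > 0, na.rm = TRUE))
})

test_that("truth count matches round(frac * n_peaks) across designs", {
  for (frac in c(0, 0.05, 0.13, 0.5)) {
    sim <- generate_voc_study(voc_sim_params(n_peaks = 77,
                                             frac_differential = frac,
                                             seed = 11))
    expect_equal(sum(sim$truth$is_differential), round(frac * 77))
  }
  expect_error(voc_sim_params(n_peaks = 10, frac_differential = 1),
               "null peaks")
})

test_that("raising the censoring quantile only adds missing cells", {
  miss <- lapply(c(0, 0.1, 0.25, 0.4), function(q) {
    sim <- generate_voc_study(voc_sim_params(n_peaks = 60, lod_quantile = q,
                                             missing_rate = 0.05, seed = 5))
    is.na(sim$table$intensities)
  })
  for (i in seq_len(length(miss) - 1)) {
    expect_true(all(miss[[i + 1]][miss[[i]]]))  # superset of missing cells
    expect_gte(sum(miss[[i + 1]]), sum(miss[[i]]))
  }
})

test_that("per-peak log2 SD approaches sigma_log2 with missingness disabled", {
  sim <- generate_voc_study(voc_sim_params(
    n_case = 250, n_control = 250, n_peaks = 60, frac_differential = 0,
    sigma_log2 = 1.381, lod_quantile = 0, missing_rate = 0,
    scale_jitter = 0.01, seed = 8))
  sds <- apply(log2(sim$table$intensities), 1, sd)
  expect_lt(abs(mean(sds) - 1.381) / 1.381, 0.1)
})

test_that("differential peaks realize the planted fold change on average", {
  sim <- generate_voc_study(voc_sim_params(
    n_case = 400, n_control = 400, n_peaks = 50, frac_differential = 0.5,
    effect_log2 = -1.467, lod_quantile = 0, missing_rate = 0,
    scale_jitter = 0.01, seed = 13))
  x <- sim$table$intensities
  lfc <- log2(rowMeans(x[, 1:400]) / rowMeans(x[, 401:800]))
  planted <- sim$truth$is_differential
  # lognormal mean ratio equals 2^effect; sampling noise at n=400 is small
  expect_lt(abs(mean(lfc[planted]) - (-1.467)), 0.25)
  expect_lt(abs(mean(lfc[!planted])), 0.25)
})

test_that("expression generator: determinism, null design, realized fold change", {
  sim1 <- generate_expression_study(n_probes = 200, seed = 4)
  sim2 <- generate_expression_study(n_probes = 200, seed = 4)
  expect_identical(sim1, sim2)

  null_sim <- generate_expression_study(n_probes = 100, frac_de = 0, seed = 2)
  expect_false(any(null_sim$truth$is_differential))

  # law of large numbers: geometric-mean fold change of DE probes -> 1.5
  sim <- generate_expression_study(n_probes = 1000, n_per_condition = 3,
                                   conditions = c("A", "B"), frac_de = 1,
                                   effect_log2 = log2(1.5), sigma = 0.25,
                                   de_condition = "B", seed = 9)
  dm <- rowMeans(sim$matrix[, sim$condition == "B"]) -
    rowMeans(sim$matrix[, sim$condition == "A"])
  expect_lt(abs(2^mean(dm) - 1.5), 0.02)

  expect_error(generate_expression_study(n_per_condition = 1),
               "n_per_condition")
})

test_that("bundled fixtures resolve the reference CAS-to-KEGG mappings", {
  fx <- bundled_fixtures()
  lookup <- function(cas) fx$cas_kegg$kegg_id[fx$cas_kegg$cas_rn == cas]
  expect_equal(lookup("89-78-1"), "C00400")
  expect_equal(lookup("21634-04-4"), "C11344")
  expect_equal(lookup("107-87-9"), "C01949")
  expect_length(lookup("5779-95-3"), 0)
  expect_true(all(c("term_id", "gene_id") %in% names(fx$go_terms)))
  expect_true(all(validate_cas(c("89-78-1", "107-87-9", "67-64-1",
                                 "64-17-5", "50-00-0"))))
})
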