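test_that("abundance filter keeps probes above the grand mean", {
  x <- rbind(a = rep(4, 4), b = rep(8, 4))
  expect_equal(abundance_filter(x), "b")
  y <- matrix(5, 3, 4, dimnames = list(c("a", "b", "c"), NULL))
  expect_length(abundance_filter(y), 0)   # strict inequality

  set.seed(71)
  z <- matrix(rnorm(10000 * 4, 8, 2), 10000, 4,
              dimnames = list(sprintf("p%05d", 1:10000), NULL))
  frac <- length(abundance_filter(z)) / 10000
  expect_lt(abs(frac - 0.5), 0.05)        # symmetric distribution
})

test_that("vectorized Welch test matches stats::t.test per probe", {
  set.seed(73)
  x <- matrix(rnorm(20 * 6, 8, 1), 20, 6,
              dimnames = list(sprintf("p%02d", 1:20), sprintf("s%d", 1:6)))
  cond <- rep(c("C", "LPS"), each = 3)
  deg <- welch_deg(x, cond, "C", "LPS", abundance = rownames(x))
  for (i in 1:20) {
    tt <- t.test(x[i, 1:3], x[i, 4:6])
    expect_equal(deg$p_value[i], tt$p.value, tolerance = 1e-12)
    expect_equal(deg$df[i], unname(tt$parameter), tolerance = 1e-12)
  }
})

test_that("Welch DEG calls respect thresholds, symmetry and degeneracy", {
  set.seed(79)
  x <- matrix(rnorm(50 * 6, 8, 0.25), 50, 6,
              dimnames = list(sprintf("p%02d", 1:50), sprintf("s%d", 1:6)))
  cond <- rep(c("A", "B"), each = 3)
  # plant a probe exactly at the fold-change boundary (delta = log2 1.5)
  x[1, ] <- rep(c(8, 8 - log2(1.5)), each = 3)
  deg <- welch_deg(x, cond, "A", "B", abundance = rownames(x))
  expect_identical(deg$fc_linear[1], 1.5)
  expect_true(deg$is_deg[1])              # ">= 1.5" is inclusive

  # symmetry: swapping conditions preserves p, inverts direction
  rev_deg <- welch_deg(x, cond, "B", "A", abundance = rownames(x))
  expect_equal(deg$p_value, rev_deg$p_value, tolerance = 1e-12)
  expect_equal(deg$direction, -rev_deg$direction)

  # identical groups -> p = 1, no call
  y <- matrix(c(5, 6, 7, 5, 6, 7), 1,
              dimnames = list("flat", sprintf("s%d", 1:6)))
  d0 <- welch_deg(y, cond, "A", "B", abundance = rownames(y))
  expect_equal(d0$p_value, 1)
  expect_false(d0$is_deg)

  # DEG count is monotone non-increasing in the FC threshold
  counts <- sapply(c(1, 1.2, 1.5, 2), function(fc)
    sum(welch_deg(x, cond, "A", "B", fc_threshold = fc,
                  abundance = rownames(x))$is_deg))
  expect_true(all(diff(counts) <= 0))
})

test_that("hypergeometric enrichment matches tail summation and Fisher", {
  term_table <- data.frame(term_id = "T1",
                           gene_id = sprintf("g%03d", 1:10))
  background <- sprintf("g%03d", 1:100)
  degs <- sprintf("g%03d", c(1:5, 51:55))      # overlap 5 with the term
  res <- gobp_enrichment(degs, background, term_table)
  p_oracle <- hyper_tail_sum(5, 10, 100, 10)
  expect_equal(res$p_value, p_oracle, tolerance = 1e-12)
  fisher_p <- fisher.test(matrix(c(5, 5, 5, 85), 2),
                          alternative = "greater")$p.value
  expect_equal(res$p_value, fisher_p, tolerance = 1e-12)
  expect_equal(res$n_deg_in_term, 5)
  expect_true(res$selected)
})

test_that("terms below the minimum DEG overlap are never selected", {
  term_table <- data.frame(term_id = c("tiny", "tiny", "big"),
                           gene_id = c("g001", "g002", "g001"))
  term_table <- rbind(term_table,
                      data.frame(term_id = "big", gene_id = sprintf("g%03d", 2:10)))
  background <- sprintf("g%03d", 1:40)
  degs <- sprintf("g%03d", 1:2)
  res <- gobp_enrichment(degs, background, term_table)
  tiny <- res[res$term_id == "tiny", ]
  expect_lt(tiny$p_value, 0.05)
  expect_false(tiny$selected)             # overlap 2 < 3
})

test_that("enrichment handles the extreme and empty cases", {
  term_table <- data.frame(term_id = "all", gene_id = sprintf("g%03d", 1:5))
  background <- sprintf("g%03d", 1:30)
  degs <- sprintf("g%03d", 1:5)           # term identical to DEG set
  res <- gobp_enrichment(degs, background, term_table)
  expect_equal(res$n_deg_in_term, 5)
  expect_equal(res$p_value, 1 / choose(30, 5), tolerance = 1e-12)

  expect_warning(empty <- gobp_enrichment(character(0), background, term_table),
                 "empty")
  expect_equal(nrow(empty), 0)
  expect_error(gobp_enrichment("not_there", background, term_table), "subset")
})
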