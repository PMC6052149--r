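#' Parameters for the VOC study simulator
#'
#' Defaults emulate the urinary VOC study design this package targets:
#' 10 case vs 10 control urines, 113 detected peaks, log-normal peak
#' intensities, left-censored plus random missingness, and a minority of
#' peaks carrying a planted log2 effect of the magnitude seen for the
#' strongest reported urinary compound (log2 fold change -1.467 with a
#' log2 standard deviation of 1.381).
#'
#' @param n_case,n_control Samples per group (each `>= 2`).
#' @param n_peaks Number of peaks.
#' @param frac_differential Fraction of peaks carrying the planted effect,
#'   in `[0, 1)`. `round(frac_differential * n_peaks)` peaks are made
#'   differential; at least one null peak must remain.
#' @param effect_log2 Signed planted log2 fold change (case vs control);
#'   negative means lower in cases.
#' @param sigma_log2 Per-peak standard deviation of log2 intensity (`> 0`).
#' @param lod_quantile Left-censoring fraction in `[0, 1)`: within each
#'   peak, intensities below the peak's `lod_quantile` quantile are
#'   censored to missing (limit-of-detection behaviour).
#' @param missing_rate Additional independent random dropout in `[0, 1)`.
#' @param scale_jitter Positive per-sample multiplicative scale spread:
#'   scale factors are log-uniform on
#'   `[1/(1 + scale_jitter), 1 + scale_jitter]`, so mTIC normalization is
#'   non-trivial.
#' @param seed Integer seed; the generator is fully reproducible from it.
#' @return A validated list of class `"voc_sim_params"`.
#' @seealso [generate_voc_study()]
#' @export
voc_sim_params <- function(n_case = 10, n_control = 10, n_peaks = 113,
                           frac_differential = 0.1, effect_log2 = -1.467,
                           sigma_log2 = 1.381, lod_quantile = 0.2,
                           missing_rate = 0.05, scale_jitter = 0.25,
                           seed = 1) {
  stopifnot(n_case >= 2, n_control >= 2, n_peaks >= 1,
            frac_differential >= 0, frac_differential <= 1,
            sigma_log2 > 0,
            lod_quantile >= 0, lod_quantile < 1,
            missing_rate >= 0, missing_rate < 1,
            scale_jitter > 0)
  n_diff <- round(frac_differential * n_peaks)
  if (n_diff > 0 && n_diff >= n_peaks)
    stop("frac_differential leaves no null peaks; FDR evaluation would be impossible")
  structure(list(n_case = as.integer(n_case), n_control = as.integer(n_control),
                 n_peaks = as.integer(n_peaks),
                 frac_differential = frac_differential,
                 effect_log2 = effect_log2, sigma_log2 = sigma_log2,
                 lod_quantile = lod_quantile, missing_rate = missing_rate,
                 scale_jitter = scale_jitter, seed = as.integer(seed)),
            class = "voc_sim_params")
}

#' Simulate a two-group VOC peak table with known ground truth
#'
#' Generative model: per-peak log2 mean intensities are drawn uniformly on
#' `[10, 20]` so peaks span roughly three orders of magnitude, as in
#' untargeted GC-MS practice; log2 intensities are Normal(mu_j, sigma_log2)
#' per peak. Differential peaks get `effect_log2` added to the case-group
#' mean. Each sample's linear intensities are multiplied by a private
#' scale factor (log-uniform, spread `scale_jitter`). Missingness arises
#' from (i) per-peak left-censoring at the peak's `lod_quantile` quantile
#' and (ii) independent random dropout at `missing_rate`. All random draws
#' happen in a fixed order before censoring is applied, so raising
#' `lod_quantile` under the same seed only ever adds missing cells.
#'
#' @param params A [voc_sim_params()] object.
#' @return A list with elements `table` (a [peak_table]) and `truth`
#'   (data frame `feature_id`, `is_differential`, `effect_log2`; the
#'   effect is 0 for null peaks).
#' @examples
#' sim <- generate_voc_study(voc_sim_params(n_peaks = 50, seed = 7))
#' sim$table
#' table(sim$truth$is_differential)
#' @export
generate_voc_study <- function(params) {
  stopifnot(inherits(params, "voc_sim_params"))
  p <- params
  n <- p$n_case + p$n_control
  set.seed(p$seed)

  # fixed draw order: means, differential assignment, noise, scales, dropout
  mu <- stats::runif(p$n_peaks, 10, 20)
  n_diff <- round(p$frac_differential * p$n_peaks)
  diff_idx <- if (n_diff > 0) sort(sample.int(p$n_peaks, n_diff)) else integer(0)
  effect <- numeric(p$n_peaks)
  effect[diff_idx] <- p$effect_log2
  noise <- matrix(stats::rnorm(p$n_peaks * n, sd = p$sigma_log2), p$n_peaks, n)
  lj <- log(1 + p$scale_jitter)
  scales <- exp(stats::runif(n, -lj, lj))
  drop_u <- matrix(stats::runif(p$n_peaks * n), p$n_peaks, n)

  log2x <- mu + noise
  case_cols <- seq_len(p$n_case)
  log2x[, case_cols] <- log2x[, case_cols] + effect
  x <- sweep(2^log2x, 2, scales, `*`)

  feature_ids <- sprintf("peak_%03d", seq_len(p$n_peaks))
  sample_ids <- c(sprintf("case_%02d", seq_len(p$n_case)),
                  sprintf("ctrl_%02d", seq_len(p$n_control)))
  dimnames(x) <- list(feature_ids, sample_ids)

  miss <- drop_u < p$missing_rate
  if (p$lod_quantile > 0) {
    thr <- apply(x, 1, stats::quantile, probs = p$lod_quantile, names = FALSE)
    miss <- miss | (x < thr)
  }
  x[miss] <- NA_real_

  groups <- rep(c("case", "control"), c(p$n_case, p$n_control))
  list(table = peak_table(x, stats::setNames(groups, sample_ids)),
       truth = data.frame(feature_id = feature_ids,
                          is_differential = seq_len(p$n_peaks) %in% diff_idx,
                          effect_log2 = effect))
}

#' Simulate a multi-condition log2 expression matrix
#'
#' Emulates a small-replicate microarray design (for example control,
#' menthol, LPS at n = 3 arrays each). Per-probe baseline log2 means are
#' uniform on `[4, 12]`; values are Normal(mean, sigma). Differentially
#' expressed probes have `effect_log2` added to their mean in
#' `de_condition` only, so any contrast involving that condition carries
#' the planted effect.
#'
#' @param n_probes Number of probes.
#' @param n_per_condition Replicates per condition (`>= 2`; a Welch test
#'   is undefined below that).
#' @param conditions Character vector of condition labels (`>= 2`).
#' @param frac_de Fraction of probes differentially expressed in
#'   `de_condition`.
#' @param effect_log2 Signed planted log2 shift.
#' @param sigma Per-probe log2 standard deviation.
#' @param de_condition Condition receiving the shift; defaults to the last
#'   label in `conditions`.
#' @param seed Integer seed.
#' @return A list with `matrix` (probes x samples log2 values),
#'   `condition` (named factor) and `truth` (data frame `feature_id`,
#'   `is_differential`, `effect_log2`).
#' @export
generate_expression_study <- function(n_probes = 1000, n_per_condition = 3,
                                      conditions = c("C", "M", "LPS"),
                                      frac_de = 0.05,
                                      effect_log2 = log2(1.5) * 2,
                                      sigma = 0.25,
                                      de_condition = conditions[length(conditions)],
                                      seed = 1) {
  stopifnot(length(conditions) >= 2, n_per_condition >= 2,
            de_condition %in% conditions,
            frac_de >= 0, frac_de <= 1, sigma > 0)
  set.seed(as.integer(seed))
  k <- length(conditions)
  n <- k * n_per_condition
  mu <- stats::runif(n_probes, 4, 12)
  n_de <- round(frac_de * n_probes)
  de_idx <- if (n_de > 0) sort(sample.int(n_probes, n_de)) else integer(0)
  effect <- numeric(n_probes)
  effect[de_idx] <- effect_log2
  cond <- factor(rep(conditions, each = n_per_condition), levels = conditions)
  x <- mu + matrix(stats::rnorm(n_probes * n, sd = sigma), n_probes, n)
  x[, cond == de_condition] <- x[, cond == de_condition] + effect
  probe_ids <- sprintf("probe_%05d", seq_len(n_probes))
  sample_ids <- paste0(rep(conditions, each = n_per_condition), "_",
                       rep(seq_len(n_per_condition), k))
  dimnames(x) <- list(probe_ids, sample_ids)
  names(cond) <- sample_ids
  list(matrix = x, condition = cond,
       truth = data.frame(feature_id = probe_ids,
                          is_differential = seq_len(n_probes) %in% de_idx,
                          effect_log2 = effect))
}

#' Bundled annotation and term fixtures
#'
#' Small plain-text tables shipped with the package so the annotation and
#' enrichment stages run without any network access: a CAS registry number
#' to KEGG compound id mapping (containing the urinary compounds reported
#' by the study this package models, e.g. menthol 89-78-1 -> C00400), an
#' illustrative compound-to-pathway table (synthetic, not a KEGG release),
#' and a small synthetic GO-term-to-gene table for enrichment tests.
#'
#' @return A list with data frames `cas_kegg` (`cas_rn`, `kegg_id`,
#'   `compound_name`), `pathways` (`kegg_id`, `pathway_id`,
#'   `pathway_name`) and `go_terms` (`term_id`, `term_name`, `gene_id`).
#' @export
bundled_fixtures <- function() {
  path <- function(f) system.file("extdata", f, package = "vocdiff",
                                  mustWork = TRUE)
  list(cas_kegg = utils::read.delim(path("cas_kegg.tsv"),
                                    colClasses = "character"),
       pathways = utils::read.delim(path("pathways_synthetic.tsv"),
                                    colClasses = "character"),
       go_terms = utils::read.delim(path("go_terms_synthetic.tsv"),
                                    colClasses = "character"))
}
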