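#' Pipeline configuration
#'
#' Collects the thresholds and permutation settings of the full VOC
#' workflow. The defaults are the study thresholds this package models:
#' metabolite significance at FDR (q-value) < 0.1; DEGs at Welch p < 0.05
#' and fold change >= 1.5; GO terms at p < 0.05 with >= 3 DEGs.
#'
#' @param fdr_threshold q-value cutoff for significant peaks.
#' @param deg_p,deg_fc DEG thresholds (p-value, linear fold change).
#' @param enrich_p,enrich_min_genes GO-term selection thresholds.
#' @param n_permutations,seed Passed to [permutation_config()].
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(fdr_threshold = 0.1, deg_p = 0.05, deg_fc = 1.5,
                            enrich_p = 0.05, enrich_min_genes = 3,
                            n_permutations = 10000, seed = 1) {
  stopifnot(fdr_threshold > 0, fdr_threshold <= 1,
            deg_p > 0, deg_p <= 1, deg_fc >= 1,
            enrich_p > 0, enrich_p <= 1, enrich_min_genes >= 0)
  structure(list(fdr_threshold = fdr_threshold, deg_p = deg_p,
                 deg_fc = deg_fc, enrich_p = enrich_p,
                 enrich_min_genes = enrich_min_genes,
                 permutation = permutation_config(n_permutations,
                                                 seed = seed),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the VOC differential pipeline end to end
#'
#' detection filter -> mTIC normalization -> integrative differential
#' test -> (optional) CAS/KEGG annotation, with a run report. Every
#' output file carries a `#` header recording the package version, seed
#' and a hash of the configuration, so result files are traceable to the
#' run that produced them.
#'
#' @param table A [peak_table] (or path of an intensity TSV, in which
#'   case `groups_path` must name the sidecar).
#' @param config A [pipeline_config()].
#' @param annotations Optional annotation data frame (`feature_id`,
#'   `compound_name`, `cas_rn`, `retention_time`, ...).
#' @param cas_kegg Optional CAS-to-KEGG mapping data frame; defaults to
#'   the bundled fixture when annotations are given.
#' @param output_path Optional TSV path for the result table.
#' @param groups_path Sidecar path when `table` is a file path.
#' @return A list with `results` (the sorted result data frame), and
#'   `report` (versions, seed, thresholds, funnel counts, per-stage
#'   timings).
#' @export
run_voc_pipeline <- function(table, config = pipeline_config(),
                             annotations = NULL, cas_kegg = NULL,
                             output_path = NULL, groups_path = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- proc.time()[["elapsed"]]
  if (is.character(table)) {
    if (is.null(groups_path))
      stop("groups_path is required when reading the table from disk")
    table <- read_peak_table(table, groups_path)
  }
  stopifnot(inherits(table, "peak_table"))
  n_in <- nrow(table$intensities)

  timings <- c()
  stage <- function(name, expr) {
    s <- proc.time()[["elapsed"]]
    value <- force(expr)
    timings[[name]] <<- round(proc.time()[["elapsed"]] - s, 3)
    value
  }

  filtered <- stage("detection_filter", detection_filter(table))
  normalized <- stage("mtic_normalize", mtic_normalize(filtered))
  results <- stage("difftest",
                   differential_analysis(normalized, config$permutation,
                                         config$fdr_threshold))
  funnel <- attr(results, "summary")

  annot_funnel <- NULL
  if (!is.null(annotations)) {
    if (is.null(cas_kegg)) cas_kegg <- bundled_fixtures()$cas_kegg
    annotations <- stage("annotate", map_cas_to_kegg(annotations, cas_kegg))
    annot_funnel <- attr(annotations, "funnel")
    results <- annotate_results(results, annotations)
  }

  report <- list(
    package_version = as.character(utils::packageVersion("vocdiff")),
    r_version = as.character(getRversion()),
    seed = config$seed,
    config_hash = config_hash(config),
    thresholds = config[c("fdr_threshold", "deg_p", "deg_fc",
                          "enrich_p", "enrich_min_genes")],
    n_permutations = config$permutation$n_permutations,
    funnel = c(list(n_peaks_in = n_in,
                    n_after_detection_filter = nrow(filtered$intensities)),
               funnel[c("n_tested", "n_untestable", "n_significant")],
               annot_funnel),
    timings_sec = timings,
    total_sec = round(proc.time()[["elapsed"]] - t0, 3))

  if (!is.null(output_path))
    write_diff_results(results, output_path, output_header(config))
  list(results = results, report = report)
}

#' @keywords internal
output_header <- function(config) {
  sprintf("vocdiff %s | seed=%d | config=%s",
          as.character(utils::packageVersion("vocdiff")),
          config$seed, config_hash(config))
}

# Polynomial rolling hash (mod 2^31 - 1) of the deparsed configuration;
# dependency-free and stable across sessions, used only to tag output files.
config_hash <- function(config) {
  bytes <- utf8ToInt(paste(deparse(unclass(config)), collapse = ""))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
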