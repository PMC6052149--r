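#' Above-average abundance filter
#'
#' Retains probes whose mean log2 expression across all samples strictly
#' exceeds the grand mean of all probe means — the standard guard against
#' unreliable low-intensity probes before differential testing.
#'
#' @param matrix Numeric probes-by-samples log2 expression matrix with
#'   probe row names.
#' @return Character vector of retained probe ids.
#' @export
abundance_filter <- function(matrix) {
  stopifnot(is.matrix(matrix), nrow(matrix) >= 1)
  means <- rowMeans(matrix)
  rownames(matrix)[means > mean(means)]
}

#' Welch differential expression between two conditions
#'
#' Per probe: two-tailed Welch t-test (Satterthwaite degrees of freedom)
#' on log2 values, linear fold change `2^|mean_a - mean_b|` with a
#' direction flag (`+1` = higher in `condition_a`), and the DEG call
#' `p < p_threshold & fc_linear >= fc_threshold & passes_abundance`.
#' The fold-change boundary is inclusive.
#'
#' @param matrix Probes-by-samples log2 expression matrix.
#' @param condition Factor/character vector (named by sample or in column
#'   order) of condition labels.
#' @param condition_a,condition_b The two conditions to contrast
#'   (`>= 2` replicates each).
#' @param p_threshold,fc_threshold DEG thresholds (defaults 0.05 and 1.5).
#' @param abundance Character vector of probes passing the abundance
#'   filter; defaults to [abundance_filter()] on the full matrix. Pass
#'   `rownames(matrix)` to disable.
#' @return Data frame with one row per probe: `probe_id`, `mean_a`,
#'   `mean_b`, `delta_log2`, `t`, `df`, `p_value`, `fc_linear`,
#'   `direction`, `passes_abundance`, `is_deg`; attribute `"summary"`
#'   holds the contrast and the up/down DEG counts.
#' @export
welch_deg <- function(matrix, condition, condition_a, condition_b,
                      p_threshold = 0.05, fc_threshold = 1.5,
                      abundance = abundance_filter(matrix)) {
  stopifnot(is.matrix(matrix))
  condition <- as.character(condition)
  if (!is.null(names(condition))) condition <- condition[colnames(matrix)]
  stopifnot(length(condition) == ncol(matrix))
  xa <- matrix[, condition == condition_a, drop = FALSE]
  xb <- matrix[, condition == condition_b, drop = FALSE]
  if (ncol(xa) < 2 || ncol(xb) < 2)
    stop("each contrasted condition needs at least 2 replicates")
  na <- ncol(xa)
  nb <- ncol(xb)
  ma <- rowMeans(xa)
  mb <- rowMeans(xb)
  va <- rowSums((xa - ma)^2) / (na - 1)
  vb <- rowSums((xb - mb)^2) / (nb - 1)
  sa <- va / na
  sb <- vb / nb
  se2 <- sa + sb
  dm <- ma - mb
  t <- dm / sqrt(se2)
  df <- se2^2 / (sa^2 / (na - 1) + sb^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(t), df)
  degen <- se2 == 0
  if (any(degen)) {
    # no within-group variance: equal means are a perfect null, unequal
    # means a perfect separation
    p[degen] <- ifelse(dm[degen] == 0, 1, .Machine$double.xmin)
    t[degen] <- ifelse(dm[degen] == 0, 0, sign(dm[degen]) * Inf)
  }
  fc_linear <- 2^abs(dm)
  passes <- rownames(matrix) %in% abundance
  res <- data.frame(probe_id = rownames(matrix),
                    mean_a = ma, mean_b = mb, delta_log2 = dm,
                    t = t, df = df, p_value = p,
                    fc_linear = fc_linear,
                    direction = sign(dm),
                    passes_abundance = passes,
                    stringsAsFactors = FALSE)
  res$is_deg <- res$p_value < p_threshold &
    res$fc_linear >= fc_threshold & res$passes_abundance
  rownames(res) <- NULL
  attr(res, "summary") <- list(
    contrast = paste(condition_a, "vs", condition_b),
    n_deg = sum(res$is_deg),
    n_up = sum(res$is_deg & res$direction > 0),
    n_down = sum(res$is_deg & res$direction < 0))
  res
}

#' GO biological-process over-representation test
#'
#' One-sided hypergeometric test per term: the probability of observing at
#' least the realized overlap between the DEG list and the term's gene
#' set, drawn from the background. A term is selected when `p <
#' p_threshold` and at least `min_genes` DEGs fall in it. An informational
#' Benjamini-Hochberg column is emitted; selection uses the raw p.
#'
#' @param deg_ids Character vector of DEG identifiers (must be a subset of
#'   `background_ids`).
#' @param background_ids Character vector: the tested universe (typically
#'   the abundance-filtered probe set).
#' @param term_table Data frame with columns `term_id` and `gene_id`
#'   (optionally `term_name`).
#' @param p_threshold,min_genes Selection thresholds (defaults 0.05, 3).
#' @return Data frame sorted by p-value with columns `term_id`,
#'   `term_name`, `n_deg_in_term`, `n_deg`, `n_background_in_term`,
#'   `n_background`, `p_value`, `p_bh`, `selected`.
#' @export
gobp_enrichment <- function(deg_ids, background_ids, term_table,
                            p_threshold = 0.05, min_genes = 3) {
  stopifnot(all(c("term_id", "gene_id") %in% names(term_table)))
  deg_ids <- unique(deg_ids)
  background_ids <- unique(background_ids)
  if (!all(deg_ids %in% background_ids))
    stop("deg_ids must be a subset of background_ids")
  if (length(deg_ids) == 0) {
    warning("empty DEG list; no enrichment computed")
    return(data.frame(term_id = character(0), term_name = character(0),
                      n_deg_in_term = integer(0), n_deg = integer(0),
                      n_background_in_term = integer(0),
                      n_background = integer(0), p_value = numeric(0),
                      p_bh = numeric(0), selected = logical(0)))
  }
  N <- length(background_ids)
  n <- length(deg_ids)
  terms <- unique(term_table$term_id)
  name_of <- if ("term_name" %in% names(term_table))
    tapply(term_table$term_name, term_table$term_id, `[`, 1) else NULL
  rows <- lapply(terms, function(tid) {
    genes <- intersect(unique(term_table$gene_id[term_table$term_id == tid]),
                       background_ids)
    K <- length(genes)
    k <- length(intersect(genes, deg_ids))
    data.frame(term_id = tid,
               term_name = if (is.null(name_of)) NA_character_
                           else unname(name_of[tid]),
               n_deg_in_term = k, n_deg = n,
               n_background_in_term = K, n_background = N,
               p_value = stats::phyper(k - 1, K, N - K, n,
                                       lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$p_bh <- stats::p.adjust(res$p_value, method = "BH")
  res$selected <- res$p_value < p_threshold & res$n_deg_in_term >= min_genes
  res <- res[order(res$p_value), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Read an expression matrix and condition sidecar
#'
#' @param path TSV with probes in rows (first column = probe id) and
#'   samples in columns.
#' @param condition_path Two-column TSV (`sample_id`, `condition`).
#' @return List with `matrix` and named factor `condition`.
#' @export
read_expression_matrix <- function(path, condition_path) {
  tab <- utils::read.delim(path, check.names = FALSE, comment.char = "#")
  x <- as.matrix(tab[, -1, drop = FALSE])
  rownames(x) <- as.character(tab[[1]])
  cond <- utils::read.delim(condition_path, check.names = FALSE,
                            comment.char = "#")
  condition <- factor(stats::setNames(as.character(cond[[2]]),
                                      as.character(cond[[1]]))[colnames(x)])
  names(condition) <- colnames(x)
  list(matrix = x, condition = condition)
}

#' Read a term-to-gene table
#'
#' Accepts either the two/three-column TSV dialect (`term_id`, `gene_id`,
#' optional `term_name`) or, via [read_gmt()], the GMT format.
#'
#' @param path TSV path.
#' @return Data frame with `term_id`, `gene_id` and (if present)
#'   `term_name`.
#' @export
read_term_table <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, comment.char = "#",
                           colClasses = "character")
  stopifnot(all(c("term_id", "gene_id") %in% names(tab)))
  tab
}

#' @rdname read_term_table
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  rows <- lapply(strsplit(lines, "\t"), function(f) {
    if (length(f) < 3) return(NULL)
    data.frame(term_id = f[1], term_name = f[2], gene_id = f[-(1:2)],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
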