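#' Validate CAS registry numbers
#'
#' A CAS RN has the form `N{2,7}-NN-R` where `R` is a check digit: with
#' the digits (check digit excluded) read right to left and weighted
#' 1, 2, 3, ..., the weighted sum modulo 10 must equal `R`.
#'
#' @param cas_rn Character vector of candidate CAS registry numbers.
#' @return Logical vector: `TRUE` where the format and check digit are
#'   valid. `NA` input gives `FALSE`.
#' @examples
#' validate_cas(c("89-78-1", "89-78-2", "abc"))  # TRUE FALSE FALSE
#' @export
validate_cas <- function(cas_rn) {
  cas_rn <- as.character(cas_rn)
  ok <- !is.na(cas_rn) & grepl("^[0-9]{2,7}-[0-9]{2}-[0-9]$", cas_rn)
  idx <- which(ok)
  for (i in idx) {
    digits <- as.integer(strsplit(gsub("-", "", cas_rn[i]), "")[[1]])
    nd <- length(digits)
    check <- digits[nd]
    body <- rev(digits[-nd])
    ok[i] <- sum(body * seq_along(body)) %% 10 == check
  }
  ok
}

#' Map CAS registry numbers to KEGG compound ids
#'
#' Fills the `kegg_id` column of an annotation table from a CAS-to-KEGG
#' mapping (bundled fixture or user-supplied TSV), leaving entries without
#' a mapping as `NA`. Funnel counts for the annotation workflow (total
#' peaks, peaks with a valid CAS RN, peaks mapped to KEGG) are attached as
#' attribute `"funnel"`.
#'
#' @param annotations Data frame with at least `feature_id` and `cas_rn`
#'   columns (`NA` for unannotated peaks); an existing `kegg_id` column is
#'   only filled where empty.
#' @param mapping Data frame with columns `cas_rn` and `kegg_id`.
#'   Duplicate CAS entries must agree; conflicting duplicates are an
#'   error.
#' @return `annotations` with `kegg_id` filled where known.
#' @export
map_cas_to_kegg <- function(annotations, mapping) {
  stopifnot(all(c("feature_id", "cas_rn") %in% names(annotations)),
            all(c("cas_rn", "kegg_id") %in% names(mapping)))
  if (anyDuplicated(annotations$feature_id))
    stop("feature ids must be unique")
  mp <- unique(mapping[, c("cas_rn", "kegg_id")])
  dup <- mp$cas_rn[duplicated(mp$cas_rn)]
  if (length(dup))
    stop("conflicting duplicate CAS entries in mapping: ",
         paste(unique(dup), collapse = ", "))
  if (!"kegg_id" %in% names(annotations))
    annotations$kegg_id <- NA_character_
  hit <- match(annotations$cas_rn, mp$cas_rn)
  fill <- !is.na(hit) & is.na(annotations$kegg_id)
  annotations$kegg_id[fill] <- mp$kegg_id[hit[fill]]
  attr(annotations, "funnel") <- list(
    n_total = nrow(annotations),
    n_with_cas = sum(!is.na(annotations$cas_rn)),
    n_kegg_mapped = sum(!is.na(annotations$kegg_id)))
  annotations
}

#' Map annotated compounds to pathways
#'
#' Joins KEGG compound ids against a compound-to-pathway table with set
#' semantics (duplicate pairs count once).
#'
#' @param annotations Data frame with `feature_id` and `kegg_id` columns.
#' @param pathways Data frame with columns `kegg_id`, `pathway_id` and
#'   optionally `pathway_name`.
#' @return A list with `per_feature` (named list: feature id ->
#'   character vector of pathway ids, empty when unmapped) and `summary`
#'   (`n_compounds_with_pathway`, `n_distinct_pathways`).
#' @export
map_to_pathways <- function(annotations, pathways) {
  stopifnot(all(c("feature_id", "kegg_id") %in% names(annotations)),
            all(c("kegg_id", "pathway_id") %in% names(pathways)))
  pw <- unique(pathways[, c("kegg_id", "pathway_id")])
  per_feature <- lapply(seq_len(nrow(annotations)), function(i) {
    k <- annotations$kegg_id[i]
    if (is.na(k)) character(0)
    else sort(unique(pw$pathway_id[pw$kegg_id == k]))
  })
  names(per_feature) <- annotations$feature_id
  hit <- lengths(per_feature) > 0
  list(per_feature = per_feature,
       summary = list(
         n_compounds_with_pathway = sum(hit),
         n_distinct_pathways = length(unique(unlist(per_feature)))))
}

#' Append annotation columns to a differential result table
#'
#' Left-joins compound name, CAS RN, KEGG id and retention time onto the
#' output of [differential_analysis()], writing `NA` for unannotated
#' peaks (the result-table convention for unknowns).
#'
#' @param results Data frame from [differential_analysis()].
#' @param annotations Data frame with `feature_id` plus any of
#'   `compound_name`, `cas_rn`, `kegg_id`, `retention_time`.
#' @return `results` with the annotation columns prepended after
#'   `feature_id`.
#' @export
annotate_results <- function(results, annotations) {
  stopifnot("feature_id" %in% names(annotations))
  keep <- intersect(c("compound_name", "cas_rn", "kegg_id", "retention_time"),
                    names(annotations))
  hit <- match(results$feature_id, annotations$feature_id)
  for (col in rev(keep)) {
    v <- annotations[[col]][hit]
    results <- cbind(results[, 1, drop = FALSE],
                     stats::setNames(data.frame(v, stringsAsFactors = FALSE), col),
                     results[, -1, drop = FALSE])
  }
  results
}
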