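#' Construct a VOC peak table
#'
#' The central metabolomics container: a peaks-by-samples intensity matrix
#' with explicit missingness (`NA` cells) and a two-group design. Observed
#' intensities must be strictly positive (GC-MS peak areas); missing cells
#' represent peaks that were not quantified in a sample, typically because
#' they fell below the limit of detection.
#'
#' @param intensities Numeric matrix, peaks in rows and samples in columns,
#'   with row names (feature ids) and column names (sample ids). `NA` marks
#'   a missing cell; all observed values must be `> 0`.
#' @param groups Character or factor vector mapping each sample to
#'   `"case"` or `"control"`. Either named by sample id or given in column
#'   order of `intensities`.
#' @return An object of class `"peak_table"`: a list with elements
#'   `intensities` (the matrix) and `groups` (a named factor with levels
#'   `case`, `control`).
#' @examples
#' x <- matrix(c(2, 3, 5, 4, NA, 4), nrow = 3,
#'             dimnames = list(paste0("peak_", 1:3), c("s1", "s2")))
#' pt <- peak_table(cbind(x, x + 1), rep(c("case", "control"), each = 2))
#' @export
peak_table <- function(intensities, groups) {
  if (!is.matrix(intensities) || !is.numeric(intensities))
    stop("'intensities' must be a numeric matrix (peaks x samples)")
  if (is.null(rownames(intensities)))
    rownames(intensities) <- sprintf("peak_%03d", seq_len(nrow(intensities)))
  if (is.null(colnames(intensities)))
    colnames(intensities) <- sprintf("sample_%02d", seq_len(ncol(intensities)))
  if (anyDuplicated(rownames(intensities)))
    stop("duplicated feature ids in 'intensities'")
  if (anyDuplicated(colnames(intensities)))
    stop("duplicated sample ids in 'intensities'")
  groups <- as.character(groups)
  if (!is.null(names(groups))) {
    missing_ids <- setdiff(colnames(intensities), names(groups))
    if (length(missing_ids))
      stop("samples without a group label: ", paste(missing_ids, collapse = ", "))
    groups <- groups[colnames(intensities)]
  } else {
    if (length(groups) != ncol(intensities))
      stop("'groups' must have one entry per sample")
    names(groups) <- colnames(intensities)
  }
  bad <- setdiff(unique(groups), c("case", "control"))
  if (length(bad))
    stop("group labels must be 'case' or 'control'; found: ",
         paste(bad, collapse = ", "))
  groups <- factor(groups, levels = c("case", "control"))
  if (any(table(groups) < 2))
    stop("each group needs at least 2 samples")
  obs <- intensities[!is.na(intensities)]
  if (any(obs <= 0))
    stop("observed intensities must be strictly positive")
  structure(list(intensities = intensities, groups = groups),
            class = "peak_table")
}

#' @export
print.peak_table <- function(x, ...) {
  d <- dim(x$intensities)
  n_miss <- sum(is.na(x$intensities))
  cat(sprintf("peak_table: %d peaks x %d samples (%d case / %d control), %d missing cells (%.1f%%)\n",
              d[1], d[2], sum(x$groups == "case"), sum(x$groups == "control"),
              n_miss, 100 * n_miss / prod(d)))
  invisible(x)
}

#' @export
dim.peak_table <- function(x) dim(x$intensities)

#' Read / write peak tables as TSV
#'
#' The on-disk dialect is a TSV with features in rows and samples in
#' columns; the first column holds the feature id and missing cells are
#' written as `"NA"` (empty strings are also accepted on read). Group
#' labels live in a two-column sidecar TSV (`sample_id`, `group`). Lines
#' starting with `#` are treated as comments.
#'
#' @param path Path of the intensity TSV.
#' @param groups_path Path of the sample-to-group sidecar TSV.
#' @return `read_peak_table` returns a [peak_table]; `write_peak_table`
#'   returns `path` invisibly.
#' @export
read_peak_table <- function(path, groups_path) {
  tab <- utils::read.delim(path, check.names = FALSE, comment.char = "#",
                           na.strings = c("NA", ""))
  x <- as.matrix(tab[, -1, drop = FALSE])
  rownames(x) <- as.character(tab[[1]])
  g <- utils::read.delim(groups_path, check.names = FALSE, comment.char = "#")
  groups <- stats::setNames(as.character(g[[2]]), as.character(g[[1]]))
  peak_table(x, groups)
}

#' @rdname read_peak_table
#' @param table A [peak_table].
#' @param header_lines Optional character vector of `#`-prefixed comment
#'   lines written above both files (provenance: seed, config hash, version).
#' @export
write_peak_table <- function(table, path, groups_path = NULL,
                             header_lines = NULL) {
  stopifnot(inherits(table, "peak_table"))
  write_tsv_commented(
    data.frame(feature_id = rownames(table$intensities),
               table$intensities, check.names = FALSE),
    path, header_lines)
  if (!is.null(groups_path))
    write_tsv_commented(
      data.frame(sample_id = names(table$groups),
                 group = as.character(table$groups)),
      groups_path, header_lines)
  invisible(path)
}

# Shared TSV writer: optional '#' header lines, NA written literally.
write_tsv_commented <- function(df, path, header_lines = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(header_lines))
    writeLines(paste0("# ", sub("^#\\s*", "", header_lines)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
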