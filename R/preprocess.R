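#' mTIC normalization
#'
#' Divides every observed intensity by its sample's mTIC — the sum of peak
#' intensities over all identified metabolites in that sample — so each
#' peak is expressed as a fraction of the sample's total volatile
#' metabolome. Missing cells are excluded from the sum (censored values
#' are unknown, not zero) and stay missing. After normalization every
#' sample's observed values sum to 1.
#'
#' @param table A [peak_table].
#' @return A [peak_table] with normalized intensities.
#' @examples
#' x <- matrix(c(2, 3, 5, 4, NA, 4, 1, 1, 2, 2, 2, 4), nrow = 3,
#'             dimnames = list(NULL, c("a", "b", "c", "d")))
#' pt <- peak_table(x, c("case", "case", "control", "control"))
#' colSums(mtic_normalize(pt)$intensities, na.rm = TRUE)
#' @export
mtic_normalize <- function(table) {
  stopifnot(inherits(table, "peak_table"))
  x <- table$intensities
  n_obs <- colSums(!is.na(x))
  if (any(n_obs == 0))
    stop("sample(s) with no observed intensities: ",
         paste(colnames(x)[n_obs == 0], collapse = ", "))
  mtic <- colSums(x, na.rm = TRUE)
  table$intensities <- sweep(x, 2, mtic, `/`)
  table
}

#' Quantile normalization (QC transform)
#'
#' Classic rank-mean quantile normalization: within each sample the k-th
#' smallest value is replaced by the mean of the k-th smallest values
#' across all samples, so afterwards all samples share an identical sorted
#' value vector. Tied values receive the mean of the reference values at
#' their tied ranks. Used for quality assessment of the quantification;
#' the default differential-testing path uses [mtic_normalize()] instead.
#'
#' Refuses tables with missing cells: rank-mean normalization of unequal
#' observed counts would silently impute, so callers must filter (e.g.
#' [detection_filter()]) or complete the table first.
#'
#' @param table A [peak_table] without missing values.
#' @return A [peak_table] with quantile-normalized intensities.
#' @export
quantile_normalize <- function(table) {
  stopifnot(inherits(table, "peak_table"))
  x <- table$intensities
  if (anyNA(x))
    stop("quantile_normalize requires a complete table; ",
         "filter or impute missing values first")
  y <- limma::normalizeQuantiles(x, ties = TRUE)
  dimnames(y) <- dimnames(x)
  table$intensities <- y
  table
}

#' Detection filter
#'
#' Retains peaks quantified in more than half of the samples of each
#' group (strict inequality: with 10 samples per group a peak needs at
#' least 6 observations in both groups). Peak order is preserved; the
#' result may be empty.
#'
#' @param table A [peak_table].
#' @return A [peak_table] containing only the retained peaks.
#' @export
detection_filter <- function(table) {
  stopifnot(inherits(table, "peak_table"))
  x <- table$intensities
  keep <- rep(TRUE, nrow(x))
  for (g in levels(table$groups)) {
    cols <- table$groups == g
    keep <- keep & (rowSums(!is.na(x[, cols, drop = FALSE])) > sum(cols) / 2)
  }
  table$intensities <- x[keep, , drop = FALSE]
  table
}
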