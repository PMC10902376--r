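#' Z-score feature columns
#'
#' Centers and scales every column to mean 0 and unit sample SD. Columns with
#' (near-)zero SD are passed through untouched and flagged in the
#' `"constant_columns"` attribute; the SD filter removes them downstream.
#'
#' @param x numeric matrix, subjects in rows.
#' @param sd_tolerance SD at or below which a column counts as constant.
#' @return matrix of the same shape, attribute `constant_columns` holding the
#'   indices of untouched columns.
#' @export
zscore_features <- function(x, sd_tolerance = 1e-6) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("z-scoring requires at least 2 subjects")
  sds <- apply(x, 2, stats::sd)
  keep <- sds > sd_tolerance
  x[, keep] <- scale(x[, keep, drop = FALSE])
  attr(x, "constant_columns") <- which(!keep)
  x
}

#' Drop near-constant feature columns
#'
#' Removes columns whose sample SD is less than or equal to `sd_tolerance`
#' (the boundary is inclusive). Column order is preserved.
#'
#' @param x numeric matrix.
#' @param sd_tolerance inclusive SD threshold.
#' @return list with `matrix` (retained columns) and `dropped` (indices).
#' @export
filter_low_sd <- function(x, sd_tolerance = 1e-6) {
  x <- as.matrix(x)
  sds <- apply(x, 2, stats::sd)
  dropped <- unname(which(sds <= sd_tolerance))
  keep <- setdiff(seq_len(ncol(x)), dropped)
  list(matrix = x[, keep, drop = FALSE], dropped = dropped)
}

#' Drop highly correlated feature columns
#'
#' Greedy left-to-right scan: a column is dropped iff its absolute Pearson
#' correlation with any earlier retained column reaches the threshold.
#' Deterministic given column order; the earlier column always survives.
#'
#' @param x numeric matrix with no constant columns (apply [filter_low_sd()]
#'   first).
#' @param correlation_threshold inclusive absolute-correlation threshold.
#' @return list with `matrix` and `dropped` (indices into `x`'s columns).
#' @export
filter_correlated <- function(x, correlation_threshold = 0.85) {
  x <- as.matrix(x)
  p <- ncol(x)
  if (p <= 1) return(list(matrix = x, dropped = integer(0)))
  cm <- abs(stats::cor(x))
  kept <- integer(0)
  dropped <- integer(0)
  for (j in seq_len(p)) {
    if (length(kept) && any(cm[j, kept] >= correlation_threshold)) {
      dropped <- c(dropped, j)
    } else {
      kept <- c(kept, j)
    }
  }
  list(matrix = x[, kept, drop = FALSE], dropped = dropped)
}

#' Imaging preprocessing pipeline
#'
#' Fixed order: z-score, then SD filter, then correlation filter. Re-running
#' the pipeline on its own output is a no-op (idempotence).
#'
#' @param x numeric subjects x features matrix.
#' @param sd_tolerance inclusive SD threshold.
#' @param correlation_threshold inclusive absolute-correlation threshold.
#' @return list with `matrix`, `dropped_low_sd`, `dropped_correlated`
#'   (original column indices), `kept` (original column indices retained).
#' @export
preprocess_imaging <- function(x, sd_tolerance = 1e-6,
                               correlation_threshold = 0.85) {
  x <- as.matrix(x)
  z <- zscore_features(x, sd_tolerance)
  f1 <- filter_low_sd(z, sd_tolerance)
  kept1 <- setdiff(seq_len(ncol(x)), f1$dropped)
  f2 <- filter_correlated(f1$matrix, correlation_threshold)
  list(matrix = f2$matrix,
       dropped_low_sd = f1$dropped,
       dropped_correlated = kept1[f2$dropped],
       kept = kept1[setdiff(seq_along(kept1), f2$dropped)])
}
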