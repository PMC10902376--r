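#' Adjusted Rand index between two partitions
#'
#' Hubert-Arabie adjustment of the Rand index: 1 for identical partitions
#' (up to relabeling), expectation 0 under independent random partitions.
#' Used throughout for clustering-recovery checks against planted truth.
#'
#' @param a,b label vectors of equal length.
#' @return scalar ARI.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  n2 <- choose(length(a), 2)
  expected <- ai * bj / n2
  denom <- (ai + bj) / 2 - expected
  if (denom == 0) return(as.numeric(nij == expected))
  (nij - expected) / denom
}

# deterministic per-stage seed derived from a global seed and a stage name
# (kept below 2^31 so it stays a valid R integer)
stage_seed <- function(global_seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(global_seed) * 10007 + h) %% 2147483647L)
}
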