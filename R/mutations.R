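#' Pairwise mutation co-occurrence / mutual exclusivity per subtype
#'
#' For every subtype and unordered gene pair, builds the 2x2
#' mutated/wild-type table, computes the odds ratio (Haldane-Anscombe 0.5
#' correction when any cell is zero; OR > 1 = co-occurrence, OR < 1 =
#' exclusivity) and a two-sided Fisher exact p-value from the uncorrected
#' table. Significance marks mirror the raw-p convention: "*" for p < 0.01,
#' "." for p < 0.05. Benjamini-Hochberg adjusted p-values are attached when
#' `fdr = TRUE`.
#'
#' @param genomic binary subjects x genes matrix (no NA rows).
#' @param labels subtype per subject.
#' @param genes genes to analyze (default all columns).
#' @param fdr also report BH-adjusted p-values per subtype.
#' @return object of class `cooccurrence_report`: named list per subtype,
#'   each with `odds_ratio` and `p_value` (genes x genes, upper triangle,
#'   symmetric content), `marks` (character matrix), and optionally
#'   `p_adjusted`; plus `pairs`, a long data.frame over all subtypes.
#' @export
pairwise_mutation_or <- function(genomic, labels, genes = NULL, fdr = FALSE) {
  genomic <- as.matrix(genomic)
  if (is.null(genes)) genes <- colnames(genomic)
  missing <- setdiff(genes, colnames(genomic))
  if (length(missing))
    stop("gene(s) absent from mutation table: ",
         paste(missing, collapse = ", "))
  stopifnot(nrow(genomic) == length(labels))
  g <- length(genes)
  subtypes <- sort(unique(labels))
  per <- list(); long <- list()
  for (st in subtypes) {
    M <- genomic[labels == st, genes, drop = FALSE]
    orm <- pm <- matrix(NA_real_, g, g, dimnames = list(genes, genes))
    marks <- matrix("", g, g, dimnames = list(genes, genes))
    for (i in seq_len(g - 1)) for (j in (i + 1):g) {
      a <- sum(M[, i] == 1 & M[, j] == 1)
      b <- sum(M[, i] == 1 & M[, j] == 0)
      c_ <- sum(M[, i] == 0 & M[, j] == 1)
      d <- sum(M[, i] == 0 & M[, j] == 0)
      or <- if (min(a, b, c_, d) == 0)
        ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
      else (a * d) / (b * c_)
      p <- stats::fisher.test(matrix(c(a, c_, b, d), 2))$p.value
      orm[i, j] <- orm[j, i] <- or
      pm[i, j] <- pm[j, i] <- p
      marks[i, j] <- marks[j, i] <- if (p < 0.01) "*" else if (p < 0.05) "." else ""
      long[[length(long) + 1L]] <- data.frame(
        subtype = st, gene_a = genes[i], gene_b = genes[j],
        odds_ratio = or, p_value = p,
        direction = ifelse(or > 1, "co-occurrence", "exclusivity"),
        stringsAsFactors = FALSE)
    }
    entry <- list(odds_ratio = orm, p_value = pm, marks = marks)
    if (fdr) {
      padj <- pm
      ut <- upper.tri(pm)
      padj[ut] <- stats::p.adjust(pm[ut], method = "BH")
      padj[lower.tri(padj)] <- t(padj)[lower.tri(padj)]
      entry$p_adjusted <- padj
    }
    per[[as.character(st)]] <- entry
  }
  structure(c(per, list(pairs = do.call(rbind, long))),
            class = "cooccurrence_report")
}

#' @export
print.cooccurrence_report <- function(x, ...) {
  pr <- x$pairs
  sig <- pr[pr$p_value < 0.05, ]
  cat(sprintf("cooccurrence_report: %d subtypes, %d gene pairs each; %d pairs at p < 0.05\n",
              length(setdiff(names(x), "pairs")),
              nrow(pr) / length(setdiff(names(x), "pairs")), nrow(sig)))
  invisible(x)
}

#' Per-subtype mutation proportions
#'
#' Fraction of mutated subjects per gene within each subtype, plus overall;
#' rows sorted by overall mutation frequency, descending.
#'
#' @inheritParams pairwise_mutation_or
#' @return data.frame: gene, overall, one column per subtype.
#' @export
mutation_proportions <- function(genomic, labels) {
  genomic <- as.matrix(genomic)
  stopifnot(nrow(genomic) == length(labels))
  subtypes <- sort(unique(labels))
  out <- data.frame(gene = colnames(genomic),
                    overall = colMeans(genomic),
                    stringsAsFactors = FALSE, row.names = NULL)
  for (st in subtypes)
    out[[paste0("subtype_", st)]] <-
      colMeans(genomic[labels == st, , drop = FALSE])
  out[order(-out$overall), , drop = FALSE]
}
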