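#' Canonical correlation analysis of imaging and genomic views
#'
#' Finds the coefficient vectors a, b maximizing the correlation r between
#' the latent variables u = X a and v = Y b. Solved through the SVD of the
#' whitened cross-covariance Sxx^(-1/2) Sxy Syy^(-1/2) (equivalent to the
#' generalized eigen-problem). Binary gene columns are treated as numeric;
#' all columns are centered internally. An optional ridge is added to each
#' within-block covariance for near-singular blocks.
#'
#' @param X subjects x imaging-features matrix (both-modality subjects).
#' @param Y subjects x genes (or pathways) matrix, same subjects.
#' @param ridge nonnegative ridge added to the diagonal of both within-block
#'   covariances.
#' @return object of class `cca_result`: `a`, `b` (coefficients; sign
#'   convention: first nonzero entry of `a` positive), `u`, `v` (latent
#'   scores scaled to unit sum of squares), `r` (first canonical
#'   correlation, in [0, 1]), `r_all` (all canonical correlations),
#'   `n_subjects`, `ridge`, and the centered `X`, `Y` (for permutation
#'   tests).
#' @export
fit_cca <- function(X, Y, ridge = 0) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  stopifnot(nrow(X) == nrow(Y), ridge >= 0)
  n <- nrow(X); p <- ncol(X); q <- ncol(Y)
  if (n < 3) stop("CCA needs at least 3 subjects")
  if (ridge == 0 && n - 1 < p + q)
    stop("fewer subjects than total variables: within-block covariances are ",
         "singular; supply ridge > 0")
  Xc <- scale(X, center = TRUE, scale = FALSE)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  Sxx <- crossprod(Xc) / (n - 1) + diag(ridge, p)
  Syy <- crossprod(Yc) / (n - 1) + diag(ridge, q)
  Sxy <- crossprod(Xc, Yc) / (n - 1)
  ix <- inv_sqrt(Sxx); iy <- inv_sqrt(Syy)
  if (is.null(ix) || is.null(iy))
    stop("singular within-block covariance (constant or collinear columns); ",
         "supply ridge > 0 or drop offending columns")
  sv <- svd(ix %*% Sxy %*% iy)
  a <- drop(ix %*% sv$u[, 1]); b <- drop(iy %*% sv$v[, 1])
  nz <- which(abs(a) > 1e-12)[1]
  if (!is.na(nz) && a[nz] < 0) { a <- -a; b <- -b }
  u <- drop(Xc %*% a); v <- drop(Yc %*% b)
  if (sum(u^2) > 0) { a <- a / sqrt(sum(u^2)); u <- u / sqrt(sum(u^2)) }
  if (sum(v^2) > 0) { b <- b / sqrt(sum(v^2)); v <- v / sqrt(sum(v^2)) }
  structure(list(a = a, b = b, u = u, v = v,
                 r = min(max(sv$d[1], 0), 1),
                 r_all = pmin(pmax(sv$d, 0), 1),
                 n_subjects = n, ridge = ridge, X = Xc, Y = Yc),
            class = "cca_result")
}

# symmetric inverse square root; NULL if numerically singular
inv_sqrt <- function(M) {
  eg <- eigen((M + t(M)) / 2, symmetric = TRUE)
  if (any(eg$values < max(eg$values) * 1e-10)) return(NULL)
  eg$vectors %*% (t(eg$vectors) / sqrt(eg$values))
}

#' @export
print.cca_result <- function(x, ...) {
  cat(sprintf("cca_result: r = %.4f on %d subjects (%d x %d variables%s)\n",
              x$r, x$n_subjects, length(x$a), length(x$b),
              if (x$ridge > 0) sprintf(", ridge %.2g", x$ridge) else ""))
  invisible(x)
}

#' Significance of the first canonical correlation
#'
#' Default `"permutation"`: Y's subject rows are permuted `n_perm` times, the
#' CCA refitted, and p = (1 + #\{r_perm >= r_obs\}) / (1 + n_perm).
#' `"bartlett"`: Wilks-lambda chi-square approximation over all canonical
#' pairs, Lambda = prod(1 - r_i^2), chi-sq = -(n - 1 - (p + q + 1)/2) log
#' Lambda with p*q degrees of freedom.
#'
#' @param result a [fit_cca()] result.
#' @param method `"permutation"` or `"bartlett"`.
#' @param n_perm number of permutations.
#' @param seed RNG seed for the permutations.
#' @return p-value (scalar).
#' @export
cca_pvalue <- function(result, method = c("permutation", "bartlett"),
                       n_perm = 999L, seed = 1L) {
  stopifnot(inherits(result, "cca_result"))
  method <- match.arg(method)
  if (method == "bartlett") {
    n <- result$n_subjects
    p <- length(result$a); q <- length(result$b)
    lambda <- prod(1 - result$r_all^2)
    stat <- -(n - 1 - (p + q + 1) / 2) * log(max(lambda, 1e-300))
    return(stats::pchisq(stat, df = p * q, lower.tail = FALSE))
  }
  if (n_perm < 100) warning("n_perm < 100 gives a coarse permutation p-value")
  set.seed(seed)
  r_obs <- result$r
  hits <- 0L
  for (b in seq_len(n_perm)) {
    perm <- sample.int(result$n_subjects)
    r_b <- fit_cca(result$X, result$Y[perm, , drop = FALSE],
                   ridge = result$ridge)$r
    if (r_b >= r_obs) hits <- hits + 1L
  }
  (1 + hits) / (1 + n_perm)
}

#' Transductive kNN subtype prediction in the CCA latent space
#'
#' Euclidean k-nearest-neighbor majority vote in the (u, v) latent plane,
#' with voting ties broken by the label of the single nearest neighbor.
#'
#' @param train_scores n_train x d matrix of latent coordinates (typically
#'   d = 2: the first imaging and genomic latent variables).
#' @param train_labels training subtype labels.
#' @param test_scores n_test x d matrix.
#' @param k neighbor count (default 13).
#' @param test_labels optional true labels; enables the confusion matrix and
#'   accuracy.
#' @return list: `predicted`, and when `test_labels` given, `confusion`
#'   (true x predicted) and `accuracy`.
#' @export
knn_latent_predict <- function(train_scores, train_labels, test_scores,
                               k = 13L, test_labels = NULL) {
  Tr <- as.matrix(train_scores); Te <- as.matrix(test_scores)
  stopifnot(ncol(Tr) == ncol(Te), nrow(Tr) == length(train_labels))
  if (k > nrow(Tr)) stop("k exceeds the number of training subjects")
  d2 <- outer(rowSums(Te^2), rowSums(Tr^2), "+") - 2 * tcrossprod(Te, Tr)
  pred <- vapply(seq_len(nrow(Te)), function(i) {
    nn <- order(d2[i, ])[seq_len(k)]
    votes <- table(train_labels[nn])
    top <- names(votes)[votes == max(votes)]
    if (length(top) == 1) top else as.character(train_labels[nn[1]])
  }, character(1))
  if (is.numeric(train_labels)) pred <- as.numeric(pred)
  out <- list(predicted = pred)
  if (!is.null(test_labels)) {
    lv <- sort(unique(c(test_labels, pred)))
    out$confusion <- table(true = factor(test_labels, lv),
                           predicted = factor(pred, lv))
    out$accuracy <- mean(pred == test_labels)
  }
  out
}

#' Imaging feature vs gene correlation matrix
#'
#' Pearson correlation of every selected imaging feature with every gene
#' indicator, overall and within each subtype, with two-sided t-test
#' p-values. Entries where either column is constant within the stratum are
#' reported as missing and flagged.
#'
#' @param X subjects x imaging-features matrix (both-modality subjects).
#' @param Y subjects x genes binary matrix, same subjects.
#' @param labels optional subtype per subject (adds per-subtype strata).
#' @return data.frame: stratum, feature, gene, r, p_value, significant
#'   (p < 0.05), flag ("constant" where undefined).
#' @export
feature_gene_correlation <- function(X, Y, labels = NULL) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  stopifnot(nrow(X) == nrow(Y))
  strata <- list(all = seq_len(nrow(X)))
  if (!is.null(labels))
    for (st in sort(unique(labels)))
      strata[[paste0("subtype_", st)]] <- which(labels == st)
  rows <- list()
  for (sn in names(strata)) {
    idx <- strata[[sn]]
    for (fi in seq_len(ncol(X))) for (gi in seq_len(ncol(Y))) {
      x <- X[idx, fi]; y <- Y[idx, gi]
      if (stats::sd(x) < 1e-12 || stats::sd(y) < 1e-12) {
        rows[[length(rows) + 1L]] <- data.frame(
          stratum = sn, feature = colnames(X)[fi] %||% paste0("f", fi),
          gene = colnames(Y)[gi] %||% paste0("g", gi),
          r = NA_real_, p_value = NA_real_, significant = FALSE,
          flag = "constant", stringsAsFactors = FALSE)
        next
      }
      ct <- stats::cor.test(x, y)
      rows[[length(rows) + 1L]] <- data.frame(
        stratum = sn, feature = colnames(X)[fi] %||% paste0("f", fi),
        gene = colnames(Y)[gi] %||% paste0("g", gi),
        r = unname(ct$estimate), p_value = ct$p.value,
        significant = ct$p.value < 0.05, flag = "",
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
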