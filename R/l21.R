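#' Pathway-supervised L2,1-norm feature selection
#'
#' Solves min ||W||_2,1 subject to W' X = Y by iteratively reweighted least
#' squares: with G = diag(2 ||w_i||_2 + eps), each step takes the closed form
#' W = G X (X' G X)^+ Y' (computed through an SVD of G^(1/2) X for
#' stability). Minimizing the L2,1 norm — the sum of the Euclidean norms of
#' W's rows — drives whole rows to zero, eliminating entire imaging features;
#' the surviving rows, ranked by row norm, are the selected features. When
#' subjects outnumber features the equality constraint is enforced in the
#' least-squares sense (projection onto X's row space) and the residual
#' ||W'X - Y||_F is reported.
#'
#' When subjects outnumber features the equality constraint W' X = Y is
#' overdetermined: any least-squares solution is unique and the L2,1 term
#' has nothing to select. In that regime the standard augmented system of
#' the L2,1 feature-selection literature is solved instead: U' [X; gamma I]
#' = Y with U = \[W; E\], i.e. min ||W||_2,1 + (1/gamma) ||W'X - Y||_2,1
#' with a per-subject robust residual block, which keeps the row-sparsity
#' mechanism active. The hard-constraint program (the regime with more
#' features than subjects, as in high-dimensional radiomics) is untouched
#' by this.
#'
#' @param X numeric features x subjects matrix (z-scored, filtered).
#' @param Y numeric targets x subjects matrix (pathway alteration labels for
#'   the same subjects).
#' @param n_features number of features to select (`NULL`: all rows above
#'   `zero_row_tolerance`).
#' @param max_iter,tol IRLS iteration cap and relative-change tolerance on
#'   the objective.
#' @param eps row-norm regularizer avoiding division by zero.
#' @param zero_row_tolerance rows with L2 norm at or below this are treated
#'   as eliminated.
#' @param gamma sparsity/fit trade-off of the augmented system used when
#'   subjects outnumber features (ignored otherwise); larger values shrink
#'   more rows to zero. The default `"auto"` calibrates gamma by bisection
#'   so that the surviving support modestly exceeds the requested feature
#'   count (between `n_features` and 3 times it), keeping the ranking
#'   sparse without collapsing below the target.
#' @return object of class `selection_result`: `W`, `row_norms`,
#'   `selected_feature_ids` (descending row norm), `n_selected`,
#'   `objective_trace`, `residual`, `converged`, `iterations`, `augmented`,
#'   `gamma` (the value used, `NA` in the hard-constraint regime).
#' @export
l21_select <- function(X, Y, n_features = NULL, max_iter = 200L, tol = 1e-6,
                       eps = 1e-8, zero_row_tolerance = 1e-6,
                       gamma = "auto") {
  X <- as.matrix(X); Y <- as.matrix(Y)
  d <- nrow(X); n <- ncol(X)
  if (ncol(Y) != n) stop("X and Y must cover the same subjects (columns)")
  sv0 <- svd(X, nu = 0, nv = 0)$d
  if (sum(sv0 > max(sv0) * 1e-10) < min(d, n))
    stop("rank-deficient system: X has collinear rows/columns; ",
         "apply stronger preprocessing before selection")
  augmented <- d < n

  fit_at <- function(g) {
    Xa <- if (augmented) rbind(X, diag(g, n)) else X
    l21_irls(Xa, Y, max_iter = max_iter, tol = tol, eps = eps)
  }

  if (!augmented) {
    gamma_used <- NA_real_
    res <- fit_at(0)
  } else if (identical(gamma, "auto")) {
    m_target <- if (is.null(n_features)) max(2L, d %/% 8L)
                else as.integer(n_features)
    alive_at <- function(fit)
      sum(sqrt(rowSums(fit$W[seq_len(d), , drop = FALSE]^2)) >
            zero_row_tolerance)
    lo <- 1e-2; hi <- 1e4
    best <- NULL; best_dist <- Inf; gamma_used <- NA_real_
    for (it in seq_len(20)) {
      g <- sqrt(lo * hi)
      f <- fit_at(g)
      alive <- alive_at(f)
      # distance from the target band [m_target, 3 m_target], in log counts
      dist <- if (alive < m_target) log((m_target + 1) / (alive + 1))
              else log(max(alive / (3 * m_target), 1))
      if (dist < best_dist ||
          (dist == best_dist && alive >= m_target)) {
        best <- f; best_dist <- dist; gamma_used <- g
      }
      if (alive >= m_target && alive <= 3 * m_target) break
      if (alive > 3 * m_target) lo <- g else hi <- g
    }
    res <- best
  } else {
    gamma_used <- as.numeric(gamma)
    res <- fit_at(gamma_used)
  }

  W <- res$W[seq_len(d), , drop = FALSE]
  row_norms <- sqrt(rowSums(W^2))
  alive <- which(row_norms > zero_row_tolerance)
  ord <- alive[order(row_norms[alive], decreasing = TRUE)]
  if (!is.null(n_features)) ord <- utils::head(ord, n_features)
  structure(list(
    W = W, row_norms = row_norms, selected_feature_ids = ord,
    n_selected = length(ord), objective_trace = res$trace,
    residual = sqrt(sum((crossprod(W, X) - Y)^2)),
    converged = res$converged, iterations = res$iterations,
    augmented = augmented, gamma = gamma_used
  ), class = "selection_result")
}

# IRLS for min ||W||_21 s.t. W'X = Y (X full column rank assumed feasible
# after augmentation); SVD-based pseudoinverse step, monotone objective
l21_irls <- function(X, Y, max_iter, tol, eps) {
  d <- nrow(X)
  irls_step <- function(g) {
    sg <- sqrt(g)
    s <- svd(sg * X)           # G^(1/2) X, rows scaled
    pos <- s$d > max(s$d) * 1e-12
    # W = G^(1/2) U D^-1 V' Y'
    sg * (s$u[, pos, drop = FALSE] %*%
            ((crossprod(s$v[, pos, drop = FALSE], t(Y))) / s$d[pos]))
  }
  W <- irls_step(rep(1, d))    # minimum-Frobenius start
  obj <- sum(sqrt(rowSums(W^2)))
  trace <- obj
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    g <- 2 * sqrt(rowSums(W^2)) + eps
    W <- irls_step(g)
    obj_new <- sum(sqrt(rowSums(W^2)))
    trace <- c(trace, obj_new)
    if (abs(obj - obj_new) <= tol * max(obj, 1e-12)) {
      converged <- TRUE
      break
    }
    obj <- obj_new
  }
  if (!converged)
    warning("l21_select did not converge in ", max_iter,
            " iterations; returning best iterate")
  list(W = W, trace = trace, converged = converged, iterations = iter)
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf(
    "selection_result: %d features selected of %d | ||W||_21 = %.5g | residual = %.3g (%d IRLS iterations)\n",
    x$n_selected, length(x$row_norms), utils::tail(x$objective_trace, 1),
    x$residual, x$iterations))
  invisible(x)
}

#' Choose the number of selected features by leave-one-out cross-validation
#'
#' For each candidate count m: on every leave-one-out training fold, rank the
#' features by [l21_select()] row norm, keep the top m, fit ordinary least
#' squares from those features to the pathway labels, and score the held-out
#' subject by 0/1 label-prediction error at a 0.5 threshold. Returns the
#' candidate with the smallest mean LOOCV error; ties go to the smallest m.
#'
#' @param X features x subjects matrix.
#' @param Y targets x subjects binary label matrix.
#' @param candidate_counts candidate numbers of features.
#' @param ... passed to [l21_select()].
#' @return list with `best` (chosen count) and `errors` (named mean LOOCV
#'   error per candidate).
#' @export
loocv_feature_count <- function(X, Y, candidate_counts, ...) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  d <- nrow(X); n <- ncol(X)
  if (!length(candidate_counts)) stop("candidate_counts must be non-empty")
  cand <- sort(unique(as.integer(candidate_counts)))
  if (any(cand > d)) {
    warning("dropping candidate counts exceeding the number of features (",
            d, ")")
    cand <- cand[cand <= d]
  }
  if (!length(cand)) stop("no admissible candidate counts")
  err <- matrix(0, n, length(cand), dimnames = list(NULL, cand))
  for (i in seq_len(n)) {
    Xtr <- X[, -i, drop = FALSE]; Ytr <- Y[, -i, drop = FALSE]
    fit <- l21_select(Xtr, Ytr, ...)
    ranking <- order(fit$row_norms, decreasing = TRUE)
    for (ci in seq_along(cand)) {
      top <- ranking[seq_len(cand[ci])]
      A <- cbind(1, t(Xtr[top, , drop = FALSE]))      # subjects x (1+m)
      beta <- qr.coef(qr(A), t(Ytr))                  # (1+m) x targets
      beta[is.na(beta)] <- 0
      pred <- as.numeric(c(1, X[top, i]) %*% beta) > 0.5
      err[i, ci] <- mean(pred != (Y[, i] > 0.5))
    }
  }
  mean_err <- colMeans(err)
  list(best = cand[which.min(mean_err)],
       errors = stats::setNames(mean_err, cand))
}
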