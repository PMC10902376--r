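# Independent oracles used to pin expected values. Each deliberately avoids
# the code path of the function it checks.

# min ||W||_21 s.t. W'X = Y by direct optimization over the constraint
# manifold: W = W0 + N A with W0 a particular solution and N an orthonormal
# basis of the null space of X' (needs full column rank X, d >= n).
l21_oracle <- function(X, Y, n_starts = 8, seed = 1) {
  d <- nrow(X); n <- ncol(X); t_ <- nrow(Y)
  W0 <- X %*% solve(crossprod(X), t(Y))
  if (d == n) return(sum(sqrt(rowSums(W0^2))))
  N <- svd(X, nu = d)$u[, (n + 1):d, drop = FALSE]
  free <- (d - n) * t_
  obj <- function(par) {
    W <- W0 + N %*% matrix(par, d - n, t_)
    sum(sqrt(rowSums(W^2) + 1e-14))
  }
  set.seed(seed)
  best <- Inf
  for (s in seq_len(n_starts)) {
    par0 <- if (s == 1) rep(0, free) else stats::rnorm(free)
    for (m in c("BFGS", "Nelder-Mead")) {
      o <- tryCatch(stats::optim(par0, obj, method = m,
                                 control = list(maxit = 5000,
                                                reltol = 1e-14)),
                    error = function(e) NULL)
      if (!is.null(o)) {
        best <- min(best, o$value)
        par0 <- o$par    # polish with the other method
      }
    }
  }
  best
}

# two-sided Fisher exact p for table (a, b; c, d) by hypergeometric
# enumeration over all tables with the observed margins, summing the
# probabilities not exceeding the observed one (with the conventional
# relative slack for floating-point ties).
fisher_oracle <- function(a, b, c, d) {
  m <- a + b; n_ <- c + d; k <- a + c
  lo <- max(0L, k - n_); hi <- min(k, m)
  xs <- lo:hi
  logp <- lchoose(m, xs) + lchoose(n_, k - xs) - lchoose(m + n_, k)
  sum(exp(logp[logp <= logp[a - lo + 1] + log(1 + 1e-7)]))
}

# first canonical correlation of 2-column X, Y by grid search over unit
# coefficient vectors a = (cos t, sin t), b = (cos u, sin u).
cca_grid_oracle <- function(X, Y, n_grid = 1600L) {
  th <- seq(0, pi, length.out = n_grid)
  A <- rbind(cos(th), sin(th))
  U <- scale(X, scale = FALSE) %*% A
  V <- scale(Y, scale = FALSE) %*% A
  max(abs(stats::cor(U, V)))
}

# two-step similarity by literal term-by-term evaluation of the double sum
two_step_oracle <- function(Z) {
  n <- nrow(Z); K <- ncol(Z)
  colsum <- colSums(Z)
  S <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(K))
    S[i, j] <- S[i, j] + Z[i, k] * Z[j, k] / colsum[k]
  S
}

# random row-stochastic nonnegative matrix
random_row_stochastic <- function(n, K) {
  Z <- matrix(stats::rexp(n * K), n, K)
  Z / rowSums(Z)
}
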