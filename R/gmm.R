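# Weighted Gaussian mixture fitting by EM.
#
# Observation weights enter as multiplicities in the responsibilities and
# sufficient statistics; callers normalize weights to mean 1 for optimizer
# stability. Covariances are full, with a ridge added to the diagonal
# (escalated tenfold on Cholesky failure, flagged via $regularized).

# log N(x; mean, Sigma) for rows of X, given the upper Cholesky factor of Sigma
.log_dmvnorm <- function(X, mean, chol_cov) {
  z <- backsolve(chol_cov, t(X) - mean, transpose = TRUE)
  -0.5 * colSums(z^2) - sum(log(diag(chol_cov))) -
    0.5 * ncol(X) * log(2 * pi)
}

.logsumexp_rows <- function(L) {
  m <- apply(L, 1, max)
  m + log(rowSums(exp(L - m)))
}

.safe_chol <- function(S, ridge) {
  d <- nrow(S)
  reg <- FALSE
  for (i in 0:6) {
    r <- ridge * 10^i
    ch <- tryCatch(chol(S + diag(r, d)), error = function(e) NULL)
    if (!is.null(ch)) return(list(chol = ch, regularized = reg || i > 0))
    reg <- TRUE
  }
  stop("singular component covariance: regularization failed")
}

# X: n x d, w: weights (mean approximately 1), K components.
.fit_wgmm <- function(X, w, K, ridge = 1e-6, max_iter = 200, tol = 1e-8) {
  X <- as.matrix(X)
  n <- nrow(X); d <- ncol(X)
  if (n < K) stop("input error: fewer observations than mixture components")
  regularized <- FALSE

  if (K == 1) {
    resp <- matrix(1, n, 1)
  } else {
    km <- tryCatch(
      kmeans(X, centers = K, nstart = 5, iter.max = 50),
      error = function(e) NULL
    )
    assign <- if (is.null(km)) ((seq_len(n) - 1) %% K) + 1 else km$cluster
    resp <- matrix(0, n, K)
    resp[cbind(seq_len(n), assign)] <- 1
  }

  pi_k <- numeric(K)
  means <- vector("list", K)
  chols <- vector("list", K)
  ll_old <- -Inf
  iter <- 0
  repeat {
    iter <- iter + 1
    # M step
    wr <- w * resp
    Nk <- colSums(wr)
    Nk[Nk < 1e-12] <- 1e-12
    pi_k <- Nk / sum(w)
    for (k in seq_len(K)) {
      mu <- colSums(X * wr[, k]) / Nk[k]
      Xc <- sweep(X, 2, mu)
      S <- crossprod(Xc * wr[, k], Xc) / Nk[k]
      sc <- .safe_chol(S, ridge)
      regularized <- regularized || sc$regularized
      means[[k]] <- mu
      chols[[k]] <- sc$chol
    }
    # E step
    L <- vapply(seq_len(K), function(k) {
      log(pi_k[k]) + .log_dmvnorm(X, means[[k]], chols[[k]])
    }, numeric(n))
    L <- matrix(L, n, K)
    lse <- .logsumexp_rows(L)
    ll <- sum(w * lse)
    resp <- exp(L - lse)
    if (abs(ll - ll_old) < tol * (abs(ll) + 1) || iter >= max_iter) break
    ll_old <- ll
  }
  list(weights = pi_k, means = means, chols = chols,
       loglik = ll, iterations = iter, converged = iter < max_iter,
       regularized = regularized)
}

# mixture log density of rows of X under a fitted component list
.wgmm_logdens <- function(model, X) {
  X <- as.matrix(X)
  K <- length(model$weights)
  L <- vapply(seq_len(K), function(k) {
    log(model$weights[k]) + .log_dmvnorm(X, model$means[[k]], model$chols[[k]])
  }, numeric(nrow(X)))
  .logsumexp_rows(matrix(L, nrow(X), K))
}
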