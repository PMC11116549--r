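# Newton-Raphson maximum likelihood for the baseline-category (multinomial)
# logit. The binary logistic outcome model is the two-class special case, so a
# single solver backs both nuisance models. Convergence is declared on the
# score norm (max |score| < tol_score) or on a vanishing Newton step, which
# makes refits deterministic and order-invariant to ~1e-8.

# Class probabilities for coefficient matrix beta (p x (K-1)); column j is the
# coefficient vector of class j vs class 0. Softmax with max-subtraction.
mlogit_probs <- function(X, beta) {
  eta <- cbind(0, X %*% beta, deparse.level = 0)
  m <- eta[cbind(seq_len(nrow(eta)), max.col(eta, ties.method = "first"))]
  e <- exp(eta - m)
  e / rowSums(e)
}

# X: n x p design (with intercept column); y: integer classes in 0..K-1.
# ridge: L2 penalty (0 = plain MLE). Returns coefficients, penalized loglik,
# convergence metadata. Errors are left to callers, which know the context
# (empty arm vs single-class outcome etc.).
mlogit_newton <- function(X, y, K, ridge = 0, max_iter = 100L,
                          tol_score = 1e-8, tol_step = 1e-10,
                          beta_init = NULL) {
  n <- nrow(X)
  p <- ncol(X)
  stopifnot(length(y) == n, all(y %in% 0:(K - 1)))
  Yind <- matrix(0, n, K - 1L)
  for (j in seq_len(K - 1L)) Yind[, j] <- as.numeric(y == j)

  beta <- if (is.null(beta_init)) matrix(0, p, K - 1L)
          else matrix(beta_init, p, K - 1L)
  own <- cbind(seq_len(n), y + 1L)
  pll <- function(P, beta) {
    sum(log(pmax(P[own], 1e-300))) - ridge / 2 * sum(beta^2)
  }
  P <- mlogit_probs(X, beta)
  ll <- pll(P, beta)
  converged <- FALSE
  score_norm <- Inf
  iter <- 0L

  while (iter < max_iter) {
    iter <- iter + 1L
    Pj <- P[, -1L, drop = FALSE]
    # score (stacked by class), with ridge
    G <- crossprod(X, Yind - Pj) - ridge * beta
    score_norm <- max(abs(G))
    if (score_norm < tol_score) {
      converged <- TRUE
      break
    }
    # Fisher information: blocks H[j,l] = X' diag(P_j (d_jl - P_l)) X
    m <- p * (K - 1L)
    H <- matrix(0, m, m)
    for (j in seq_len(K - 1L)) {
      for (l in j:(K - 1L)) {
        w <- if (j == l) Pj[, j] * (1 - Pj[, j]) else -Pj[, j] * Pj[, l]
        blk <- crossprod(X, X * w)
        rj <- (j - 1L) * p + seq_len(p)
        rl <- (l - 1L) * p + seq_len(p)
        H[rj, rl] <- blk
        if (l != j) H[rl, rj] <- t(blk)
      }
    }
    if (ridge > 0) H <- H + diag(ridge, m)
    step <- tryCatch(solve(H, as.vector(G)), error = function(e) NULL)
    if (is.null(step)) {
      # singular information: fall back to a tiny ridge for this step only
      step <- solve(H + diag(1e-8 * max(diag(H)), m), as.vector(G))
    }
    step <- matrix(step, p, K - 1L)
    # step-halving on the penalized likelihood
    t_fac <- 1
    repeat {
      beta_new <- beta + t_fac * step
      P_new <- mlogit_probs(X, beta_new)
      ll_new <- pll(P_new, beta_new)
      if (ll_new >= ll - 1e-12 || t_fac < 1e-4) break
      t_fac <- t_fac / 2
    }
    moved <- max(abs(beta_new - beta))
    beta <- beta_new
    P <- P_new
    ll <- ll_new
    if (moved < tol_step) {
      converged <- TRUE
      break
    }
  }

  dimnames(beta) <- list(colnames(X), paste0("class", seq_len(K - 1L)))
  list(beta = beta, loglik = ll, converged = converged, n_iter = iter,
       score_norm = score_norm)
}
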