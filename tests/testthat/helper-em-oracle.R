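# independent reference implementations used as oracles: deliberately naive
# (explicit inverses, per-point loops), sharing no code with the package

naive_dmvnorm <- function(x, mu, S) {
  J <- length(mu)
  d <- x - mu
  as.numeric(exp(-0.5 * t(d) %*% solve(S) %*% d) /
               sqrt((2 * pi)^J * det(S)))
}

naive_mixture_loglik <- function(X, p, mus, covs) {
  sum(apply(X, 1, function(x)
    log(sum(vapply(seq_along(p), function(k)
      p[k] * naive_dmvnorm(x, mus[[k]], covs[[k]]), 0)))))
}

# plain unlabeled Gaussian-mixture EM from given starting values
naive_gmm_em <- function(X, p, mus, covs, max_iter = 2000, tol = 1e-10) {
  n <- nrow(X); K <- length(p)
  ll_old <- -Inf
  for (it in 1:max_iter) {
    W <- matrix(0, n, K)
    for (i in 1:n) for (k in 1:K)
      W[i, k] <- p[k] * naive_dmvnorm(X[i, ], mus[[k]], covs[[k]])
    ll <- sum(log(rowSums(W)))
    W <- W / rowSums(W)
    if (abs(ll - ll_old) < tol * (abs(ll_old) + 1e-3)) break
    ll_old <- ll
    for (k in 1:K) {
      wk <- W[, k]
      p[k] <- mean(wk)
      mus[[k]] <- colSums(X * wk) / sum(wk)
      D <- sweep(X, 2, mus[[k]])
      covs[[k]] <- crossprod(D * sqrt(wk)) / sum(wk)
    }
    p <- p / sum(p)
  }
  list(p = p, mus = mus, covs = covs, loglik = ll)
}
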