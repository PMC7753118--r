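# Independent oracles used across tests. These deliberately avoid the
# package's own code paths: plain normal equations for least squares, and
# direct numerical minimization of the penalized objective for the elastic
# net.

# OLS via explicit normal equations (coefficients, standard errors)
ols_oracle <- function(D, y) {
  DtD <- crossprod(D)
  b <- solve(DtD, crossprod(D, y))
  res <- y - D %*% b
  df <- length(y) - ncol(D)
  sigma2 <- sum(res^2) / df
  se <- sqrt(sigma2 * diag(solve(DtD)))
  list(b = drop(b), se = se, sigma2 = sigma2, df = df)
}

# The penalized objective the solver claims to minimize
enet_objective_r <- function(X, y, b0, beta, lambda, alpha,
                             pf = rep(1, ncol(X))) {
  r <- y - b0 - X %*% beta
  sum(r^2) / (2 * length(y)) +
    lambda * sum(pf * (alpha * abs(beta) + (1 - alpha) / 2 * beta^2))
}

# Brute-force minimizer: multi-start Nelder-Mead over (b0, beta).
# Practical for p <= 3, n <= 10.
enet_brute <- function(X, y, lambda, alpha, pf = rep(1, ncol(X)),
                       n_starts = 30) {
  p <- ncol(X)
  obj <- function(par) enet_objective_r(X, y, par[1], par[-1], lambda, alpha, pf)
  best <- NULL
  set.seed(99)
  starts <- rbind(rep(0, p + 1),
                  matrix(rnorm(n_starts * (p + 1), 0, 2), n_starts))
  for (i in seq_len(nrow(starts))) {
    fit <- optim(starts[i, ], obj, method = "Nelder-Mead",
                 control = list(maxit = 50000, reltol = 1e-14))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  list(intercept = best$par[1], beta = best$par[-1], value = best$value)
}
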