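# Independent oracles used to check the package's fitting routines.

# Newton-Raphson maximisation of the binomial log-likelihood
#   l(beta) = sum(s * eta - t * log(1 + exp(eta))),  eta = X beta,
# written directly from the likelihood, independent of the IRLS path used
# by the package.  Returns the coefficient vector (intercept, x, ...).
nr_logit_oracle <- function(successes, total, x, covariates = NULL,
                            iters = 100) {
  X <- cbind(1, x)
  if (!is.null(covariates)) X <- cbind(X, covariates)
  beta <- rep(0, ncol(X))
  for (i in seq_len(iters)) {
    eta <- as.numeric(X %*% beta)
    p <- 1 / (1 + exp(-eta))
    grad <- as.numeric(crossprod(X, successes - total * p))
    H <- crossprod(X, X * (total * p * (1 - p)))
    step <- solve(H, grad)
    beta <- beta + step
    if (max(abs(step)) < 1e-13) break
  }
  as.numeric(beta)
}

# Normal-equations least squares: beta = (X'X)^{-1} X'y.
ols_oracle <- function(X, y) {
  as.numeric(solve(t(X) %*% X, t(X) %*% y))
}

# VanRaden's first relationship-matrix construction on individual
# genotypes, coded directly from its definition.
vanraden_oracle <- function(dosage) {
  pbar <- colMeans(dosage) / 2
  use <- pbar > 0 & pbar < 1
  M <- sweep(dosage[, use, drop = FALSE], 2, 2 * pbar[use])
  tcrossprod(M) / (2 * sum(pbar[use] * (1 - pbar[use])))
}
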