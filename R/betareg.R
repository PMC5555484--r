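# Beta regression with logit mean link, estimated by full maximum
# likelihood. Used for proportion-family traits. Parameterization:
#   y ~ Beta(mu * phi, (1 - mu) * phi),  logit(mu) = X beta,  phi > 0
# with phi the precision; var(y) = mu (1 - mu) / (1 + phi). phi is estimated
# on the log scale jointly with beta; standard errors come from the inverse
# observed-information (Hessian) matrix.

beta_nll <- function(par, X, y) {
  p <- ncol(X)
  mu <- stats::plogis(drop(X %*% par[seq_len(p)]))
  phi <- exp(par[p + 1L])
  mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
  -sum(stats::dbeta(y, mu * phi, (1 - mu) * phi, log = TRUE))
}

beta_nll_grad <- function(par, X, y) {
  p <- ncol(X)
  eta <- drop(X %*% par[seq_len(p)])
  mu <- stats::plogis(eta)
  mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
  phi <- exp(par[p + 1L])
  ystar <- log(y) - log1p(-y)                 # logit(y)
  mustar <- digamma(mu * phi) - digamma((1 - mu) * phi)
  dmu <- phi * (ystar - mustar) * mu * (1 - mu)   # dll/deta
  dphi <- mu * (ystar - mustar) + log1p(-y) -
    digamma((1 - mu) * phi) + digamma(phi)
  c(-drop(crossprod(X, dmu)), -sum(dphi) * phi)
}

fit_beta_ml <- function(X, y, maxit = 200L, tol = 1e-8) {
  if (any(y <= 0 | y >= 1))
    ml_stop("ml_domain_error",
            "beta fit requires responses strictly inside (0,1); shrink boundary values first")
  p <- ncol(X)
  # moment / OLS-on-logit starting values
  lm0 <- stats::lm.fit(X, stats::qlogis(y))
  mu0 <- stats::plogis(lm0$fitted.values)
  v0 <- max(stats::var(y - mu0 * 0), 1e-6)
  phi0 <- max(mean(mu0 * (1 - mu0)) / v0 - 1, 1)
  start <- c(lm0$coefficients, log(phi0))
  start[!is.finite(start)] <- 0

  opt <- stats::optim(start, beta_nll, gr = beta_nll_grad, X = X, y = y,
                      method = "BFGS", hessian = TRUE,
                      control = list(maxit = maxit, reltol = tol))
  H <- opt$hessian
  V <- try(solve(H), silent = TRUE)
  ok <- opt$convergence == 0L && !inherits(V, "try-error") &&
    all(is.finite(V)) && all(diag(V) > 0)
  if (!ok)
    ml_stop("ml_fit_error", "beta regression did not converge")
  cf <- opt$par[seq_len(p)]
  names(cf) <- colnames(X)
  se <- sqrt(diag(V)[seq_len(p)])
  names(se) <- colnames(X)
  list(coefficients = cf, standard_errors = se,
       vcov = V[seq_len(p), seq_len(p), drop = FALSE],
       phi = exp(opt$par[p + 1L]),
       log_likelihood = -opt$value,
       n_params = p + 1L)
}

# Shrink proportion observations away from the {0,1} boundary using the
# per-record cell count n: (y (n - 1) + 0.5) / n. Applied to every value so
# the transform is monotone and shared across records.
shrink_proportion <- function(y, n) {
  (y * (n - 1) + 0.5) / n
}
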