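# Independent oracles used to freeze expected values. These deliberately use
# different machinery (quadrature, enumeration, closed forms) than the code
# paths they check.

# Central finite-difference Jacobian of a vector-valued function.
fd_jacobian <- function(g, theta, step = 1e-6) {
  n <- length(g(theta))
  J <- matrix(0, n, length(theta))
  for (j in seq_along(theta)) {
    e <- rep(0, length(theta)); e[j] <- step
    J[, j] <- (g(theta + e) - g(theta - e)) / (2 * step)
  }
  J
}

# Conjugate closed form for the linear-Gaussian model y = X theta + e,
# e ~ N(0, I / tau), theta ~ N(mu0, S0): posterior moments and exact log
# evidence.
conjugate_linear_oracle <- function(X, y, mu0, S0, tau) {
  n <- nrow(X)
  P <- tau * crossprod(X) + solve(S0)
  V <- solve(P)
  m <- as.numeric(V %*% (tau * crossprod(X, y) + solve(S0, mu0)))
  Sig <- X %*% S0 %*% t(X) + diag(n) / tau
  ld <- as.numeric(determinant(Sig, logarithm = TRUE)$modulus)
  r <- as.numeric(y - X %*% mu0)
  logev <- -0.5 * (n * log(2 * pi) + ld + sum(r * solve(Sig, r)))
  list(mean = m, cov = V, logev = logev)
}

# 1-D Bayesian model reduction by brute-force quadrature: given posterior
# q = N(mq, vq) obtained under prior N(m0, v0), swap in prior N(mr, vr).
# dF = log integral q(t) * N(t; mr, vr) / N(t; m0, v0) dt; reduced posterior
# moments by weighted integrals.
bmr_quadrature_1d <- function(mq, vq, m0, v0, mr, vr) {
  w <- function(t) {
    exp(dnorm(t, mq, sqrt(vq), log = TRUE) +
          dnorm(t, mr, sqrt(vr), log = TRUE) -
          dnorm(t, m0, sqrt(v0), log = TRUE))
  }
  lim <- c(-40, 40)
  Z <- integrate(w, lim[1], lim[2], rel.tol = 1e-12, abs.tol = 1e-14)$value
  mu <- integrate(function(t) t * w(t), lim[1], lim[2], rel.tol = 1e-12)$value / Z
  v <- integrate(function(t) (t - mu)^2 * w(t), lim[1], lim[2],
                 rel.tol = 1e-12)$value / Z
  list(dF = log(Z), mean = mu, var = v)
}

# AUC by exhaustive enumeration of positive-negative pairs (ties count 1/2).
brute_auc <- function(scores, labels) {
  sp <- scores[labels == 1]
  sn <- scores[labels == 0]
  tot <- 0
  for (a in sp) for (b in sn) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

# Small synthetic linear-Gaussian hierarchy for PEB checks: subjects have
# true parameters a + b * x_k plus random effects; "first-level posteriors"
# are exact Gaussians around noisy observations of those parameters.
make_linear_hierarchy <- function(K = 24, p = 2, a = c(0.5, -0.2),
                                  b = c(0.8, 0), re_sd = 0.2, obs_sd = 0.05,
                                  prior_var = 3) {
  x <- runif(K, -1, 1)
  posts <- lapply(seq_len(K), function(k) {
    th <- a + b * x[k] + rnorm(p, 0, re_sd)
    list(mean = th + rnorm(p, 0, obs_sd), cov = diag(obs_sd^2, p),
         free_energy = 0)
  })
  list(x = x, posteriors = posts,
       priors = prior_spec(rep(0, p), diag(prior_var, p)), a = a, b = b)
}
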