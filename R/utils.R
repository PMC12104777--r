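# Internal numerical helpers shared across modules.

# Symmetrise a matrix (guards against round-off drift before chol()).
.sym <- function(M) (M + t(M)) / 2

# Log-determinant of a symmetric positive-definite matrix via Cholesky.
.logdet <- function(M) {
  2 * sum(log(diag(chol(.sym(M)))))
}

# Inverse of a symmetric positive-definite matrix via Cholesky.
.spd_inv <- function(M) {
  chol2inv(chol(.sym(M)))
}

# KL(N(m1,S1) || N(m0,S0)) for multivariate Gaussians; always >= 0.
.gaussian_kl <- function(m1, S1, m0, S0) {
  m1 <- as.numeric(m1)
  m0 <- as.numeric(m0)
  S1 <- as.matrix(S1)
  S0 <- as.matrix(S0)
  p <- length(m1)
  P0 <- .spd_inv(S0)
  d <- m1 - m0
  kl <- 0.5 * (sum(P0 * S1) + sum(d * (P0 %*% d)) - p + .logdet(S0) - .logdet(S1))
  max(kl, 0)
}

.is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
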