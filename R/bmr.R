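#' Gaussian Bayesian model reduction
#'
#' Given a Gaussian posterior obtained under a full prior, compute
#' analytically the posterior and the change in log evidence that would have
#' resulted from a different (reduced) prior over the same parameters. Writing
#' precisions `Pq = V^-1`, `P0`, `Pr` for posterior, full prior and reduced
#' prior, the reduced posterior precision is `Pq + Pr - P0` and
#' \deqn{\Delta F = \tfrac12\left[\ln|Pq| + \ln|Pr| - \ln|P0| - \ln|Pr'|
#'  + \tilde m' Pr' \tilde m - m' Pq m - \mu_r' Pr \mu_r + \mu_0' P0 \mu_0\right]}
#' with `Pr'` the reduced posterior precision and `\tilde m` its mean.
#'
#' @param post A `bsd_posterior` (or any list with `mean`, `cov`).
#' @param prior The [prior_spec()] the posterior was estimated under.
#' @param reduced_prior The alternative [prior_spec()] (same dimension).
#' @return List with `posterior` (list `mean`, `cov`), `dF` (change in log
#'   evidence) and `free_energy` (`post$free_energy + dF` when available).
#' @examples
#' pr <- prior_spec(0, 1)
#' post <- list(mean = 0.5, cov = matrix(0.5), free_energy = 0)
#' bmr_reduce(post, pr, prior_spec(0, 0.25))$dF
#' @export
bmr_reduce <- function(post, prior, reduced_prior) {
  m <- as.numeric(post$mean)
  V <- as.matrix(post$cov)
  mu0 <- as.numeric(prior$mean)
  S0 <- as.matrix(prior$cov)
  mur <- as.numeric(reduced_prior$mean)
  Sr <- as.matrix(reduced_prior$cov)
  p <- length(m)
  if (length(mu0) != p || length(mur) != p) {
    .stopf("prior dimensions must match the posterior (%d)", p)
  }
  Pq <- .spd_inv(V)
  P0 <- .spd_inv(S0)
  Pr <- .spd_inv(Sr)
  Pq_r <- .sym(Pq + Pr - P0)
  ch <- tryCatch(chol(Pq_r), error = function(e) NULL)
  if (is.null(ch)) {
    .stopf("reduction invalid: reduced posterior precision is not positive definite")
  }
  h <- Pq %*% m + Pr %*% mur - P0 %*% mu0
  m_r <- as.numeric(chol2inv(ch) %*% h)
  dF <- 0.5 * (.logdet(Pq) + .logdet(Pr) - .logdet(P0) - .logdet(Pq_r) +
                 sum(m_r * (Pq_r %*% m_r)) - sum(m * (Pq %*% m)) -
                 sum(mur * (Pr %*% mur)) + sum(mu0 * (P0 %*% mu0)))
  F_red <- if (!is.null(post$free_energy)) post$free_energy + dF else NULL
  list(posterior = list(mean = m_r, cov = chol2inv(ch)), dF = dF,
       free_energy = F_red)
}
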