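#' Construct a prior specification
#'
#' Gaussian priors over the unconstrained parameters plus an independent
#' Gaussian prior over the noise log-precision.
#'
#' @param mean Prior mean vector.
#' @param cov Prior covariance (matrix, or vector of variances for a
#'   diagonal prior).
#' @param hyper_mean,hyper_var Prior mean/variance of the noise log-precision.
#' @return An object of class `bsd_priors`.
#' @export
prior_spec <- function(mean, cov, hyper_mean = 0, hyper_var = 1) {
  mean <- as.numeric(mean)
  if (is.null(dim(cov))) cov <- diag(as.numeric(cov), nrow = length(cov))
  cov <- as.matrix(cov)
  if (nrow(cov) != length(mean) || ncol(cov) != length(mean)) {
    .stopf("prior cov must be %d x %d", length(mean), length(mean))
  }
  if (!isTRUE(all.equal(cov, t(cov), tolerance = 1e-8))) {
    .stopf("prior cov must be symmetric")
  }
  ch <- tryCatch(chol(.sym(cov)), error = function(e) NULL)
  if (is.null(ch)) .stopf("prior cov must be positive definite")
  if (!.is_number(hyper_var) || hyper_var <= 0) .stopf("hyper_var must be > 0")
  structure(
    list(mean = mean, cov = .sym(cov), hyper_mean = hyper_mean,
         hyper_var = hyper_var),
    class = "bsd_priors"
  )
}

#' Default priors for a spectral model
#'
#' All unconstrained parameters have prior mean 0. Prior variances are 3 for
#' the aperiodic power and exponent and 2 for peak height, centre and width;
#' the noise log-precision prior is N(0, 1). With a condition design the same
#' pattern is applied to every design block (baseline and deltas).
#'
#' @param spec A [model_spec()].
#' @param aperiodic_var,peak_var,hyper_mean,hyper_var Override the defaults.
#' @return A [prior_spec()].
#' @examples
#' default_priors(model_spec(list(band("alpha", 8, 12), band("beta", 12, 30))))
#' @export
default_priors <- function(spec, aperiodic_var = 3, peak_var = 2,
                           hyper_mean = 0, hyper_var = 1) {
  v_base <- c(aperiodic_var, aperiodic_var,
              rep(peak_var, 3L * length(spec$bands)))
  p <- n_params(spec)
  v <- rep(v_base, length.out = p)
  prior_spec(mean = rep(0, p), cov = v, hyper_mean = hyper_mean,
             hyper_var = hyper_var)
}

#' @export
print.bsd_priors <- function(x, ...) {
  cat(sprintf("<priors: %d parameters, lambda ~ N(%g, %g)>\n",
              length(x$mean), x$hyper_mean, x$hyper_var))
  invisible(x)
}
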