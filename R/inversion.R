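#' Options controlling variational-Laplace inversion
#'
#' @param max_iter Maximum number of outer iterations.
#' @param tol_df Convergence tolerance: stop when `|dF| < tol_df` on three
#'   consecutive accepted iterations.
#' @param damping_init Initial Levenberg-Marquardt damping (multiplied by 8
#'   when a step is rejected, halved when accepted).
#' @param jacobian `"analytic"` (default) or `"finite_diff"`.
#' @param fd_step Central-difference step on the unconstrained scale.
#' @return An object of class `bsd_fit_options`.
#' @export
fit_options <- function(max_iter = 128L, tol_df = 1e-3, damping_init = 1e-2,
                        jacobian = c("analytic", "finite_diff"),
                        fd_step = 1e-4) {
  jacobian <- match.arg(jacobian)
  if (max_iter < 1L) .stopf("max_iter must be >= 1")
  if (tol_df <= 0) .stopf("tol_df must be > 0")
  structure(
    list(max_iter = as.integer(max_iter), tol_df = tol_df,
         damping_init = damping_init, jacobian = jacobian, fd_step = fd_step),
    class = "bsd_fit_options"
  )
}

# Free-energy decomposition used by the inner loop.
#   accuracy = E_q[ln p(y | theta, lambda)]
#            = -n/2 ln(2*pi) + n/2 E[lambda] - 1/2 ln|R|
#              - 1/2 E[exp(lambda)] * (r' Rinv r + tr(J' Rinv J V))
#   complexity terms are KL(posterior || prior) for theta and lambda.
.vl_F <- function(E2, n, l, v, logdetR, m, V, mu0, S0, lmu, lvar,
                  lambda_fixed) {
  tau <- exp(l + v / 2)
  accuracy <- -n / 2 * log(2 * pi) + n / 2 * l - logdetR / 2 - tau * E2 / 2
  c_theta <- .gaussian_kl(m, V, mu0, S0)
  c_lambda <- if (lambda_fixed) 0 else {
    max(0.5 * (v / lvar + (l - lmu)^2 / lvar - 1 + log(lvar / v)), 0)
  }
  list(F = accuracy - c_theta - c_lambda, accuracy = accuracy,
       complexity_theta = c_theta, complexity_lambda = c_lambda)
}

# Newton maximisation of the variational energy of lambda given E2:
#   f(l) = n/2 l - 1/2 exp(l + v/2) E2 - (l - lmu)^2 / (2 lvar)
# Concave in l; posterior variance v = -1/f''(l).
.vl_lambda_update <- function(E2, n, lmu, lvar, l_init = lmu) {
  l <- l_init
  v <- 0
  for (outer in 1:4) {
    for (it in 1:100) {
      e <- exp(min(l + v / 2, 700))
      g1 <- n / 2 - e * E2 / 2 - (l - lmu) / lvar
      g2 <- -e * E2 / 2 - 1 / lvar
      dl <- -g1 / g2
      dl <- max(min(dl, 4), -4)
      l <- l + dl
      if (abs(dl) < 1e-10) break
    }
    e <- exp(min(l + v / 2, 700))
    v_new <- 1 / (e * E2 / 2 + 1 / lvar)
    if (abs(v_new - v) < 1e-12) { v <- v_new; break }
    v <- v_new
  }
  list(l = l, v = v)
}

#' Variational-Laplace fit of a nonlinear Gaussian model
#'
#' Inverts the observation model `y = g(theta) + e`,
#' `e ~ N(0, exp(-lambda) R)`, with Gaussian priors on `theta` and on the
#' noise log-precision `lambda`, using a fixed-form Gaussian approximate
#' posterior. Gauss-Newton steps on `theta` (Levenberg-Marquardt damped)
#' alternate with Newton updates of the `lambda` variational energy; a joint
#' step is accepted only if the free energy increases, so the free energy is
#' non-decreasing over accepted iterations.
#'
#' This is the generic engine; [fit_spectrum()] wraps it for spectral models.
#'
#' @param y Observed data vector.
#' @param g Forward model: function of `theta` returning predictions.
#' @param jac Jacobian: function of `theta` returning the `n x p` matrix of
#'   derivatives (`NULL` to use central finite differences on `g`).
#' @param prior_mean,prior_cov Gaussian prior over `theta`.
#' @param R Noise correlation matrix (`NULL` = identity).
#' @param lambda_prior `c(mean, variance)` of the log-precision prior.
#' @param lambda_fixed If non-`NULL`, the log-precision is clamped to this
#'   value (known noise) and gets zero complexity.
#' @param init Optional start for the posterior mean search (default: the
#'   prior mean). The free energy, not the start, decides what is reported,
#'   so alternative starts are a device against local optima only.
#' @param opts [fit_options()].
#' @return An object of class `bsd_posterior` with fields `mean`, `cov`,
#'   `lambda_mean`, `lambda_var`, `free_energy`, `accuracy`,
#'   `complexity_theta`, `complexity_lambda`, `n_iter`, `converged`, and
#'   `F_trace` (free energy after each accepted step; non-decreasing).
#' @export
vl_fit <- function(y, g, jac = NULL, prior_mean, prior_cov, R = NULL,
                   lambda_prior = c(0, 1), lambda_fixed = NULL,
                   init = NULL, opts = fit_options()) {
  y <- as.numeric(y)
  n <- length(y)
  if (any(!is.finite(y))) .stopf("data must be finite")
  mu0 <- as.numeric(prior_mean)
  S0 <- as.matrix(prior_cov)
  p <- length(mu0)
  P0 <- .spd_inv(S0)
  if (is.null(jac)) {
    fd <- opts$fd_step
    jac <- function(th) {
      J <- matrix(0, n, p)
      for (j in seq_len(p)) {
        e <- rep(0, p); e[j] <- fd
        J[, j] <- (g(th + e) - g(th - e)) / (2 * fd)
      }
      J
    }
  }
  if (!is.null(R)) {
    Rinv <- .spd_inv(R)
    logdetR <- .logdet(R)
  } else {
    Rinv <- NULL
    logdetR <- 0
  }
  lmu <- lambda_prior[1]
  lvar <- lambda_prior[2]
  fixed <- !is.null(lambda_fixed)

  # weighted quadratic forms under the noise correlation
  quads <- function(r, J) {
    if (is.null(Rinv)) {
      list(rtr = sum(r^2), JtR = t(J), JtRJ = crossprod(J), Jtr = crossprod(J, r))
    } else {
      RJ <- Rinv %*% J
      list(rtr = sum(r * (Rinv %*% r)), JtR = t(RJ), JtRJ = crossprod(J, RJ),
           Jtr = crossprod(RJ, r))
    }
  }

  state_at <- function(m, l_init) {
    pred <- g(m)
    if (any(!is.finite(pred))) return(NULL)
    r <- y - pred
    J <- jac(m)
    if (any(!is.finite(J))) return(NULL)
    q <- quads(r, J)
    list(m = m, r = r, J = J, q = q)
  }

  finish_state <- function(st, l_prev) {
    # given location st, update (V, lambda) self-consistently and score F
    l <- if (fixed) lambda_fixed else l_prev
    v <- 0
    for (rep in 1:3) {
      tau <- exp(l + v / 2)
      H <- .sym(tau * st$q$JtRJ + P0)
      ch <- tryCatch(chol(H), error = function(e) NULL)
      if (is.null(ch)) return(NULL)
      V <- chol2inv(ch)
      E2 <- st$q$rtr + sum(st$q$JtRJ * V)
      if (fixed) { break }
      up <- .vl_lambda_update(E2, n, lmu, lvar, l_init = l)
      if (abs(up$l - l) < 1e-9 && rep > 1) { l <- up$l; v <- up$v; break }
      l <- up$l; v <- up$v
    }
    if (fixed) { l <- lambda_fixed; v <- 0 }
    tau <- exp(l + v / 2)
    H <- .sym(tau * st$q$JtRJ + P0)
    ch <- tryCatch(chol(H), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    V <- chol2inv(ch)
    E2 <- st$q$rtr + sum(st$q$JtRJ * V)
    fe <- .vl_F(E2, n, l, v, logdetR, st$m, V, mu0, S0, lmu, lvar, fixed)
    c(st, list(V = V, H = H, l = l, v = v, E2 = E2, fe = fe))
  }

  start <- if (is.null(init)) mu0 else as.numeric(init)
  if (length(start) != p) .stopf("init must have length %d", p)
  cur <- state_at(start, lmu)
  if (is.null(cur)) .stopf("forward model not finite at the start")
  cur <- finish_state(cur, if (fixed) lambda_fixed else lmu)
  if (is.null(cur)) .stopf("singular curvature at the start")

  damping <- opts$damping_init
  converged <- FALSE
  n_ok <- 0L
  iter <- 0L
  F_trace <- cur$fe$F
  while (iter < opts$max_iter) {
    iter <- iter + 1L
    tau <- exp(cur$l + cur$v / 2)
    grad <- tau * cur$q$Jtr - P0 %*% (cur$m - mu0)
    H <- .sym(tau * cur$q$JtRJ + P0)
    accepted <- FALSE
    dF <- 0
    for (try in 1:12) {
      Hd <- H + damping * diag(diag(H), nrow = p)
      dm <- tryCatch(solve(Hd, grad), error = function(e) NULL)
      if (!is.null(dm)) {
        st <- state_at(cur$m + as.numeric(dm), cur$l)
        if (!is.null(st)) st <- finish_state(st, cur$l)
        if (!is.null(st) && is.finite(st$fe$F) && st$fe$F > cur$fe$F) {
          dF <- st$fe$F - cur$fe$F
          cur <- st
          damping <- max(damping / 2, 1e-8)
          accepted <- TRUE
          break
        }
      }
      damping <- damping * 8
      if (damping > 1e10) break
    }
    if (!accepted) { converged <- TRUE; break }
    F_trace <- c(F_trace, cur$fe$F)
    n_ok <- if (abs(dF) < opts$tol_df) n_ok + 1L else 0L
    if (n_ok >= 3L) { converged <- TRUE; break }
  }

  structure(
    list(mean = as.numeric(cur$m), cov = cur$V,
         lambda_mean = cur$l, lambda_var = cur$v,
         free_energy = cur$fe$F, accuracy = cur$fe$accuracy,
         complexity_theta = cur$fe$complexity_theta,
         complexity_lambda = cur$fe$complexity_lambda,
         n_iter = iter, converged = converged, F_trace = F_trace),
    class = "bsd_posterior"
  )
}

#' @export
print.bsd_posterior <- function(x, ...) {
  cat(sprintf(
    "<posterior: %d parameters, F = %.3f (accuracy %.3f, complexity %.3f + %.3f), %d iter%s>\n",
    length(x$mean), x$free_energy, x$accuracy, x$complexity_theta,
    x$complexity_lambda, x$n_iter, if (x$converged) "" else " (not converged)"
  ))
  invisible(x)
}

#' Fit a spectral model to observed spectra
#'
#' Inverts a [model_spec()] on one observed spectrum (or one spectrum per
#' condition) with variational Laplace. By default the data are first scaled
#' to the reference signal variance (see [scale_spectrum()]); the factor is
#' recorded on the returned posterior.
#'
#' @param y Observed spectrum: numeric vector, or `n_freq x n_conditions`
#'   matrix when `spec` has a condition design.
#' @param freqs Frequencies in Hz matching `y` rows.
#' @param spec A [model_spec()].
#' @param priors A [prior_spec()]; defaults to [default_priors()].
#' @param noise Optional [noise_model()] supplying the correlation `R`.
#' @param scale Scale the data to the reference variance before fitting.
#' @param lambda_fixed Optional fixed noise log-precision.
#' @param init Optional start for the search on the unconstrained scale (on
#'   the scaled-data scale when `scale = TRUE`); default is the prior mean.
#' @param opts [fit_options()].
#' @return A `bsd_posterior` with extra fields `spec`, `freqs`,
#'   `scale_factor` and `param_names`.
#' @examples
#' sp <- model_spec(list(band("alpha", 8, 12)))
#' f <- seq(2, 30, 0.5)
#' y <- evaluate_spectrum(apply_links(c(0, 0, 0, 0, 0), sp$bands), f)
#' post <- fit_spectrum(y, f, sp, scale = FALSE)
#' @export
fit_spectrum <- function(y, freqs, spec, priors = NULL, noise = NULL,
                         scale = TRUE, lambda_fixed = NULL, init = NULL,
                         opts = fit_options()) {
  freqs <- .validate_grid(freqs)
  y <- as.matrix(y)
  if (nrow(y) != length(freqs)) {
    .stopf("data has %d rows but the grid has %d frequencies",
           nrow(y), length(freqs))
  }
  n_cond <- if (is.null(spec$condition_design)) 1L else
    spec$condition_design$n_conditions
  if (ncol(y) != n_cond) {
    .stopf("data has %d columns but the model expects %d condition(s)",
           ncol(y), n_cond)
  }
  if (is.null(priors)) priors <- default_priors(spec)
  p <- n_params(spec)
  if (length(priors$mean) != p) {
    .stopf("priors have %d parameters, model has %d", length(priors$mean), p)
  }
  fac <- 1
  if (scale) {
    sc <- scale_spectrum(y, freqs, target = 8)
    y <- sc$scaled
    fac <- sc$factor
  }
  R <- NULL
  if (!is.null(noise)) {
    R1 <- noise$R
    R <- if (n_cond == 1L) R1 else {
      # shared correlation per condition, independent across conditions
      kronecker(diag(n_cond), R1)
    }
    if (isTRUE(all.equal(R, diag(nrow(R)), tolerance = 1e-12))) R <- NULL
  }
  g <- function(th) as.numeric(.model_predict(spec, th, freqs))
  jac <- if (opts$jacobian == "analytic") {
    function(th) spectrum_jacobian(th, spec, freqs)
  } else NULL
  post <- vl_fit(as.numeric(y), g, jac, prior_mean = priors$mean,
                 prior_cov = priors$cov, R = R,
                 lambda_prior = c(priors$hyper_mean, priors$hyper_var),
                 lambda_fixed = lambda_fixed, init = init, opts = opts)
  post$spec <- spec
  post$freqs <- freqs
  post$scale_factor <- fac
  post$param_names <- param_names(spec)
  names(post$mean) <- post$param_names
  post
}

#' Predicted spectrum at the posterior mean
#'
#' @param post A posterior from [fit_spectrum()].
#' @return Matrix of fitted model values (columns are conditions), on the
#'   scaled data scale.
#' @export
fitted_spectrum <- function(post) {
  if (is.null(post$spec)) .stopf("posterior does not carry a model spec")
  .model_predict(post$spec, post$mean, post$freqs)
}
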