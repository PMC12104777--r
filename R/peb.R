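#' Second-level (group) design matrix
#'
#' @param X2 Subjects x regressors matrix; the first column should be the
#'   intercept (all ones). A plain vector is taken as a single covariate and
#'   an intercept is prepended.
#' @param names Optional regressor names.
#' @param center Mean-center non-intercept regressors (default TRUE), so the
#'   intercept estimates the group average.
#' @return An object of class `bsd_group_design` with fields `X2`, `names`,
#'   `centers`.
#' @export
group_design <- function(X2, names = NULL, center = TRUE) {
  if (is.null(dim(X2))) X2 <- cbind(1, as.numeric(X2))
  X2 <- as.matrix(X2)
  if (any(!is.finite(X2))) .stopf("design matrix must be finite")
  r <- ncol(X2)
  if (is.null(names)) {
    names <- colnames(X2)
    if (is.null(names)) {
      names <- c("intercept", if (r > 1) paste0("x", seq_len(r - 1L)))
    }
  }
  centers <- rep(0, r)
  if (center && r > 1L && nrow(X2) > 1L) {
    for (j in 2:r) {
      if (isTRUE(stats::sd(X2[, j]) > 0)) {
        centers[j] <- mean(X2[, j])
        X2[, j] <- X2[, j] - centers[j]
      }
    }
  }
  if (qr(X2)$rank < r) .stopf("design matrix is rank deficient")
  structure(list(X2 = X2, names = names, centers = centers),
            class = "bsd_group_design")
}

# Per-subject sufficient statistics for the second level, written so that a
# singular data precision (posterior no sharper than the prior) stays valid:
#   Lam = V^-1 - S0^-1          (first-level data precision)
#   h   = V^-1 m - S0^-1 mu0
#   W   = (Lam^-1 + Q)^-1 = Lam - Lam (Lam + Q^-1)^-1 Lam   (Woodbury)
#   W mu_L = h - Lam (Lam + Q^-1)^-1 h
.peb_suff <- function(Lam, h, Qinv) {
  A <- .sym(Lam + Qinv)
  Ai <- tryCatch(.spd_inv(A), error = function(e) NULL)
  if (is.null(Ai)) return(NULL)
  LAi <- Lam %*% Ai
  list(W = .sym(Lam - LAi %*% Lam), wh = as.numeric(h - LAi %*% h))
}

# Evidence contribution of swapping subject k's prior N(mu0, S0) for the
# implied second-level prior N(mu_k, Q) -- plain Gaussian model reduction.
.peb_dF <- function(Pq, P0, m, mu0, Qinv, mu_k) {
  Pr <- Qinv
  Pq_r <- .sym(Pq + Pr - P0)
  ch <- tryCatch(chol(Pq_r), error = function(e) NULL)
  if (is.null(ch)) return(NA_real_)
  hh <- Pq %*% m + Pr %*% mu_k - P0 %*% mu0
  m_r <- as.numeric(chol2inv(ch) %*% hh)
  0.5 * (.logdet(Pq) + .logdet(Pr) - .logdet(P0) - 2 * sum(log(diag(ch))) +
           sum(m_r * (Pq_r %*% m_r)) - sum(m * (Pq %*% m)) -
           sum(mu_k * (Pr %*% mu_k)) + sum(mu0 * (P0 %*% mu0)))
}

#' Parametric empirical Bayes over subject-level posteriors
#'
#' Hierarchical Gaussian model: subject parameters are design-weighted group
#' effects plus Gaussian random effects,
#' `theta_k = X2[k, ] (x) I beta + epsilon`, with diagonal random-effects
#' covariance `Q_jj = exp(-gamma_j) * prior_var_j / 16` and `gamma_j ~ N(0, 1)`.
#' Given the random-effects log-precisions the group coefficients have a
#' conjugate Gaussian posterior; the log-precisions are optimised on the
#' hierarchical free energy (quasi-Newton) with a Laplace posterior. Each
#' subject enters through its stored first-level posterior only (Bayesian
#' model reduction), so no spectra are refitted.
#'
#' @param posteriors List of first-level posteriors (`bsd_posterior`, or any
#'   list with `mean`, `cov`, optionally `free_energy`).
#' @param priors First-level [prior_spec()] the posteriors were fitted under.
#' @param design A [group_design()] (or subjects x regressors matrix).
#' @param gamma_fixed Optional fixed vector (or scalar) of random-effects
#'   log-precisions, skipping their optimisation.
#' @param beta_prior_var Prior variance of each group coefficient; defaults
#'   to the first-level prior variances, reused for every regressor.
#' @return An object of class `bsd_group`: `beta_mean` (parameters x
#'   regressors), `beta_cov` (full, vectorised parameters-within-regressor),
#'   `gamma_mean`, `gamma_cov`, `F_total`, `design`, `param_names`.
#' @export
peb_fit <- function(posteriors, priors, design, gamma_fixed = NULL,
                    beta_prior_var = NULL) {
  if (!inherits(design, "bsd_group_design")) {
    dm <- as.matrix(design)
    if (ncol(dm) > 1L && nrow(dm) < 2L) {
      .stopf("covariate effects need at least 2 subjects")
    }
    design <- group_design(design)
  }
  K <- length(posteriors)
  if (nrow(design$X2) != K) {
    .stopf("design has %d rows but there are %d posteriors",
           nrow(design$X2), K)
  }
  r <- ncol(design$X2)
  if (r > 1L && K < 2L) .stopf("covariate effects need at least 2 subjects")
  p <- length(posteriors[[1]]$mean)
  for (po in posteriors) {
    if (length(po$mean) != p) .stopf("all posteriors must share dimension %d", p)
  }
  if (length(priors$mean) != p) {
    .stopf("first-level priors have dimension %d, posteriors %d",
           length(priors$mean), p)
  }
  mu0 <- priors$mean
  S0 <- priors$cov
  P0 <- .spd_inv(S0)
  v0 <- diag(S0) / 16          # base scale of random-effects variances
  pnames <- names(posteriors[[1]]$mean)
  if (is.null(pnames)) pnames <- paste0("p", seq_len(p))

  Pq <- vector("list", K); h <- vector("list", K); Lam <- vector("list", K)
  m1 <- matrix(0, K, p)
  F1 <- 0
  for (k in seq_len(K)) {
    Vk <- .sym(as.matrix(posteriors[[k]]$cov))
    Pq[[k]] <- .spd_inv(Vk)
    m1[k, ] <- as.numeric(posteriors[[k]]$mean)
    h[[k]] <- as.numeric(Pq[[k]] %*% m1[k, ] - P0 %*% mu0)
    Lam[[k]] <- .sym(Pq[[k]] - P0)
    if (!is.null(posteriors[[k]]$free_energy)) F1 <- F1 + posteriors[[k]]$free_energy
  }
  if (is.null(beta_prior_var)) beta_prior_var <- rep(diag(S0), r)
  beta_prior_var <- rep(beta_prior_var, length.out = p * r)
  Pb0 <- diag(1 / beta_prior_var, p * r)

  Xk <- lapply(seq_len(K), function(k) kronecker(t(design$X2[k, ]), diag(p)))

  # profile free energy over gamma: conjugate update of beta inside
  eval_gamma <- function(gam, kl_gamma = 0.5 * sum(gam^2)) {
    Qvar <- exp(-gam) * v0
    Qinv <- diag(1 / Qvar, p)
    Hs <- vector("list", K)
    gsum <- rep(0, p * r)
    Hsum <- matrix(0, p * r, p * r)
    for (k in seq_len(K)) {
      sf <- .peb_suff(Lam[[k]], h[[k]], Qinv)
      if (is.null(sf)) return(NULL)
      Hs[[k]] <- crossprod(Xk[[k]], sf$W %*% Xk[[k]])
      Hsum <- Hsum + Hs[[k]]
      gsum <- gsum + as.numeric(crossprod(Xk[[k]], sf$wh))
    }
    Pbpost <- .sym(Pb0 + Hsum)
    chb <- tryCatch(chol(Pbpost), error = function(e) NULL)
    if (is.null(chb)) return(NULL)
    Sb <- chol2inv(chb)
    b <- as.numeric(Sb %*% gsum)
    Ftot <- F1 - .gaussian_kl(b, Sb, rep(0, p * r), diag(beta_prior_var, p * r)) -
      kl_gamma
    for (k in seq_len(K)) {
      dFk <- .peb_dF(Pq[[k]], P0, m1[k, ], mu0, Qinv,
                     as.numeric(Xk[[k]] %*% b))
      if (!is.finite(dFk)) return(NULL)
      Ftot <- Ftot + dFk - 0.5 * sum(Hs[[k]] * Sb)
    }
    list(F = Ftot, b = b, Sb = Sb, Qvar = Qvar)
  }

  if (is.null(gamma_fixed)) {
    obj <- function(gam) {
      res <- eval_gamma(gam)
      if (is.null(res) || !is.finite(res$F)) return(1e10)
      -res$F
    }
    opt <- stats::optim(rep(0, p), obj, method = "BFGS",
                        control = list(maxit = 200, reltol = 1e-10))
    gam <- opt$par
    # Laplace posterior over gamma from the numerical curvature of F
    eps <- 1e-3
    Hg <- matrix(0, p, p)
    f0 <- -obj(gam)
    for (i in seq_len(p)) {
      for (j in i:p) {
        ei <- rep(0, p); ei[i] <- eps
        ej <- rep(0, p); ej[j] <- eps
        fpp <- -obj(gam + ei + ej); fpm <- -obj(gam + ei - ej)
        fmp <- -obj(gam - ei + ej); fmm <- -obj(gam - ei - ej)
        Hg[i, j] <- Hg[j, i] <- (fpp - fpm - fmp + fmm) / (4 * eps^2)
      }
    }
    Sg <- tryCatch(.spd_inv(-Hg), error = function(e) diag(1e-2, p))
    if (any(!is.finite(Sg)) || any(diag(Sg) <= 0)) Sg <- diag(1e-2, p)
    klg <- .gaussian_kl(gam, Sg, rep(0, p), diag(p))
  } else {
    gam <- rep(gamma_fixed, length.out = p)
    Sg <- diag(0, p)
    klg <- 0   # fixed log-precisions carry no complexity
  }
  res <- eval_gamma(gam, kl_gamma = klg)
  if (is.null(res)) .stopf("PEB free energy is not computable at the optimum")

  beta_mean <- matrix(res$b, p, r, dimnames = list(pnames, design$names))
  structure(
    list(beta_mean = beta_mean, beta_cov = res$Sb,
         gamma_mean = gam, gamma_cov = Sg, re_var = res$Qvar,
         F_total = res$F, design = design, param_names = pnames,
         n_subjects = K),
    class = "bsd_group"
  )
}

#' @export
print.bsd_group <- function(x, ...) {
  cat(sprintf("<group posterior: %d parameter(s) x %d regressor(s), %d subjects, F = %.3f>\n",
              nrow(x$beta_mean), ncol(x$beta_mean), x$n_subjects, x$F_total))
  invisible(x)
}

# Resolve the link for a named first-level parameter given a model spec.
.param_link <- function(name, spec = NULL) {
  base <- sub("^(base|cond[0-9]+_delta)\\.", "", name)
  if (base == "ap_exponent") return(list(fun = function(x) -exp(x), decreasing = TRUE))
  if (base == "ap_power" || grepl("_h$", base) || grepl("_s$", base)) {
    return(list(fun = exp, decreasing = FALSE))
  }
  if (grepl("_m$", base) && !is.null(spec)) {
    bname <- sub("_m$", "", base)
    for (b in spec$bands) {
      if (b$name == bname) {
        L <- b$lower; U <- b$upper
        return(list(fun = function(x) L + stats::plogis(x) * (U - L),
                    decreasing = FALSE))
      }
    }
  }
  list(fun = identity, decreasing = FALSE)
}

#' Credible band for a parameter over a covariate range
#'
#' The linear predictor `eta(x) = beta_0 + beta_x * x` and its posterior
#' variance (from the full coefficient covariance) give a Gaussian band on
#' the unconstrained scale, which is mapped through the parameter's monotone
#' link to the natural scale (quantiles are preserved).
#'
#' @param group A `bsd_group` from [peb_fit()].
#' @param param Parameter name or index.
#' @param covariate Covariate values at which to evaluate (original, uncentred
#'   scale).
#' @param level Credible level (default 0.90).
#' @param regressor Index of the covariate column in the design (default 2).
#' @param spec Optional [model_spec()] used to resolve the natural-scale link
#'   (band-bounded links need the band limits); `NULL` keeps the
#'   unconstrained scale.
#' @return Data frame `covariate`, `mean`, `lower`, `upper` (natural scale).
#' @export
credible_band <- function(group, param, covariate, level = 0.90,
                          regressor = 2L, spec = NULL) {
  if (level <= 0 || level >= 1) .stopf("level must be in (0, 1)")
  p <- nrow(group$beta_mean)
  r <- ncol(group$beta_mean)
  if (is.character(param)) {
    j <- match(param, group$param_names)
    if (is.na(j)) .stopf("unknown parameter '%s'", param)
  } else {
    j <- as.integer(param)
    if (j < 1L || j > p) .stopf("parameter index %d out of range", j)
  }
  if (regressor > r) .stopf("design has no regressor %d", regressor)
  idx <- j + (seq_len(r) - 1L) * p
  z <- stats::qnorm((1 + level) / 2)
  xc <- covariate - group$design$centers[regressor]
  link <- .param_link(group$param_names[j], spec)
  out <- data.frame(covariate = covariate, mean = NA_real_,
                    lower = NA_real_, upper = NA_real_)
  for (i in seq_along(covariate)) {
    w <- rep(0, r); w[1] <- 1; w[regressor] <- xc[i]
    eta <- sum(w * group$beta_mean[j, ])
    se <- sqrt(max(sum(w * (group$beta_cov[idx, idx] %*% w)), 0))
    qq <- link$fun(c(eta, eta - z * se, eta + z * se))
    out$mean[i] <- qq[1]
    out$lower[i] <- min(qq[2], qq[3])
    out$upper[i] <- max(qq[2], qq[3])
  }
  attr(out, "level") <- level
  attr(out, "param") <- group$param_names[j]
  out
}

#' Group-level predicted spectra over a covariate range
#'
#' Evaluates the model spectrum at the link-mapped group-level predicted
#' parameters for each covariate value (and condition, when the model has a
#' condition design).
#'
#' @param group A `bsd_group` fitted with an intercept + covariate design.
#' @param spec The first-level [model_spec()].
#' @param freqs Frequencies in Hz.
#' @param covariate Covariate values (original scale).
#' @param condition Condition index when `spec` has a condition design.
#' @param regressor Covariate column in the design (default 2).
#' @return `length(freqs) x length(covariate)` matrix of predicted spectra.
#' @export
interpolate_group_spectrum <- function(group, spec, freqs, covariate,
                                       condition = NULL, regressor = 2L) {
  freqs <- .validate_grid(freqs)
  rng <- range(group$design$X2[, regressor] + group$design$centers[regressor])
  if (any(covariate < rng[1] - 1e-9) || any(covariate > rng[2] + 1e-9)) {
    warning("covariate values outside the design support; extrapolating")
  }
  r <- ncol(group$beta_mean)
  out <- matrix(0, length(freqs), length(covariate))
  for (i in seq_along(covariate)) {
    w <- rep(0, r); w[1] <- 1
    w[regressor] <- covariate[i] - group$design$centers[regressor]
    theta <- as.numeric(group$beta_mean %*% w)
    th_c <- if (is.null(spec$condition_design)) theta else {
      condition_expand(theta, spec$condition_design,
                       if (is.null(condition)) 1L else condition)
    }
    nat <- apply_links(th_c, spec$bands)
    out[, i] <- apply_filters(evaluate_spectrum(nat, freqs, spec$domain),
                              spec$filters, freqs)
  }
  colnames(out) <- signif(covariate, 6)
  out
}
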