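#' Define a frequency band
#'
#' A band is a disjoint interval of the spectrum within which at most one
#' Gaussian peak is modelled. The peak-frequency link soft-clips the centre
#' frequency into the open interval (lower, upper).
#'
#' @param name Label for the band (e.g. "alpha").
#' @param lower Lower edge in Hz.
#' @param upper Upper edge in Hz; must exceed `lower`.
#' @return An object of class `bsd_band`.
#' @examples
#' band("alpha", 8, 12)
#' @export
band <- function(name, lower, upper) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    .stopf("band 'name' must be a non-empty string")
  }
  if (!.is_number(lower) || !.is_number(upper) || lower >= upper) {
    .stopf("band '%s': need finite lower < upper (got %s, %s)", name, lower, upper)
  }
  structure(list(name = name, lower = lower, upper = upper), class = "bsd_band")
}

#' @export
print.bsd_band <- function(x, ...) {
  cat(sprintf("<band %s: %g-%g Hz>\n", x$name, x$lower, x$upper))
  invisible(x)
}

# Canonical frequency-band presets used throughout the package.
#' Standard frequency-band presets
#'
#' @param name One of "delta", "theta", "alpha", "beta", "gamma".
#' @return A [band()] with the conventional limits (delta 1-4, theta 4-8,
#'   alpha 8-12, beta 12-30, gamma 30-64 Hz).
#' @export
standard_band <- function(name = c("delta", "theta", "alpha", "beta", "gamma")) {
  name <- match.arg(name)
  lims <- list(
    delta = c(1, 4), theta = c(4, 8), alpha = c(8, 12),
    beta = c(12, 30), gamma = c(30, 64)
  )[[name]]
  band(name, lims[1], lims[2])
}

.validate_bands <- function(bands) {
  if (length(bands) == 0L) return(invisible(bands))
  for (b in bands) {
    if (!inherits(b, "bsd_band")) .stopf("all bands must be created with band()")
  }
  nm <- vapply(bands, `[[`, "", "name")
  if (anyDuplicated(nm)) .stopf("band names must be unique")
  if (length(bands) > 1L) {
    lo <- vapply(bands, `[[`, 0, "lower")
    up <- vapply(bands, `[[`, 0, "upper")
    o <- order(lo)
    if (any(lo[o][-1] < up[o][-length(up)])) {
      .stopf("bands must be pairwise disjoint")
    }
  }
  invisible(bands)
}

.validate_grid <- function(freqs) {
  freqs <- as.numeric(freqs)
  if (length(freqs) < 2L) .stopf("frequency grid needs at least 2 points")
  if (any(!is.finite(freqs)) || any(freqs <= 0)) {
    .stopf("frequencies must be finite and > 0")
  }
  if (any(diff(freqs) <= 0)) .stopf("frequencies must be strictly increasing")
  freqs
}

#' Specify a parametric spectral model
#'
#' A model is a power-law aperiodic component plus one Gaussian peak per
#' frequency band, evaluated either on the amplitude spectral density or with
#' the aperiodic component log-transformed (peaks remain additive).
#'
#' @param bands List of [band()] objects (possibly empty) — one peak each.
#' @param domain `"amplitude"` (default) fits the amplitude spectral density;
#'   `"log"` replaces the aperiodic term by its logarithm.
#' @param filters Optional list of [filter_spec()] objects applied to the
#'   model prediction.
#' @param condition_design Optional [condition_design()] mapping a stacked
#'   parameter vector to per-condition parameters.
#' @return An object of class `bsd_model`.
#' @examples
#' model_spec(list(band("alpha", 8, 12)))
#' @export
model_spec <- function(bands = list(), domain = c("amplitude", "log"),
                       filters = list(), condition_design = NULL) {
  domain <- match.arg(domain)
  if (inherits(bands, "bsd_band")) bands <- list(bands)
  .validate_bands(bands)
  if (inherits(filters, "bsd_filter")) filters <- list(filters)
  for (fl in filters) {
    if (!inherits(fl, "bsd_filter")) .stopf("filters must be filter_spec() objects")
  }
  if (!is.null(condition_design) && !inherits(condition_design, "bsd_condition_design")) {
    .stopf("condition_design must be created with condition_design()")
  }
  if (!is.null(condition_design)) {
    p_base <- 2L + 3L * length(bands)
    if (nrow(condition_design$X[[1]]) != p_base) {
      .stopf("condition design maps to %d parameters but the model has %d",
             nrow(condition_design$X[[1]]), p_base)
    }
  }
  structure(
    list(bands = bands, domain = domain, filters = filters,
         condition_design = condition_design),
    class = "bsd_model"
  )
}

#' @export
print.bsd_model <- function(x, ...) {
  nm <- vapply(x$bands, `[[`, "", "name")
  cat(sprintf(
    "<spectral model: %d peak(s)%s, %s domain, %d filter(s)%s>\n",
    length(x$bands),
    if (length(nm)) paste0(" [", paste(nm, collapse = ", "), "]") else "",
    x$domain, length(x$filters),
    if (!is.null(x$condition_design)) {
      sprintf(", %d conditions", x$condition_design$n_conditions)
    } else ""
  ))
  invisible(x)
}

#' Names of the unconstrained parameters of a model
#'
#' Order is aperiodic power, aperiodic exponent, then (height, centre, width)
#' per band; with a condition design the pattern repeats per design block.
#'
#' @param spec A [model_spec()].
#' @return Character vector of parameter names.
#' @export
param_names <- function(spec) {
  nm <- c("ap_power", "ap_exponent")
  for (b in spec$bands) nm <- c(nm, paste0(b$name, c("_h", "_m", "_s")))
  if (!is.null(spec$condition_design)) {
    blocks <- ncol(spec$condition_design$X[[1]]) / length(nm)
    lab <- c("base", paste0("cond", seq_len(blocks - 1) + 1L, "_delta"))
    nm <- as.vector(vapply(lab, function(l) paste(l, nm, sep = "."), character(length(nm))))
  }
  nm
}

#' Number of unconstrained parameters of a model
#' @param spec A [model_spec()].
#' @return Integer parameter count (2 + 3 peaks, times design blocks).
#' @export
n_params <- function(spec) {
  p <- 2L + 3L * length(spec$bands)
  if (!is.null(spec$condition_design)) p <- ncol(spec$condition_design$X[[1]])
  p
}

#' Map unconstrained parameters to the natural scale
#'
#' Link functions give each constrained quantity a tractable unconstrained
#' Gaussian parameterisation: aperiodic amplitude `gamma = exp(theta)`,
#' exponent `alpha = -exp(theta)`, peak height and width `exp(theta)`, and
#' peak centre soft-clipped into its band,
#' `m = L + sigma(theta) (U - L)` with the logistic sigmoid `sigma`.
#'
#' @param theta Numeric vector of length `2 + 3 * length(bands)`:
#'   aperiodic power, aperiodic exponent, then (height, centre, width) per band.
#' @param bands List of [band()] objects.
#' @return An object of class `bsd_natural`: list with `gamma`, `alpha` and a
#'   data frame `peaks` (name, h, m, s).
#' @examples
#' apply_links(c(0, 0, 0, 0, 0), list(band("alpha", 8, 12)))
#' @export
apply_links <- function(theta, bands = list()) {
  theta <- as.numeric(theta)
  if (any(!is.finite(theta))) .stopf("theta must be finite")
  n_b <- length(bands)
  if (length(theta) != 2L + 3L * n_b) {
    .stopf("theta has length %d but %d bands imply length %d",
           length(theta), n_b, 2L + 3L * n_b)
  }
  .validate_bands(bands)
  peaks <- data.frame(
    name = character(n_b), h = numeric(n_b), m = numeric(n_b), s = numeric(n_b),
    stringsAsFactors = FALSE
  )
  if (n_b > 0L) {
    for (i in seq_len(n_b)) {
      b <- bands[[i]]
      th <- theta[2L + 3L * (i - 1L) + 1:3]
      peaks$name[i] <- b$name
      peaks$h[i] <- exp(th[1])
      peaks$m[i] <- b$lower + stats::plogis(th[2]) * (b$upper - b$lower)
      peaks$s[i] <- exp(th[3])
    }
  }
  structure(
    list(gamma = exp(theta[1]), alpha = -exp(theta[2]), peaks = peaks),
    class = "bsd_natural"
  )
}

#' Map natural-scale parameters back to the unconstrained scale
#'
#' Inverse of [apply_links()]; used to seed simulations and report truths.
#'
#' @param nat A `bsd_natural` object (or list with the same fields).
#' @param bands The bands that produced it.
#' @return Numeric vector theta.
#' @export
natural_to_raw <- function(nat, bands = list()) {
  n_b <- length(bands)
  theta <- c(log(nat$gamma), log(-nat$alpha))
  for (i in seq_len(n_b)) {
    b <- bands[[i]]
    m <- nat$peaks$m[i]
    if (m <= b$lower || m >= b$upper) {
      .stopf("peak centre %g outside open band (%g, %g)", m, b$lower, b$upper)
    }
    theta <- c(theta, log(nat$peaks$h[i]),
               stats::qlogis((m - b$lower) / (b$upper - b$lower)),
               log(nat$peaks$s[i]))
  }
  theta
}

#' Evaluate the noise-free model spectrum
#'
#' Amplitude domain: `S(f) = gamma * f^alpha + sum_i h_i exp(-((f-m_i)/s_i)^2/2)`.
#' Log domain: the aperiodic term is replaced by its logarithm
#' (`log gamma + alpha log f`); peaks remain additive.
#'
#' @param nat Natural-scale parameters from [apply_links()].
#' @param freqs Strictly increasing frequencies in Hz (> 0).
#' @param domain `"amplitude"` or `"log"`.
#' @return Numeric vector of model values at `freqs`.
#' @examples
#' nat <- apply_links(c(log(2), log(0.5), 0, 0, log(2)), list(band("b", 8, 12)))
#' evaluate_spectrum(nat, c(8, 10))
#' @export
evaluate_spectrum <- function(nat, freqs, domain = c("amplitude", "log")) {
  domain <- match.arg(domain)
  freqs <- .validate_grid(freqs)
  ap <- nat$gamma * freqs^nat$alpha
  if (domain == "log") ap <- log(nat$gamma) + nat$alpha * log(freqs)
  S <- ap
  for (i in seq_len(nrow(nat$peaks))) {
    z <- (freqs - nat$peaks$m[i]) / nat$peaks$s[i]
    S <- S + nat$peaks$h[i] * exp(-z^2 / 2)
  }
  S
}

#' Specify a filter response
#'
#' Either an analytic Butterworth magnitude response or a tabulated
#' per-frequency magnitude. Filters act multiplicatively on the model
#' spectrum (see [apply_filters()]).
#'
#' @param kind `"highpass_butter"`, `"lowpass_butter"` or `"tabulated"`.
#' @param order Filter order (Butterworth kinds).
#' @param cutoff Cutoff frequency in Hz (Butterworth kinds).
#' @param freqs,magnitude Tabulated grid and magnitudes in `[0, 1]`
#'   (`"tabulated"` kind); linearly interpolated onto the model grid.
#' @return An object of class `bsd_filter`.
#' @export
filter_spec <- function(kind = c("highpass_butter", "lowpass_butter", "tabulated"),
                        order = 2L, cutoff = NULL, freqs = NULL, magnitude = NULL) {
  kind <- match.arg(kind)
  if (kind == "tabulated") {
    freqs <- as.numeric(freqs)
    magnitude <- as.numeric(magnitude)
    if (length(freqs) != length(magnitude) || length(freqs) < 2L) {
      .stopf("tabulated filter needs matching freqs/magnitude of length >= 2")
    }
    if (any(diff(freqs) <= 0)) .stopf("tabulated filter grid must be increasing")
    if (any(magnitude < 0) || any(magnitude > 1 + 1e-8)) {
      .stopf("filter magnitudes must lie in [0, 1]")
    }
    out <- list(kind = kind, freqs = freqs, magnitude = magnitude)
  } else {
    if (!.is_number(cutoff) || cutoff <= 0) .stopf("Butterworth filter needs cutoff > 0")
    if (!.is_number(order) || order < 1) .stopf("Butterworth filter needs order >= 1")
    out <- list(kind = kind, order = as.integer(order), cutoff = cutoff)
  }
  structure(out, class = "bsd_filter")
}

#' Magnitude response of one filter on a grid
#'
#' @param filter A [filter_spec()].
#' @param freqs Frequencies in Hz.
#' @return Numeric vector `|H(f)|`.
#' @export
filter_response <- function(filter, freqs) {
  freqs <- .validate_grid(freqs)
  switch(filter$kind,
    highpass_butter = 1 / sqrt(1 + (filter$cutoff / freqs)^(2 * filter$order)),
    lowpass_butter = 1 / sqrt(1 + (freqs / filter$cutoff)^(2 * filter$order)),
    tabulated = {
      if (min(freqs) < min(filter$freqs) || max(freqs) > max(filter$freqs)) {
        .stopf("tabulated filter grid [%g, %g] does not cover model grid [%g, %g]",
               min(filter$freqs), max(filter$freqs), min(freqs), max(freqs))
      }
      stats::approx(filter$freqs, filter$magnitude, xout = freqs)$y
    }
  )
}

#' Apply a filter cascade to a model spectrum
#'
#' The default composition is the product of the filter magnitudes (how a
#' cascade of filters acts physically); `combine = "sum"` adds them instead,
#' matching a literal additive reading of the transfer-function expansion.
#'
#' @param S Model spectrum values.
#' @param filters List of [filter_spec()] objects (possibly empty).
#' @param freqs Frequencies matching `S`.
#' @param combine `"product"` (default) or `"sum"`.
#' @return Filtered spectrum values.
#' @export
apply_filters <- function(S, filters, freqs, combine = c("product", "sum")) {
  combine <- match.arg(combine)
  if (length(filters) == 0L) return(S)
  mags <- vapply(filters, filter_response, numeric(length(freqs)), freqs = freqs)
  mags <- matrix(mags, nrow = length(freqs))
  mult <- if (combine == "product") apply(mags, 1L, prod) else rowSums(mags)
  mult * S
}

#' Condition design: map a stacked parameter vector to per-condition parameters
#'
#' Condition-specific effects enter as linear maps on the unconstrained scale:
#' condition `c` uses effective parameters `X_c theta`. The default
#' baseline/delta encoding stacks a baseline block and one delta block per
#' additional condition, so `X_1 = [I 0 ...]` and `X_c = [I 0 .. I .. 0]`.
#'
#' @param n_conditions Number of conditions (>= 1).
#' @param n_base Number of per-condition parameters (2 + 3 peaks).
#' @param X Optional list of custom design matrices (one per condition, equal
#'   shapes, `n_base` rows); overrides the default encoding.
#' @return An object of class `bsd_condition_design`.
#' @export
condition_design <- function(n_conditions, n_base, X = NULL) {
  if (is.null(X)) {
    n_conditions <- as.integer(n_conditions)
    if (n_conditions < 1L) .stopf("need at least one condition")
    I <- diag(n_base)
    Z <- matrix(0, n_base, n_base)
    # baseline block always on; delta block j switches on for condition j
    X <- lapply(seq_len(n_conditions), function(cond) {
      blocks <- lapply(seq_len(n_conditions), function(j) {
        if (j == 1L || j == cond) I else Z
      })
      do.call(cbind, blocks)
    })
  } else {
    n_conditions <- length(X)
    shp <- vapply(X, dim, integer(2))
    if (any(shp[1, ] != shp[1, 1]) || any(shp[2, ] != shp[2, 1])) {
      .stopf("all condition design matrices must share the same shape")
    }
    if (shp[1, 1] != n_base) .stopf("design matrices must have %d rows", n_base)
  }
  structure(list(n_conditions = n_conditions, X = X),
            class = "bsd_condition_design")
}

#' Per-condition effective parameters
#'
#' @param theta Stacked unconstrained parameter vector.
#' @param design A [condition_design()].
#' @param condition Condition index (1-based).
#' @return Unconstrained per-condition parameter vector `X_c theta`.
#' @export
condition_expand <- function(theta, design, condition) {
  if (!inherits(design, "bsd_condition_design")) {
    .stopf("design must be a condition_design()")
  }
  if (condition < 1L || condition > design$n_conditions) {
    .stopf("condition %d out of range (1..%d)", condition, design$n_conditions)
  }
  Xc <- design$X[[condition]]
  theta <- as.numeric(theta)
  if (length(theta) != ncol(Xc)) {
    .stopf("theta has length %d, design expects %d", length(theta), ncol(Xc))
  }
  as.numeric(Xc %*% theta)
}

#' Observation-noise model
#'
#' Spectral noise is Gaussian with covariance `C_f = exp(-lambda) R_f`, where
#' `lambda` is the log-precision and `R_f` a correlation matrix across
#' frequencies: identity by default (white spectral noise), or a
#' squared-exponential kernel with a frequency length-scale.
#'
#' @param n_freq Number of frequencies (identity / kernel construction).
#' @param log_precision Noise log-precision lambda.
#' @param R Optional explicit correlation matrix (unit diagonal, PSD).
#' @param length_scale If > 0, build a squared-exponential correlation
#'   `R_ij = exp(-(f_i - f_j)^2 / (2 l^2))` from `freqs`.
#' @param freqs Frequencies (required with `length_scale`).
#' @return An object of class `bsd_noise` with fields `R`, `log_precision`.
#' @export
noise_model <- function(n_freq = NULL, log_precision = 0, R = NULL,
                        length_scale = 0, freqs = NULL) {
  if (is.null(R)) {
    if (length_scale > 0) {
      freqs <- .validate_grid(freqs)
      D <- outer(freqs, freqs, `-`)
      R <- exp(-D^2 / (2 * length_scale^2))
    } else {
      if (is.null(n_freq)) .stopf("need n_freq or R or (length_scale, freqs)")
      R <- diag(n_freq)
    }
  }
  R <- as.matrix(R)
  if (!isTRUE(all.equal(R, t(R), tolerance = 1e-8))) .stopf("R must be symmetric")
  if (any(abs(diag(R) - 1) > 1e-8)) .stopf("R must have unit diagonal")
  ev <- eigen(.sym(R), symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(ev)) .stopf("R must be positive semi-definite")
  structure(list(R = .sym(R), log_precision = log_precision), class = "bsd_noise")
}

#' Noise covariance implied by a noise model
#'
#' @param noise A [noise_model()].
#' @return Matrix `C_f = exp(-lambda) R_f`.
#' @export
noise_covariance <- function(noise) {
  if (!inherits(noise, "bsd_noise")) .stopf("noise must be a noise_model()")
  exp(-noise$log_precision) * noise$R
}

#' Rescale a spectrum to the reference signal variance
#'
#' The implied total signal variance of an amplitude spectral density is
#' `sum(S^2 * df)` (Parseval). Scaling it to a fixed reference (8 by default)
#' frees the priors from the arbitrary units of the recording; the factor is
#' returned so results can be mapped back.
#'
#' @param S Amplitude spectrum (vector or matrix with spectra in columns; a
#'   matrix is scaled by one common factor).
#' @param freqs Frequencies matching `S` rows.
#' @param target Reference variance (default 8).
#' @return List with `scaled` and `factor` (the applied amplitude multiplier).
#' @examples
#' scale_spectrum(rep(1, 10), seq(1, 10))$factor
#' @export
scale_spectrum <- function(S, freqs, target = 8) {
  freqs <- .validate_grid(freqs)
  S <- as.matrix(S)
  if (nrow(S) != length(freqs)) .stopf("spectrum rows must match frequency grid")
  df <- mean(diff(freqs))
  v <- mean(colSums(S^2) * df)
  if (v <= 0) .stopf("cannot scale an all-zero spectrum")
  fac <- sqrt(target / v)
  list(scaled = S * fac, factor = fac)
}

# Model prediction for a full (possibly stacked-condition) theta vector.
# Returns an n_freq x n_cond matrix of model values after links and filters.
.model_predict <- function(spec, theta, freqs) {
  des <- spec$condition_design
  n_cond <- if (is.null(des)) 1L else des$n_conditions
  out <- matrix(0, length(freqs), n_cond)
  for (cc in seq_len(n_cond)) {
    th_c <- if (is.null(des)) theta else condition_expand(theta, des, cc)
    nat <- apply_links(th_c, spec$bands)
    S <- evaluate_spectrum(nat, freqs, spec$domain)
    out[, cc] <- apply_filters(S, spec$filters, freqs)
  }
  out
}

#' Analytic Jacobian of the model spectrum
#'
#' Derivatives of the (filtered) model values with respect to the
#' unconstrained parameters, propagated through the link functions. With a
#' condition design, per-condition rows are stacked and the chain rule picks
#' up the design matrices.
#'
#' @param theta Unconstrained parameter vector.
#' @param spec A [model_spec()].
#' @param freqs Frequencies in Hz.
#' @return Matrix with `length(freqs) * n_conditions` rows and
#'   `length(theta)` columns.
#' @export
spectrum_jacobian <- function(theta, spec, freqs) {
  freqs <- .validate_grid(freqs)
  des <- spec$condition_design
  n_cond <- if (is.null(des)) 1L else des$n_conditions
  rows <- vector("list", n_cond)
  for (cc in seq_len(n_cond)) {
    th_c <- if (is.null(des)) theta else condition_expand(theta, des, cc)
    J <- .jacobian_base(th_c, spec$bands, spec$domain, freqs)
    if (length(spec$filters)) {
      mult <- apply_filters(rep(1, length(freqs)), spec$filters, freqs)
      J <- J * mult
    }
    rows[[cc]] <- if (is.null(des)) J else J %*% des$X[[cc]]
  }
  do.call(rbind, rows)
}

# d S(f) / d theta for a single-condition parameter vector (no filters).
.jacobian_base <- function(theta, bands, domain, freqs) {
  n_b <- length(bands)
  nat <- apply_links(theta, bands)
  J <- matrix(0, length(freqs), 2L + 3L * n_b)
  fa <- freqs^nat$alpha
  if (domain == "amplitude") {
    J[, 1] <- nat$gamma * fa                              # d/d theta_beta
    J[, 2] <- nat$gamma * fa * log(freqs) * nat$alpha     # d/d theta_alpha
  } else {
    J[, 1] <- 1
    J[, 2] <- nat$alpha * log(freqs)
  }
  for (i in seq_len(n_b)) {
    b <- bands[[i]]
    h <- nat$peaks$h[i]; m <- nat$peaks$m[i]; s <- nat$peaks$s[i]
    z <- (freqs - m) / s
    P <- h * exp(-z^2 / 2)
    sig <- stats::plogis(theta[2L + 3L * (i - 1L) + 2L])
    dmdth <- sig * (1 - sig) * (b$upper - b$lower)
    k <- 2L + 3L * (i - 1L)
    J[, k + 1L] <- P                    # height: exp link
    J[, k + 2L] <- P * z / s * dmdth    # centre: through sigmoid
    J[, k + 3L] <- P * z^2              # width: exp link
  }
  J
}
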