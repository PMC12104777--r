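test_that("link functions map to the natural scale and its constraints", {
  b <- band("alpha", 8, 12)
  nat <- apply_links(c(0, 0, 0, 0, 0), list(b))
  expect_equal(nat$peaks$m, 10)              # sigma(0) = 1/2 mid-band
  expect_equal(nat$peaks$h, 1)               # exp(0)
  expect_equal(nat$gamma, 1)
  expect_equal(nat$alpha, -1)                # -exp(0)

  # soft clipping: the centre never leaves the band
  far <- apply_links(c(0, 0, 0, 16, 0), list(b))
  expect_lt(far$peaks$m, 12)
  expect_gt(far$peaks$m, 11.99)
  expect_lte(apply_links(c(0, 0, 0, 1e3, 0), list(b))$peaks$m, 12)

  # property: invariants hold for arbitrary finite raw vectors
  set.seed(41)
  bands <- list(band("theta", 4, 8), band("beta", 12, 30))
  for (i in 1:50) {
    th <- rnorm(8, 0, 3)
    nat <- apply_links(th, bands)
    expect_gt(nat$gamma, 0)
    expect_lt(nat$alpha, 0)
    expect_true(all(nat$peaks$h > 0) && all(nat$peaks$s > 0))
    expect_true(all(nat$peaks$m > c(4, 12)) && all(nat$peaks$m < c(8, 30)))
  }

  # centre is monotone in its raw parameter
  ms <- vapply(seq(-4, 4, 0.5),
               function(t) apply_links(c(0, 0, 0, t, 0), list(b))$peaks$m, 0)
  expect_true(all(diff(ms) > 0))

  # round trip through the inverse links
  th <- c(0.3, -0.5, 0.2, 0.7, -0.1)
  expect_equal(natural_to_raw(apply_links(th, list(b)), list(b)), th,
               tolerance = 1e-10)

  expect_error(apply_links(c(0, 0, 0), list(b)), "length")
})

test_that("evaluate_spectrum matches hand-computed values", {
  f <- c(2, 4)
  nat <- apply_links(c(0, 0), list())
  expect_equal(evaluate_spectrum(nat, f)[1], 0.5)   # 1 * 2^-1

  # value at the peak mode is aperiodic + height exactly
  b <- band("alpha", 8, 12)
  th <- c(log(1.3), log(0.8), log(2), 0, log(1.5))
  nat <- apply_links(th, list(b))
  f2 <- c(5, nat$peaks$m, 20)
  S <- evaluate_spectrum(nat, f2)
  expect_equal(S[2], nat$gamma * nat$peaks$m^nat$alpha + nat$peaks$h,
               tolerance = 1e-12)

  # hand-computed: gamma=2, alpha=-0.5, peak (1, 10, 2) at f=8
  nat3 <- structure(list(gamma = 2, alpha = -0.5,
                         peaks = data.frame(name = "p", h = 1, m = 10, s = 2)),
                    class = "bsd_natural")
  expect_equal(evaluate_spectrum(nat3, c(8, 10))[1],
               2 * 8^-0.5 + exp(-0.5), tolerance = 1e-6)
  expect_equal(evaluate_spectrum(nat3, c(8, 10))[1], 1.31364, tolerance = 1e-5)

  # amplitude-domain spectra are positive whenever gamma > 0
  set.seed(42)
  for (i in 1:20) {
    nat <- apply_links(rnorm(5, 0, 2), list(b))
    expect_true(all(evaluate_spectrum(nat, seq(1, 32, 0.5)) > 0))
  }

  # log domain: aperiodic term log-transformed, peaks still additive
  Slog <- evaluate_spectrum(nat3, c(8, 10), domain = "log")
  expect_equal(Slog[1], log(2 * 8^-0.5) + exp(-0.5), tolerance = 1e-12)

  expect_error(evaluate_spectrum(nat3, c(0, 1)), "> 0")
})

test_that("filters compose multiplicatively on the model grid", {
  f <- seq(1, 10, 0.5)
  S <- rep(1, length(f))
  expect_equal(apply_filters(S, list(), f), S)

  hp <- filter_spec("tabulated", freqs = c(0.5, 1.49, 1.5, 64),
                    magnitude = c(0, 0, 1, 1))
  out <- apply_filters(S, list(hp), f)
  expect_true(all(out[f < 1.49] < 0.05))
  expect_equal(out[f >= 1.5], S[f >= 1.5])

  f0 <- 4
  t1 <- filter_spec("tabulated", freqs = c(1, 10), magnitude = c(0.8, 0.8))
  t2 <- filter_spec("tabulated", freqs = c(1, 10), magnitude = c(0.5, 0.5))
  both <- apply_filters(S, list(t1, t2), f)
  expect_equal(both[f == f0], 0.4)   # product of magnitudes
  expect_equal(apply_filters(S, list(t2, t1), f), both)  # order-free
  expect_equal(apply_filters(S, list(t1, t2), f, combine = "sum")[f == f0], 1.3)

  # Butterworth magnitude is 1/sqrt(2) at the cutoff
  bw <- filter_spec("highpass_butter", order = 3, cutoff = 2)
  expect_equal(filter_response(bw, c(2, 20))[1], 1 / sqrt(2), tolerance = 1e-12)

  # unity filters are the identity
  u <- filter_spec("tabulated", freqs = c(1, 10), magnitude = c(1, 1))
  expect_equal(apply_filters(S, list(u, u), f), S)

  short <- filter_spec("tabulated", freqs = c(2, 5), magnitude = c(1, 1))
  expect_error(apply_filters(S, list(short), f), "cover")
})

test_that("condition designs expand parameters on the unconstrained scale", {
  des <- condition_design(2, 5)
  th <- c(0.1, -0.2, 0.3, 0, 0.5,   # baseline
          0, 0, -0.3, 0, 0)         # task deltas
  expect_equal(condition_expand(th, des, 1), th[1:5])
  t2 <- condition_expand(th, des, 2)
  expect_equal(t2[3], 0)  # 0.3 - 0.3
  # delta -0.3 on a log-link height halves relative ratio exp(-0.3)
  b <- band("a", 8, 12)
  h1 <- apply_links(th[1:5], list(b))$peaks$h
  h2 <- apply_links(t2, list(b))$peaks$h
  expect_equal(h2 / h1, exp(-0.3), tolerance = 1e-12)

  # all-zero deltas give identical conditions
  th0 <- c(th[1:5], rep(0, 5))
  expect_equal(condition_expand(th0, des, 1), condition_expand(th0, des, 2))

  expect_error(condition_expand(th, des, 3), "out of range")
  expect_error(condition_expand(th[1:5], des, 1), "length")
})

test_that("noise covariance is exp(-lambda) R", {
  nm <- noise_model(n_freq = 4, log_precision = 0)
  expect_equal(noise_covariance(nm), diag(4))
  nm4 <- noise_model(n_freq = 3, log_precision = log(4))
  expect_equal(noise_covariance(nm4), 0.25 * diag(3), tolerance = 1e-12)

  # scaling is linear in exp(-lambda)
  l <- rnorm(1)
  nma <- noise_model(n_freq = 2, log_precision = l)
  nmb <- noise_model(n_freq = 2, log_precision = l + log(2))
  expect_equal(noise_covariance(nma), 2 * noise_covariance(nmb),
               tolerance = 1e-12)

  # squared-exponential correlation tends to the identity as the length
  # scale shrinks
  f <- seq(1, 8)
  nk <- noise_model(log_precision = 0, length_scale = 1e-3, freqs = f)
  expect_equal(noise_covariance(nk), diag(length(f)), tolerance = 1e-10)

  bad <- matrix(c(1, 2, 2, 1), 2)  # unit diagonal but indefinite
  expect_error(noise_model(R = bad), "semi-definite")
})

test_that("default priors follow the documented pattern", {
  sp2 <- model_spec(list(band("alpha", 8, 12), band("beta", 12, 30)))
  pr <- default_priors(sp2)
  expect_length(pr$mean, 8)             # 2 + 3 * 2
  expect_true(all(pr$mean == 0))
  expect_equal(diag(pr$cov), c(3, 3, rep(2, 6)), ignore_attr = TRUE)
  expect_equal(pr$hyper_mean, 0)
  expect_equal(pr$hyper_var, 1)

  expect_length(default_priors(model_spec(list()))$mean, 2)

  # condition designs repeat the pattern per block
  des <- condition_design(2, 5)
  spc <- model_spec(list(band("alpha", 8, 12)), condition_design = des)
  prc <- default_priors(spc)
  expect_length(prc$mean, 10)
  expect_equal(diag(prc$cov), rep(c(3, 3, 2, 2, 2), 2), ignore_attr = TRUE)
})

test_that("spectra are scaled to the reference implied variance", {
  f <- seq(1, 16, 0.5)
  df <- 0.5
  S <- runif(length(f), 0.5, 2)
  v <- sum(S^2) * df
  sc <- scale_spectrum(S, f)
  expect_equal(sc$factor, sqrt(8 / v), tolerance = 1e-12)
  expect_equal(sum(sc$scaled^2) * df, 8, tolerance = 1e-10)

  S2 <- S * sqrt(2 / v)   # implied variance 2 -> factor 2
  expect_equal(scale_spectrum(S2, f)$factor, 2, tolerance = 1e-10)
  S32 <- S * sqrt(32 / v) # implied variance 32 -> factor 0.5
  expect_equal(scale_spectrum(S32, f)$factor, 0.5, tolerance = 1e-10)

  expect_error(scale_spectrum(rep(0, length(f)), f), "all-zero")
})

test_that("analytic Jacobian matches central finite differences", {
  b <- list(band("alpha", 8, 12), band("beta", 12, 30))
  sp <- model_spec(b)
  f <- seq(1, 32, 0.5)
  set.seed(7)
  for (i in 1:5) {
    th <- rnorm(8, 0, 1)
    J <- spectrum_jacobian(th, sp, f)
    Jfd <- fd_jacobian(function(t) as.numeric(bsdr:::.model_predict(sp, t, f)), th)
    expect_lt(max(abs(J - Jfd)) / max(abs(Jfd)), 1e-5)
  }

  # aperiodic-only model: d S / d theta_power equals the aperiodic term
  sp0 <- model_spec(list())
  th0 <- c(0.4, -0.3)
  J0 <- spectrum_jacobian(th0, sp0, f)
  nat0 <- apply_links(th0, list())
  expect_equal(J0[, 1], nat0$gamma * f^nat0$alpha, tolerance = 1e-12)

  # d S / d theta_h at the peak mode equals the height
  th1 <- c(0, 0, log(2), 0.3, log(1.5))
  sp1 <- model_spec(b[1])
  nat1 <- apply_links(th1, b[1])
  fm <- c(5, nat1$peaks$m)
  J1 <- spectrum_jacobian(th1, sp1, fm)
  expect_equal(J1[2, 3], nat1$peaks$h, tolerance = 1e-12)

  # log domain derivatives check out too
  splog <- model_spec(b, domain = "log")
  th <- rnorm(8, 0, 0.5)
  Jl <- spectrum_jacobian(th, splog, f)
  Jlfd <- fd_jacobian(function(t) as.numeric(bsdr:::.model_predict(splog, t, f)), th)
  expect_lt(max(abs(Jl - Jlfd)) / max(abs(Jlfd)), 1e-5)
})

test_that("model construction validates its inputs", {
  expect_error(band("a", 12, 8), "lower < upper")
  expect_error(model_spec(list(band("a", 8, 12), band("b", 10, 20))),
               "disjoint")
  expect_error(model_spec(list(band("a", 8, 12), band("a", 13, 20))),
               "unique")
  expect_silent(model_spec(list(band("a", 8, 12), band("b", 12, 30))))
  expect_equal(length(standard_band("gamma")), 3L)
  expect_error(bsdr:::.validate_grid(c(3, 2, 1)), "increasing")
})
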