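test_that("a tight hierarchy reduces to the subject posterior", {
  set.seed(31)
  p <- 3
  post <- list(mean = c(0.4, -0.7, 1.1), cov = diag(0.05, p), free_energy = 0)
  priors <- prior_spec(rep(0, p), diag(2, p))
  # random-effects precision forced huge: theta^(1) = X theta^(2) exactly
  g <- peb_fit(list(post), priors, matrix(1, 1, 1), gamma_fixed = 30)
  expect_lt(max(abs(g$beta_mean[, 1] - post$mean)), 1e-3)
})

test_that("a known covariate slope is recovered", {
  set.seed(32)
  hier <- make_linear_hierarchy(K = 24)
  g <- peb_fit(hier$posteriors, hier$priors, group_design(hier$x))
  p <- 2
  se <- sqrt(diag(g$beta_cov))
  # true slope on parameter 1 within 3 posterior sd
  expect_lt(abs(g$beta_mean[1, 2] - hier$b[1]), 3 * se[p + 1])
  # intercepts near the true group means (the design is mean-centered, so
  # the intercept estimates a + b * mean(x))
  expect_lt(max(abs(g$beta_mean[, 1] - (hier$a + hier$b * mean(hier$x)))), 0.2)
})

test_that("no effect is reported when subjects are identical", {
  set.seed(33)
  p <- 2; K <- 16
  posts <- lapply(seq_len(K), function(k) {
    list(mean = c(0.5, -0.3), cov = diag(0.04, p), free_energy = 0)
  })
  priors <- prior_spec(rep(0, p), diag(3, p))
  g <- peb_fit(posts, priors, group_design(runif(K)))
  se <- sqrt(diag(g$beta_cov))
  expect_true(all(abs(g$beta_mean[, 2]) <= 2 * se[(p + 1):(2 * p)] + 1e-8))
})

test_that("the group mean stays within the spread of subject means", {
  set.seed(34)
  p <- 2; K <- 12
  means <- cbind(rnorm(K, 1, 0.3), rnorm(K, -0.5, 0.3))
  posts <- lapply(seq_len(K), function(k) {
    list(mean = means[k, ], cov = diag(0.02, p), free_energy = 0)
  })
  priors <- prior_spec(rep(0, p), diag(3, p))
  g <- peb_fit(posts, priors, matrix(1, K, 1))
  for (j in 1:p) {
    expect_gte(g$beta_mean[j, 1], min(means[, j]) - 1e-6)
    expect_lte(g$beta_mean[j, 1], max(means[, j]) + 1e-6)
  }
})

test_that("a pure-noise regressor usually costs free energy", {
  set.seed(35)
  worse <- 0
  n_rep <- 9
  for (r in seq_len(n_rep)) {
    hier <- make_linear_hierarchy(K = 16, b = c(0, 0))
    g0 <- peb_fit(hier$posteriors, hier$priors, matrix(1, 16, 1))
    g1 <- peb_fit(hier$posteriors, hier$priors,
                  group_design(rnorm(16)))  # regressor unrelated to anything
    worse <- worse + (g1$F_total < g0$F_total)
  }
  expect_gt(worse, n_rep / 2)
})

test_that("credible bands have the right width and respect links", {
  # hand-built group posterior: one parameter, intercept + slope
  mk <- function(pname) structure(list(
    beta_mean = matrix(c(0.5, 0.2), 1, 2,
                       dimnames = list(pname, c("intercept", "x"))),
    beta_cov = diag(c(1, 0)),   # sd 1 on the intercept, none on the slope
    param_names = pname,
    design = list(X2 = cbind(1, c(-1, 1)), names = c("intercept", "x"),
                  centers = c(0, 0)),
    n_subjects = 2
  ), class = "bsd_group")
  # a parameter with no recognised link stays on the unconstrained scale:
  # half-width is the 95th-percentile z
  cb <- credible_band(mk("custom1"), "custom1", covariate = c(0), level = 0.90)
  expect_equal(cb$upper - cb$mean, qnorm(0.95), tolerance = 1e-4)

  # exp-linked parameters: endpoints are exp of the unconstrained endpoints
  g <- mk("alpha_h")
  spec <- model_spec(list(band("alpha", 8, 12)))
  cbe <- credible_band(g, "alpha_h", covariate = c(0.5), level = 0.90,
                       spec = spec)
  expect_equal(cbe$lower, exp(0.5 + 0.2 * 0.5 - qnorm(0.95)), tolerance = 1e-6)
  expect_equal(cbe$upper, exp(0.5 + 0.2 * 0.5 + qnorm(0.95)), tolerance = 1e-6)
  expect_true(all(cbe$lower <= cbe$mean & cbe$mean <= cbe$upper))

  # zero posterior covariance collapses the band
  g$beta_cov <- diag(c(0, 0))
  cb0 <- credible_band(g, 1, covariate = c(-1, 0, 1))
  expect_equal(cb0$lower, cb0$upper)

  expect_error(credible_band(g, "nope", 0), "unknown")
})

test_that("nominal 90% bands cover a linear effect at a reasonable rate", {
  set.seed(36)
  n_rep <- 20
  hits <- 0
  for (r in seq_len(n_rep)) {
    hier <- make_linear_hierarchy(K = 24)
    g <- peb_fit(hier$posteriors, hier$priors, group_design(hier$x))
    se <- sqrt(diag(g$beta_cov))[3]   # slope of parameter 1
    ci <- g$beta_mean[1, 2] + c(-1, 1) * qnorm(0.95) * se
    hits <- hits + (hier$b[1] >= ci[1] && hier$b[1] <= ci[2])
  }
  expect_gte(hits / n_rep, 0.8)
})

test_that("group spectra interpolate over the covariate", {
  spec <- model_spec(list(band("alpha", 8, 12)))
  f <- seq(4, 16, 0.25)
  mk_group <- function(slope_m) {
    structure(list(
      beta_mean = matrix(c(0, 0, log(2), 0, 0,
                           0, 0, 0, slope_m, 0), 5, 2,
                         dimnames = list(param_names(spec),
                                         c("intercept", "x"))),
      beta_cov = diag(0, 10), param_names = param_names(spec),
      design = list(X2 = cbind(1, c(-1, 1)), names = c("intercept", "x"),
                    centers = c(0, 0)),
      n_subjects = 2
    ), class = "bsd_group")
  }
  # zero slope: identical spectra across the covariate
  S0 <- interpolate_group_spectrum(mk_group(0), spec, f, c(-1, 0, 1))
  expect_equal(S0[, 1], S0[, 3])
  # negative slope on the centre parameter: peak frequency decreases
  Sm <- interpolate_group_spectrum(mk_group(-1.5), spec, f, c(-1, 0, 1))
  peak_at <- apply(Sm - outer(1 * f^-1, rep(1, 3)), 2, function(s) f[which.max(s)])
  expect_true(all(diff(peak_at) < 0))
  expect_warning(
    interpolate_group_spectrum(mk_group(0), spec, f, 5),
    "support"
  )
})

test_that("peb_fit validates designs", {
  post <- list(mean = c(0, 0), cov = diag(0.1, 2), free_energy = 0)
  priors <- prior_spec(c(0, 0), diag(2))
  expect_error(peb_fit(list(post, post), priors, cbind(1, c(1, 1))),
               "rank deficient")
  expect_error(peb_fit(list(post), priors, cbind(1, 0.5)), "2 subjects")
  expect_error(peb_fit(list(post, post), priors, matrix(1, 3, 1)), "rows")
})
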