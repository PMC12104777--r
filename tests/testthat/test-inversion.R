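test_that("linear forward model with known noise matches the conjugate closed form", {
  set.seed(11)
  n <- 30; p <- 4
  X <- matrix(rnorm(n * p), n, p)
  theta <- c(1, -0.5, 0.25, 2)
  tau <- 4
  y <- as.numeric(X %*% theta + rnorm(n, 0, 1 / sqrt(tau)))
  mu0 <- c(0.2, 0, -0.1, 0)
  S0 <- diag(c(1, 2, 0.5, 3))
  oracle <- conjugate_linear_oracle(X, y, mu0, S0, tau)
  post <- vl_fit(y, function(th) as.numeric(X %*% th), function(th) X,
                 prior_mean = mu0, prior_cov = S0, lambda_fixed = log(tau))
  expect_lt(max(abs(post$mean - oracle$mean)) / max(abs(oracle$mean)), 1e-6)
  expect_lt(max(abs(post$cov - oracle$cov)) / max(abs(oracle$cov)), 1e-6)
  expect_lt(abs(post$free_energy - oracle$logev) / abs(oracle$logev), 1e-6)
  expect_equal(post$complexity_lambda, 0)

  # posterior cannot be wider than the prior in the conjugate case
  expect_lte(max(eigen(post$cov)$values), max(eigen(S0)$values) + 1e-10)
})

test_that("free-energy decomposition behaves like accuracy minus KLs", {
  # posterior equal to the prior has zero theta-complexity
  expect_equal(bsdr:::.gaussian_kl(c(1, 2), diag(2), c(1, 2), diag(2)), 0)
  # 1-D KL of N(1,1) from N(0,1) is 1/2
  expect_equal(bsdr:::.gaussian_kl(1, matrix(1), 0, matrix(1)), 0.5)
  # and the decomposition identity holds on a real fit
  f <- seq(2, 30, 0.5)
  sp <- model_spec(list(band("alpha", 8, 12)))
  set.seed(12)
  y <- evaluate_spectrum(apply_links(c(0, 0, 0.5, 0, 0), sp$bands), f) +
    rnorm(length(f), 0, 0.05)
  post <- fit_spectrum(y, f, sp, scale = FALSE)
  expect_equal(post$free_energy,
               post$accuracy - post$complexity_theta - post$complexity_lambda,
               tolerance = 1e-10)
  expect_gte(post$complexity_theta, 0)
  expect_gte(post$complexity_lambda, 0)
})

test_that("a high-precision single-peak simulation is recovered within 3 sd", {
  f <- seq(1, 32, 0.5)
  b <- band("alpha", 8, 12)
  sp <- model_spec(list(b))
  th_true <- natural_to_raw(
    structure(list(gamma = 1.2, alpha = -1.1,
                   peaks = data.frame(name = "alpha", h = 1.5, m = 10.2, s = 1.3)),
              class = "bsd_natural"), list(b))
  set.seed(13)
  y <- as.numeric(bsdr:::.model_predict(sp, th_true, f)) +
    rnorm(length(f), 0, exp(-4))
  post <- fit_spectrum(y, f, sp, scale = FALSE)
  expect_true(post$converged)
  sd_post <- sqrt(diag(post$cov))
  expect_true(all(abs(post$mean - th_true) <= 3 * sd_post))
})

test_that("a peak model on peakless data is conservative", {
  f <- seq(1, 32, 0.5)
  sp0 <- model_spec(list())
  sp1 <- model_spec(list(band("alpha", 8, 12)))
  set.seed(14)
  y <- evaluate_spectrum(apply_links(c(0, 0), list()), f) +
    rnorm(length(f), 0, exp(-4))
  p0 <- fit_spectrum(y, f, sp0, scale = FALSE)
  p1 <- fit_spectrum(y, f, sp1, scale = FALSE)
  # fitted peak height concentrates near zero on the natural scale
  expect_lt(apply_links(p1$mean, sp1$bands)$peaks$h, 0.05)
  # the simpler model wins on free energy
  expect_lt(p1$free_energy, p0$free_energy)
})

test_that("the free energy is non-decreasing over accepted iterations and fits are deterministic", {
  f <- seq(1, 32, 0.5)
  sp <- model_spec(list(band("alpha", 8, 12)))
  set.seed(15)
  y <- as.numeric(bsdr:::.model_predict(sp, c(0.2, -0.1, 0.7, 0.4, 0.1), f)) +
    rnorm(length(f), 0, 0.05)
  p1 <- fit_spectrum(y, f, sp, scale = FALSE)
  p2 <- fit_spectrum(y, f, sp, scale = FALSE)
  expect_identical(p1$mean, p2$mean)
  expect_identical(p1$free_energy, p2$free_energy)
  expect_true(all(diff(p1$F_trace) >= 0))
})

test_that("finite-difference and analytic Jacobian routes agree on the fit", {
  f <- seq(2, 30, 1)
  sp <- model_spec(list(band("alpha", 8, 12)))
  set.seed(16)
  y <- as.numeric(bsdr:::.model_predict(sp, c(0, -0.2, 0.4, 0.2, 0), f)) +
    rnorm(length(f), 0, 0.05)
  pa <- fit_spectrum(y, f, sp, scale = FALSE)
  pf <- fit_spectrum(y, f, sp, scale = FALSE,
                     opts = fit_options(jacobian = "finite_diff"))
  expect_equal(pa$mean, pf$mean, tolerance = 1e-4)
  expect_equal(pa$free_energy, pf$free_energy, tolerance = 1e-3)
})

test_that("condition-stacked fits share the noise precision and recover deltas", {
  b <- band("alpha", 8, 12)
  des <- condition_design(2, 5)
  sp <- model_spec(list(b), condition_design = des)
  f <- seq(1, 32, 0.5)
  th_full <- c(0.1, 0, log(2), 0.2, 0.2,      # baseline
               0, 0, log(0.25), 0, 0)         # task: height x 0.25
  set.seed(17)
  Y <- bsdr:::.model_predict(sp, th_full, f) +
    matrix(rnorm(2 * length(f), 0, exp(-3)), length(f), 2)
  post <- fit_spectrum(Y, f, sp, scale = FALSE)
  expect_true(post$converged)
  # task height delta recovered: exp(delta_h) ~ 0.25
  expect_equal(exp(post$mean[["cond2_delta.alpha_h"]]), 0.25, tolerance = 0.1)
  expect_error(fit_spectrum(Y[, 1], f, sp, scale = FALSE), "condition")
})

test_that("fit_spectrum validates grids and dimensions", {
  sp <- model_spec(list())
  expect_error(fit_spectrum(rnorm(5), seq(1, 10, 0.5), sp), "rows")
  expect_error(fit_spectrum(c(1, NA, 1), c(1, 2, 3), sp, scale = FALSE),
               "finite")
})
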