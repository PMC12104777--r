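# Seeded-RNG guard: run expr with a temporary seed, restoring global state.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Configuration of the two-condition covariate-modulated group simulation
#'
#' Emulates a rest/task experiment: every subject has a large alpha-band peak
#' and a smaller beta-band peak over a 1/f background at rest, both peaks
#' strongly attenuated during task, with a continuous per-subject covariate
#' (an age-like trait) modulating the generative parameters linearly.
#' Spectra are produced directly in the frequency domain; no time-domain
#' signal is synthesised.
#'
#' Generative parameters at covariate value `x` (natural scale, rest):
#' aperiodic amplitude `1 - 0.3 x`, exponent `-(1 + 0.3 x)`, alpha peak
#' height `2.8 - 0.8 x` at `11 - 2 x` Hz (width 1.2 Hz), beta peak height
#' 0.25 at 20 Hz (width 3 Hz). Task multiplies both peak heights by
#' `task_attenuation`. Subject-level parameter noise is centred Gaussian with
#' sd equal to `param_noise_frac` times the parameter mean; observation noise
#' is white with log-precision `obs_log_precision`.
#'
#' @param n_subjects Number of subjects (default 32).
#' @param freqs Frequency grid in Hz (default 1 to 32 by 0.5).
#' @param alpha_band,beta_band The two peak bands.
#' @param task_attenuation Multiplier on both peak heights in the task
#'   condition (default 0.25).
#' @param param_noise_frac Parameter noise sd as a fraction of the mean
#'   (default 0.15).
#' @param obs_log_precision Observation-noise log-precision (default 9).
#' @param covariate_range Range of the uniform covariate (default `c(0, 1)`).
#' @param seed RNG seed.
#' @return An object of class `bsd_group_sim_config`.
#' @export
group_sim_config <- function(n_subjects = 32L, freqs = seq(1, 32, by = 0.5),
                             alpha_band = band("alpha", 8, 12),
                             beta_band = band("beta", 12, 30),
                             task_attenuation = 0.25,
                             param_noise_frac = 0.15,
                             obs_log_precision = 9,
                             covariate_range = c(0, 1),
                             seed = 1L) {
  if (n_subjects < 1L) .stopf("need at least one subject")
  if (param_noise_frac < 0) .stopf("param_noise_frac must be >= 0")
  freqs <- .validate_grid(freqs)
  structure(
    list(n_subjects = as.integer(n_subjects), freqs = freqs,
         alpha_band = alpha_band, beta_band = beta_band,
         task_attenuation = task_attenuation,
         param_noise_frac = param_noise_frac,
         obs_log_precision = obs_log_precision,
         covariate_range = covariate_range, seed = seed),
    class = "bsd_group_sim_config"
  )
}

# Natural-scale generative means at covariate x (rest condition).
.group_truth_at <- function(x, cfg) {
  list(
    gamma = 1.0 - 0.3 * x,
    alpha = -(1.0 + 0.3 * x),
    h_alpha = 2.8 - 0.8 * x,
    m_alpha = 11 - 2 * x,
    s_alpha = 1.2,
    h_beta = 0.25,
    m_beta = 20,
    s_beta = 3.0
  )
}

#' Simulate the two-condition covariate-modulated group dataset
#'
#' For each subject: draw the covariate, compute the generative parameters,
#' perturb them with centred Gaussian noise (sd = `param_noise_frac` x mean,
#' on the natural scale), evaluate the model spectrum in both conditions and
#' add white observation noise. With the defaults this yields 64 spectra
#' (32 subjects x rest/task).
#'
#' @param cfg A [group_sim_config()].
#' @return List of class `bsd_group_sim`: `freqs`, `spectra`
#'   (`n_freq x 2 n_subjects` matrix, columns `s01_rest`, `s01_task`, ...),
#'   `covariate`, `condition` (per column), `subject` (per column), `truth`
#'   (data frame of per-subject natural-scale parameters, rest condition),
#'   `config`.
#' @examples
#' sim <- simulate_group(group_sim_config(n_subjects = 2, seed = 1))
#' dim(sim$spectra)
#' @export
simulate_group <- function(cfg = group_sim_config()) {
  .with_seed(cfg$seed, {
    K <- cfg$n_subjects
    f <- cfg$freqs
    n <- length(f)
    noise_sd <- exp(-cfg$obs_log_precision / 2)
    x <- stats::runif(K, cfg$covariate_range[1], cfg$covariate_range[2])
    spectra <- matrix(0, n, 2L * K)
    cols <- character(2L * K)
    cond <- character(2L * K)
    subj <- integer(2L * K)
    truth <- vector("list", K)
    bands <- list(cfg$alpha_band, cfg$beta_band)
    clip_m <- function(m, b) {
      margin <- 0.02 * (b$upper - b$lower)
      min(max(m, b$lower + margin), b$upper - margin)
    }
    for (k in seq_len(K)) {
      mu <- .group_truth_at(x[k], cfg)
      frac <- cfg$param_noise_frac
      pert <- lapply(mu, function(v) v + stats::rnorm(1, 0, frac * abs(v)))
      # keep the perturbed draw inside the natural-parameter domain
      pert$gamma <- max(pert$gamma, 1e-3)
      pert$alpha <- min(pert$alpha, -1e-3)
      pert$h_alpha <- max(pert$h_alpha, 1e-3)
      pert$h_beta <- max(pert$h_beta, 1e-3)
      pert$s_alpha <- max(pert$s_alpha, 1e-2)
      pert$s_beta <- max(pert$s_beta, 1e-2)
      pert$m_alpha <- clip_m(pert$m_alpha, cfg$alpha_band)
      pert$m_beta <- clip_m(pert$m_beta, cfg$beta_band)
      for (cc in 1:2) {
        att <- if (cc == 2L) cfg$task_attenuation else 1
        nat <- structure(list(
          gamma = pert$gamma, alpha = pert$alpha,
          peaks = data.frame(
            name = c("alpha", "beta"),
            h = c(pert$h_alpha * att, pert$h_beta * att),
            m = c(pert$m_alpha, pert$m_beta),
            s = c(pert$s_alpha, pert$s_beta),
            stringsAsFactors = FALSE
          )
        ), class = "bsd_natural")
        S <- evaluate_spectrum(nat, f)
        j <- 2L * (k - 1L) + cc
        spectra[, j] <- S + stats::rnorm(n, 0, noise_sd)
        cols[j] <- sprintf("s%02d_%s", k, c("rest", "task")[cc])
        cond[j] <- c("rest", "task")[cc]
        subj[j] <- k
      }
      truth[[k]] <- as.data.frame(pert)
    }
    colnames(spectra) <- cols
    truth <- do.call(rbind, truth)
    truth$covariate <- x
    truth$subject <- seq_len(K)
    structure(
      list(freqs = f, spectra = spectra, covariate = x, condition = cond,
           subject = subj, truth = truth, config = cfg),
      class = "bsd_group_sim"
    )
  })
}

#' Configuration of the single-peak detection benchmark
#'
#' Random spectra with (or without) one Gaussian peak in a chosen band over a
#' random 1/f background, at a controlled signal-to-noise ratio. Half the
#' spectra carry a peak (labels for ROC analysis are balanced). The peak
#' height follows the amplitude-dB convention
#' `h = 10^(snr_db/20) * (A(m) + sd_noise)`; the observation-noise variance
#' is `exp(-noise_log_precision)` times the squared mean aperiodic level.
#'
#' @param bnd Target [band()] (or preset name for [standard_band()]).
#' @param n_spectra Total number of spectra (default 1024; balanced classes).
#' @param freqs Frequency grid (default 1 to 64 Hz by 0.5 — 127 bins).
#' @param snr_db Peak signal-to-noise ratio in dB.
#' @param noise_log_precision Output-noise log-precision (default 4).
#' @param exponent_range,amplitude_log10_range,width_frac_range Random ranges
#'   for the aperiodic exponent, log10 amplitude, and peak width (fraction of
#'   bandwidth).
#' @param seed RNG seed.
#' @return An object of class `bsd_benchmark_config`.
#' @export
benchmark_config <- function(bnd = "alpha", n_spectra = 1024L,
                             freqs = seq(1, 64, by = 0.5), snr_db = 0,
                             noise_log_precision = 4,
                             exponent_range = c(-2, -0.5),
                             amplitude_log10_range = c(-0.5, 0.5),
                             width_frac_range = c(0.05, 0.25),
                             seed = 1L) {
  if (is.character(bnd)) bnd <- standard_band(bnd)
  freqs <- .validate_grid(freqs)
  if (bnd$lower < min(freqs) || bnd$upper > max(freqs)) {
    .stopf("band [%g, %g] outside the frequency grid [%g, %g]",
           bnd$lower, bnd$upper, min(freqs), max(freqs))
  }
  if (n_spectra < 2L) .stopf("need at least 2 spectra")
  structure(
    list(band = bnd, n_spectra = as.integer(n_spectra), freqs = freqs,
         snr_db = snr_db, noise_log_precision = noise_log_precision,
         exponent_range = exponent_range,
         amplitude_log10_range = amplitude_log10_range,
         width_frac_range = width_frac_range, seed = seed),
    class = "bsd_benchmark_config"
  )
}

#' Simulate the single-peak detection benchmark
#'
#' @param cfg A [benchmark_config()].
#' @return List of class `bsd_benchmark`: `freqs`, `spectra`
#'   (`n_freq x n_spectra`), `labels` (1 = peak present), `truth` (data frame
#'   of generative parameters; `h = 0` rows are the matched no-peak
#'   negatives), `config`.
#' @examples
#' bm <- simulate_benchmark(benchmark_config(n_spectra = 4, seed = 1))
#' table(bm$labels)
#' @export
simulate_benchmark <- function(cfg = benchmark_config()) {
  .with_seed(cfg$seed, {
    f <- cfg$freqs
    n <- length(f)
    N <- cfg$n_spectra
    n_pos <- N %/% 2L
    labels <- rep(c(1L, 0L), c(n_pos, N - n_pos))
    spectra <- matrix(0, n, N)
    truth <- data.frame(gamma = numeric(N), alpha = numeric(N),
                        h = numeric(N), m = NA_real_, s = NA_real_,
                        noise_sd = numeric(N))
    b <- cfg$band
    bw <- b$upper - b$lower
    for (i in seq_len(N)) {
      gam <- 10^stats::runif(1, cfg$amplitude_log10_range[1],
                             cfg$amplitude_log10_range[2])
      al <- stats::runif(1, cfg$exponent_range[1], cfg$exponent_range[2])
      A <- gam * f^al
      noise_sd <- sqrt(exp(-cfg$noise_log_precision)) * mean(A)
      S <- A
      if (labels[i] == 1L) {
        m <- stats::runif(1, b$lower, b$upper)
        s <- stats::runif(1, cfg$width_frac_range[1],
                          cfg$width_frac_range[2]) * bw
        h <- 10^(cfg$snr_db / 20) * (gam * m^al + noise_sd)
        S <- S + h * exp(-((f - m) / s)^2 / 2)
        truth$h[i] <- h; truth$m[i] <- m; truth$s[i] <- s
      }
      truth$gamma[i] <- gam; truth$alpha[i] <- al; truth$noise_sd[i] <- noise_sd
      spectra[, i] <- S + stats::rnorm(n, 0, noise_sd)
    }
    colnames(spectra) <- sprintf("sp%04d", seq_len(N))
    structure(
      list(freqs = f, spectra = spectra, labels = labels, truth = truth,
           config = cfg),
      class = "bsd_benchmark"
    )
  })
}
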