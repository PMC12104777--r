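---
title: "Methods: models, inversion and design choices in bsdr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, inversion and design choices in bsdr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsdr)
```

This vignette documents the statistical model behind `bsdr`, the default
choices and why they were made, what the built-in simulators do and do not
emulate, and the numerical details a careful user should know. It states no
empirical result that the package's test suite or `scripts/acceptance.R` do
not themselves compute.

## 1. The generative model of a spectrum

`bsdr` models an amplitude spectral density (the square root of the PSD) on
a grid of frequencies `f > 0` as an aperiodic power-law background plus one
Gaussian peak per frequency band:

$$ S(f) = \gamma f^{\alpha} + \sum_{i=1}^{N} h_i
   \exp\!\left(-\tfrac{1}{2}\Big(\tfrac{f - m_i}{s_i}\Big)^2\right), $$

observed through additive Gaussian noise with covariance
$C_f = e^{-\lambda} R_f$. The Gaussian noise is an approximation — spectral
estimates of finite data are chi-like — but it is what makes fully
conjugate-style variational updates possible, and it is adequate once
several segments have been averaged into the spectrum. A `domain = "log"`
variant replaces the aperiodic term by its logarithm
($\log\gamma + \alpha\log f$) for users who prefer fitting log-PSDs; peaks
remain additive in that domain.

**One peak per band.** Bands are disjoint intervals supplied by the user
(e.g. alpha 8–12 Hz). Restricting each band to at most one peak keeps
parameters identifiable and comparable across subjects — two peaks can
never trade places, and "the alpha frequency" means the same coordinate in
every subject. The cost is that a genuinely split peak inside one band is
fit by a single bump; widen or split the band if that matters.

**Link functions.** All constrained parameters are reparameterised so the
unconstrained vector $\theta$ can carry a Gaussian prior:
$\gamma = e^{\theta}$, $\alpha = -e^{\theta}$, $h_i = e^{\theta}$,
$s_i = e^{\theta}$, and the peak centre is softly clipped into its band by
a logistic sigmoid, $m_i = L_i + \sigma(\theta)(U_i - L_i)$ with
$\sigma(0) = 1/2$. The sigmoid was chosen over a hard clamp because it is
smooth (Gauss–Newton needs derivatives) and over other maps
$\mathbb{R}\to(0,1)$ because its symmetric S-shape places the prior mass at
mid-band. Exponential links give positive quantities log-normal
distributions, the natural scale family for amplitudes.

**Default priors.** Unconstrained means 0; variances 3 for the aperiodic
pair and 2 for peak parameters; noise log-precision $\lambda \sim N(0, 1)$.
These are deliberately weak: variance 2 on a sigmoid-linked centre spreads
mass over essentially the whole band, and variance 3 on $\log\gamma$ covers
two orders of magnitude of amplitude. The prior scales are read as
variances (not standard deviations), matching the covariance convention of
the Gaussian prior family; `default_priors()` exposes both knobs. The
$N(0,1)$ hyperprior on $\lambda$ is a pragmatic weakly-informative default
— nothing in the model fixes the noise scale a priori — and because the
data are first rescaled (below) it is rarely influential in the fits the
package targets.

**Variance-8 rescaling.** Before fitting, spectra are scaled so the implied
signal variance $\sum_f S^2(f)\,\Delta f$ equals 8 (`scale_spectrum()`,
`scale = TRUE` by default). This frees the priors above from the arbitrary
units of the recording equipment; the multiplicative factor is stored on
the posterior so results can be mapped back. Disable it when absolute
units carry meaning.

**Filters.** Recorded data have usually passed high-/low-pass filters that
suppress amplitude near the band edges; if the model ignores this it will
chase the attenuated bins with spurious parameters. `filter_spec()`
supports Butterworth magnitude responses and tabulated responses, composed
by default as a *product* of magnitudes — the physically correct behaviour
of a filter cascade. A literal additive composition (`combine = "sum"`) is
available for compatibility with the additive transfer-function notation
some sources use, but the product is the default because two cascaded
half-gain filters attenuate to 0.25, not 1.0.

**Condition effects.** Within-subject conditions (rest/task) enter as
linear maps on the unconstrained scale: condition $c$ uses parameters
$X_c\theta$. The default encoding is baseline + per-condition deltas, so a
delta of $\ln 0.25$ on a log-linked height means "this condition attenuates
the peak to a quarter". Deltas on the unconstrained scale keep every
condition's parameters automatically inside their constraint sets.

## 2. Inversion: variational Laplace

`fit_spectrum()` maximises a free energy
$F = \text{accuracy} - \text{KL}(q_\theta\|p_\theta) -
\text{KL}(q_\lambda\|p_\lambda)$ over a fixed-form Gaussian posterior
$q_\theta = N(m, V)$ and $q_\lambda = N(\ell, v)$. $F$ is a lower-bound
approximation of the log evidence $\ln p(Y)$; its decomposition is exposed
on every posterior object, and the accuracy term uses the expected
precision $E[e^{\lambda}] = e^{\ell + v/2}$ together with the Gauss–Newton
correction $\mathrm{tr}(J^\top R^{-1} J\, V)$ for posterior spread.

The schedule: damped Gauss–Newton steps on $m$ (Levenberg–Marquardt,
damping starting at $10^{-2}$, multiplied by 8 on a rejected step, halved
on acceptance) alternate with 1-D Newton updates of $\lambda$'s variational
energy, which is concave. A joint step is accepted only if $F$ increases,
so $F$ is non-decreasing over accepted iterations (`F_trace` records it).
Convergence is declared after three consecutive accepted iterations with
$|\Delta F| < 10^{-3}$, or at 128 iterations, or when no damping level
yields an increase. Derivatives are analytic through the links
(`spectrum_jacobian()`, verified against central differences); a
finite-difference fallback exists for custom forward models.

Two properties anchor correctness: for a *linear* forward model with fixed
noise precision the posterior and $F$ equal the conjugate closed form
exactly (the test suite checks to 1e-6 relative), and for nonlinear models
the same identities hold at the Laplace fixed point up to the Gauss–Newton
approximation of the Hessian.

**Local optima and starts.** The free-energy landscape of a peak model is
multimodal in the peak centre: a narrow low peak far from the band centre
is invisible to a search started mid-band, because the ascent first kills
the (misplaced) peak's height and the centre gradient then vanishes. Fits
default to starting at the prior mean, which is fine for prominent peaks.
The evidence-based detector `detect_evidence()` additionally starts the
informed model from a deterministic data-driven guess — aperiodic
parameters from an out-of-band log-log least-squares fit, the peak at the
largest in-band excursion above it — and reports whichever start attains
the higher free energy. Since $F$ arbitrates, extra starts can only tighten
the evidence approximation; both starts are deterministic, so detection
remains reproducible.

**Overconfidence.** Variational posteriors tend to be narrower than the
exact ones, especially after nonlinear links; the frequency of a strong
peak is the most affected quantity in practice. The package implements no
correction (none is established for this family); consumers of credible
intervals should treat nominal 90% as optimistic. The PEB coverage test
accepts ≥ 80% empirical coverage at nominal 90% for exactly this reason.

## 3. Model comparison

Free-energy differences approximate log Bayes factors
($\ln\beta_{12} \approx F_1 - F_2$). `enumerate_model_space()` builds one
model per subset of the candidate bands in binary-counting order (first
candidate = least significant bit), so evidence tables are reproducible and
column order never depends on fit results. Family evidence for "band $i$ is
present" averages $F$ over all (subject, model) pairs containing the band
and subtracts the average over those lacking it; the unweighted arithmetic
mean over subjects is the default group statistic (a fixed-effect sum is
available via `statistic = "sum"` — it scales with the number of subjects,
which is why the mean is the default report). Qualitative labels follow the
conventional bins (negative < 0 ≤ weak < 1 ≤ positive < 3 ≤ strong < 5 <
very strong), with left-closed edges — an arbitrary but fixed choice, since
the conventional table does not define edge membership.

## 4. Group level: parametric empirical Bayes

`peb_fit()` models subjects' unconstrained parameters as design-weighted
group effects plus Gaussian random effects,
$\theta_k^{(1)} = (x_k^\top \otimes I)\,\beta + \varepsilon$. Each subject
enters through their stored first-level posterior only, via the Gaussian
model-reduction identity (`bmr_reduce()`): swapping the subject's fitting
prior for the implied prior $N(X_k\beta, Q)$ has a closed-form effect on
the evidence. Noise log-precisions are excluded from the second level —
they are nuisance parameters, independent of the parameters of interest by
assumption.

Choices that were genuinely open, and how they were fixed:

* **Random-effects covariance** $Q$: diagonal, one log-precision per
  first-level parameter, $Q_{jj} = e^{-\gamma_j}\,\Sigma^0_{jj}/16$ with
  $\gamma_j \sim N(0,1)$. Anchoring to a fixed fraction of the first-level
  prior variance gives $\gamma = 0$ a meaningful scale ("between-subject
  spread is a sixteenth of the prior spread") and keeps the default
  behaviour stable across models of different dimension.
* **Optimisation**: given $\gamma$ the coefficient posterior is an exact
  conjugate Gaussian update (the per-subject reduction is quadratic in
  $\beta$), so only the low-dimensional $\gamma$ needs numerical
  optimisation (BFGS on the profile free energy, Laplace posterior from the
  numerical curvature). Woodbury-form sufficient statistics keep the
  updates valid even when a subject's posterior is no sharper than the
  prior along some direction.
* **Second-level priors**: zero-mean Gaussians with the first-level prior
  variances, reused for covariate columns; covariates are mean-centered by
  default so the intercept is the group average.

`credible_band()` propagates the full coefficient covariance through the
linear predictor and then through the parameter's monotone link, which
preserves quantiles; `interpolate_group_spectrum()` evaluates the model
spectrum at the link-mapped predicted parameters over the covariate range.

## 5. The simulators: what they emulate, and what a green test shows

**Group study** (`simulate_group()`): 32 subjects × rest/task on a 1–32 Hz
grid (0.5 Hz steps), an age-like covariate $x \sim U(0,1)$, parameter noise
with sd equal to 15% of each parameter's mean on the natural scale, white
observation noise. The generative constants are package defaults chosen
once — a dominant alpha peak ($h = 2.8 - 0.8x$ at $11 - 2x$ Hz, width
1.2 Hz), a small beta peak ($h = 0.25$ at 20 Hz, width 3 Hz), background
$\gamma = 1 - 0.3x$, $\alpha = -(1 + 0.3x)$, task attenuating both heights
to a quarter, observation-noise log-precision 9 — to emulate an
eyes-closed/eyes-open-like contrast in which alpha evidence is
overwhelming and beta evidence is clear but an order of magnitude weaker.
Parameter noise is drawn once per subject (the task attenuation is then
deterministic), so conditions are paired, as in a within-subject design.

**Detection benchmark** (`simulate_benchmark()`): 1–64 Hz at 0.5 Hz (127
bins), random aperiodic background (exponent $U[-2,-0.5]$, amplitude
log-uniform over one decade), a single peak with centre uniform in the
target band and width uniform in 5–25% of the bandwidth, height set by an
amplitude-dB rule $h = 10^{\mathrm{snr}/20}(A(m) + \mathrm{sd}_e)$, noise
variance $e^{-4}$ times the squared mean aperiodic level. Half the spectra
are matched no-peak negatives — detection specificity is undefined without
negatives, so they are part of the stated design even though a
positives-only reading of the benchmark is possible.

Neither simulator produces time-domain data; spectra are drawn directly
from the observation model. Consequently the Gaussian-noise assumption is
true by construction in simulation, and a green test establishes internal
consistency (the machinery inverts what it models, evidence ranks models
correctly, coverage is near-nominal) — not robustness to chi-distributed
estimator noise, line noise, artefacts, or filter mismatch in real
recordings. The benchmark's conservative regime is real, though: at very
low SNR the evidence criterion prefers the no-peak model (complexity beats
negligible accuracy), which is the intended behaviour, and it shows up as
sub-0.5 per-spectrum scores rather than random guessing.

## 6. Numerical details and degenerate inputs

* Covariances are symmetrised before Cholesky factorisation; KL terms are
  clamped at 0 against round-off.
* The $\lambda$ update caps Newton steps at ±4 nats per inner iteration;
  with tiny residuals the optimum is finite because the prior is proper.
* All-zero spectra cannot be rescaled (error); non-positive frequencies
  are rejected; negative amplitudes (possible after additive noise) are
  passed through unchanged — the likelihood is Gaussian.
* `bmr_reduce()` refuses reductions whose implied posterior precision is
  not positive definite (e.g. relaxing a prior far beyond what the
  posterior supports).
* Sigmoid saturation: beyond $|\theta_m| \approx 37$ the centre sits at a
  band edge in floating point; priors make such values effectively
  unreachable during fitting.
* Fits are deterministic given data and options; all simulator randomness
  flows from one seed.

## 7. Known limitations

* Single-channel spectra only: no source-space projection, no
  multi-channel shared-peak constraints.
* One noise component; no frequency-dependent noise precision (a
  correlation matrix $R_f$ can be supplied, but it is fixed, not
  estimated).
* No random-effects Bayesian model selection across subjects (exceedance
  probabilities) and no parameter-level model averaging.
* Variational overconfidence (Section 2) is unquantified; credible bands
  are best treated as approximate.
* The peak-height baseline in `detect_height()` is a deliberately simple
  comparator (log-log least squares plus in-band maximum), not a
  re-implementation of any published fitting pipeline.
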