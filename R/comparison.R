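#' Enumerate a model space over candidate peaks
#'
#' One model per subset of the candidate bands (including the peakless
#' model), in binary-counting order with the first candidate as the least
#' significant bit: for candidates (b1, b2) the order is
#' `{}, {b1}, {b2}, {b1, b2}`.
#'
#' @param candidates List of [band()] objects (pairwise disjoint).
#' @param domain,filters,condition_design Passed to every [model_spec()].
#' @return An object of class `bsd_model_space`: list with `candidate_bands`,
#'   `models` (list of `bsd_model`), `presence` (models x bands logical
#'   matrix) and `model_ids`.
#' @examples
#' enumerate_model_space(list(band("alpha", 8, 12), band("beta", 12, 30)))
#' @export
enumerate_model_space <- function(candidates, domain = "amplitude",
                                  filters = list(), condition_design = NULL) {
  if (inherits(candidates, "bsd_band")) candidates <- list(candidates)
  .validate_bands(candidates)
  n_b <- length(candidates)
  n_m <- 2L^n_b
  presence <- matrix(FALSE, n_m, max(n_b, 1L))
  models <- vector("list", n_m)
  ids <- character(n_m)
  for (i in seq_len(n_m)) {
    inc <- if (n_b > 0L) {
      as.logical(bitwAnd(i - 1L, 2L^(seq_len(n_b) - 1L)) > 0L)
    } else logical(0)
    if (n_b > 0L) presence[i, ] <- inc
    bands_i <- candidates[inc]
    des <- if (is.null(condition_design)) NULL else {
      condition_design(condition_design$n_conditions, 2L + 3L * length(bands_i))
    }
    models[[i]] <- model_spec(bands_i, domain = domain, filters = filters,
                              condition_design = des)
    ids[i] <- if (any(inc)) {
      paste(vapply(candidates[inc], `[[`, "", "name"), collapse = "+")
    } else "aperiodic"
  }
  if (n_b > 0L) {
    colnames(presence) <- vapply(candidates, `[[`, "", "name")
  } else {
    presence <- matrix(FALSE, 1L, 0L)
  }
  structure(
    list(candidate_bands = candidates, models = models,
         presence = presence, model_ids = ids),
    class = "bsd_model_space"
  )
}

#' @export
print.bsd_model_space <- function(x, ...) {
  cat(sprintf("<model space: %d candidate band(s), %d models>\n",
              length(x$candidate_bands), length(x$models)))
  invisible(x)
}

#' Log Bayes factor from two free energies
#'
#' The log Bayes factor between two models is approximated by the difference
#' of their free energies: `ln B12 ~= F1 - F2`.
#'
#' @param F1,F2 Free energies (log evidences) of the two models.
#' @return `F1 - F2`.
#' @export
log_bayes_factor <- function(F1, F2) {
  if (!all(is.finite(c(F1, F2)))) .stopf("free energies must be finite")
  F1 - F2
}

#' Invert a model space over a set of spectra
#'
#' Fits every model in the space to every spectrum and collects the free
#' energies into an evidence table.
#'
#' @param spectra `n_freq x n_subjects` matrix (columns are subjects /
#'   spectra) or a vector for a single subject.
#' @param freqs Frequencies in Hz.
#' @param space A [enumerate_model_space()] result.
#' @param priors Optional list of [prior_spec()] per model (defaults per
#'   model via [default_priors()]).
#' @param ... Passed to [fit_spectrum()] (e.g. `scale`, `opts`).
#' @return An object of class `bsd_evidence`: list with `F`
#'   (subjects x models matrix), `subject_ids`, `model_ids`, `space`, and
#'   `posteriors` (list of lists, subjects x models).
#' @export
fit_model_space <- function(spectra, freqs, space, priors = NULL, ...) {
  spectra <- as.matrix(spectra)
  n_sub <- ncol(spectra)
  n_mod <- length(space$models)
  Fm <- matrix(NA_real_, n_sub, n_mod)
  posts <- vector("list", n_sub)
  sub_ids <- colnames(spectra)
  if (is.null(sub_ids)) sub_ids <- sprintf("s%02d", seq_len(n_sub))
  for (k in seq_len(n_sub)) {
    posts[[k]] <- vector("list", n_mod)
    for (j in seq_len(n_mod)) {
      pr <- if (is.null(priors)) NULL else priors[[j]]
      post <- fit_spectrum(spectra[, k], freqs, space$models[[j]],
                           priors = pr, ...)
      Fm[k, j] <- post$free_energy
      posts[[k]][[j]] <- post
    }
  }
  dimnames(Fm) <- list(sub_ids, space$model_ids)
  structure(
    list(F = Fm, subject_ids = sub_ids, model_ids = space$model_ids,
         space = space, posteriors = posts),
    class = "bsd_evidence"
  )
}

#' @export
print.bsd_evidence <- function(x, ...) {
  cat(sprintf("<evidence table: %d subject(s) x %d model(s)>\n",
              nrow(x$F), ncol(x$F)))
  invisible(x)
}

#' Family-wise evidence for the presence of each candidate peak
#'
#' For each candidate band, averages the free energy over all (subject,
#' model) pairs whose model contains the band and over those whose model does
#' not; the difference of the two averages is the family log Bayes factor for
#' the presence of that peak.
#'
#' @param evidence A `bsd_evidence` from [fit_model_space()], or a plain
#'   subjects x models matrix of free energies (then `space` is required).
#' @param space A `bsd_model_space` (taken from `evidence` when omitted).
#' @param statistic `"mean"` (default) averages over subjects; `"sum"` pools
#'   them (fixed-effect reading).
#' @return Data frame with one row per candidate band: `band`, `F_with`,
#'   `F_without`, `ln_bf`, `evidence` (qualitative label).
#' @export
family_evidence <- function(evidence, space = NULL,
                            statistic = c("mean", "sum")) {
  statistic <- match.arg(statistic)
  if (inherits(evidence, "bsd_evidence")) {
    if (is.null(space)) space <- evidence$space
    Fm <- evidence$F
  } else {
    Fm <- as.matrix(evidence)
  }
  if (is.null(space)) .stopf("a model space is required")
  if (ncol(Fm) != length(space$models)) {
    .stopf("evidence table has %d columns, model space has %d models",
           ncol(Fm), length(space$models))
  }
  n_b <- length(space$candidate_bands)
  if (n_b == 0L) .stopf("family evidence needs at least one candidate band")
  agg <- if (statistic == "mean") mean else sum
  out <- data.frame(
    band = vapply(space$candidate_bands, `[[`, "", "name"),
    F_with = NA_real_, F_without = NA_real_, ln_bf = NA_real_,
    stringsAsFactors = FALSE
  )
  for (b in seq_len(n_b)) {
    with_b <- space$presence[, b]
    # average per subject over models, then aggregate over subjects
    Fw <- agg(rowMeans(Fm[, with_b, drop = FALSE]))
    Fo <- agg(rowMeans(Fm[, !with_b, drop = FALSE]))
    out$F_with[b] <- Fw
    out$F_without[b] <- Fo
    out$ln_bf[b] <- Fw - Fo
  }
  out$evidence <- vapply(out$ln_bf, interpret_bf, "")
  out
}

#' Qualitative interpretation of a log Bayes factor
#'
#' Conventional bins: negative (< 0), weak (0 to 1), positive (1 to 3),
#' strong (3 to 5; a Bayes factor of about 20 to 150) and very strong (> 5).
#' Bins are closed on the left, so `ln_bf = 3` reads "strong".
#'
#' @param ln_bf Log Bayes factor (finite scalar).
#' @return One of `"negative"`, `"weak"`, `"positive"`, `"strong"`,
#'   `"very strong"`.
#' @examples
#' interpret_bf(4) # "strong" (Bayes factor ~ 55)
#' @export
interpret_bf <- function(ln_bf) {
  if (!.is_number(ln_bf)) .stopf("ln_bf must be a finite number")
  if (ln_bf < 0) "negative"
  else if (ln_bf < 1) "weak"
  else if (ln_bf < 3) "positive"
  else if (ln_bf < 5) "strong"
  else "very strong"
}
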