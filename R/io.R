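#' Read a spectra table from delimited text
#'
#' Expects a header row whose first column is `frequency_hz`, followed by one
#' column per series (subject / condition / channel). TSV and CSV dialects
#' are detected from the extension (".csv" = comma, otherwise tab).
#'
#' @param path File path.
#' @param sep Field separator; `NULL` (default) picks by extension.
#' @return List of class `bsd_spectra`: `freqs`, `spectra` (matrix with named
#'   columns), `series`.
#' @export
read_spectra <- function(path, sep = NULL) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) .stopf("spectra table needs a frequency column plus >= 1 series")
  if (names(tab)[1] != "frequency_hz") {
    .stopf("first column must be named 'frequency_hz' (got '%s')", names(tab)[1])
  }
  f <- as.numeric(tab[[1]])
  bad <- which(diff(f) <= 0)
  if (length(bad)) {
    .stopf("frequency column not strictly increasing at row %d", bad[1] + 1L)
  }
  f <- .validate_grid(f)
  M <- as.matrix(tab[, -1, drop = FALSE])
  if (anyDuplicated(colnames(M))) .stopf("series names must be unique")
  if (any(!is.finite(M))) .stopf("spectra contain non-finite values")
  structure(list(freqs = f, spectra = M, series = colnames(M)),
            class = "bsd_spectra")
}

#' Write a spectra table to delimited text
#'
#' @param freqs Frequencies in Hz.
#' @param spectra Matrix with one column per series (or vector).
#' @param path Output path; ".csv" writes comma-separated, otherwise tab.
#' @param names Optional series names.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(freqs, spectra, path, names = NULL) {
  spectra <- as.matrix(spectra)
  if (nrow(spectra) != length(freqs)) .stopf("rows must match frequencies")
  if (!is.null(names)) colnames(spectra) <- names
  if (is.null(colnames(spectra))) {
    colnames(spectra) <- sprintf("series%02d", seq_len(ncol(spectra)))
  }
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- data.frame(frequency_hz = freqs, spectra, check.names = FALSE)
  utils::write.table(tab, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a group design table
#'
#' Delimited text with a header: a subject-id column (first) and one column
#' per regressor. An intercept column is prepended if absent.
#'
#' @param path File path (TSV, or CSV by extension).
#' @param center Mean-center regressors (see [group_design()]).
#' @return A [group_design()]; subject ids kept as attribute `subjects`.
#' @export
read_group_design <- function(path, center = TRUE) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  ids <- tab[[1]]
  X <- as.matrix(tab[, -1, drop = FALSE])
  if (!length(X)) .stopf("design table has no regressor columns")
  if (!all(X[, 1] == 1)) X <- cbind(intercept = 1, X)
  d <- group_design(X, center = center)
  attr(d, "subjects") <- ids
  d
}

#' Serialise a posterior to JSON
#'
#' @param post A `bsd_posterior`.
#' @param path Optional output path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to file).
#' @export
posterior_to_json <- function(post, path = NULL) {
  obj <- list(
    mean = as.numeric(post$mean), cov = unname(as.matrix(post$cov)),
    param_names = post$param_names,
    lambda_mean = post$lambda_mean, lambda_var = post$lambda_var,
    free_energy = post$free_energy, accuracy = post$accuracy,
    complexity_theta = post$complexity_theta,
    complexity_lambda = post$complexity_lambda,
    n_iter = post$n_iter, converged = post$converged,
    scale_factor = post$scale_factor
  )
  js <- jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE, null = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Serialise a model specification to JSON
#'
#' @param spec A [model_spec()].
#' @param path Optional output path.
#' @return JSON string (invisibly when written to file).
#' @export
model_spec_to_json <- function(spec, path = NULL) {
  obj <- list(
    domain = spec$domain,
    bands = lapply(spec$bands, function(b) {
      list(name = b$name, lower = b$lower, upper = b$upper)
    }),
    filters = lapply(spec$filters, unclass),
    n_conditions = if (is.null(spec$condition_design)) 1L else
      spec$condition_design$n_conditions
  )
  js <- jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Read a model specification from JSON
#'
#' @param path Path to a JSON file produced by [model_spec_to_json()] (or
#'   hand-written with fields `domain`, `bands`, optional `n_conditions`).
#' @return A [model_spec()].
#' @export
model_spec_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  bands <- lapply(obj$bands, function(b) band(b$name, b$lower, b$upper))
  des <- NULL
  if (!is.null(obj$n_conditions) && obj$n_conditions > 1L) {
    des <- condition_design(obj$n_conditions, 2L + 3L * length(bands))
  }
  model_spec(bands, domain = obj$domain %||% "amplitude",
             condition_design = des)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
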