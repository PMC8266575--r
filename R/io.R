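# Delimited-text I/O for pull-cycle tables and fit reports.

#' Write pull cycles to TSV
#'
#' @param cycles `data.frame` from [simulate_cycles()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_events <- function(cycles, path) {
  utils::write.table(cycles, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read pull cycles from TSV
#'
#' Accepts files written by [write_events()] or user-supplied tables with at
#' least a `force` column (pN); `ruptured`/`censored` flags are
#' reconstructed when absent.
#'
#' @param path Input file.
#' @return `data.frame` of pull cycles.
#' @export
read_events <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"force" %in% names(tab)) {
    stop("events table must have a 'force' column (pN): ", path)
  }
  if (!"ruptured" %in% names(tab)) tab$ruptured <- is.finite(tab$force)
  if (!"censored" %in% names(tab)) tab$censored <- FALSE
  tab
}

#' Write a mixture fit report as JSON
#'
#' @param fit A `bell_mixture_fit`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "bell_mixture_fit"))
  jsonlite::write_json(
    list(
      K = fit$K,
      states = fit$states,
      w_censored_excess = fit$w_censored_excess,
      log_likelihood = fit$log_likelihood,
      BIC = fit$BIC,
      n_events = fit$n_events,
      n_censored = fit$n_censored
    ),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}
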