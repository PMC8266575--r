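# Step detection in extension-versus-time ramp traces and per-population
# step-size summaries in nm and released nucleotides.

#' Detect the rupture step in a ramp trace
#'
#' Sliding two-window change-point statistic: at each candidate point a
#' straight line is fitted to the `window` samples on either side and the
#' step is the jump between the two lines evaluated at the boundary. A local
#' linear (rather than constant) baseline keeps the estimate unbiased while
#' the handle extension rises along the force ramp. The single maximal step
#' is returned; if its signal-to-noise ratio is below `min_snr` the trace is
#' declared step-free. The noise scale is estimated robustly from first
#' differences.
#'
#' @param trace `data.frame` with columns `time_s`, `force_pN`,
#'   `extension_nm` (as from [simulate_trace()]).
#' @param window Samples per side window, `>= 5`. Default 25.
#' @param min_snr Detection threshold on the step SNR. Default 5.
#' @return `NULL` if no step passes the threshold, else a list with `time`
#'   (s), `force` (pN), `delta_x` (nm), `snr`, `index`. Warns if a second,
#'   well-separated step also passes the threshold.
#' @export
detect_step <- function(trace, window = 25, min_snr = 5) {
  stopifnot(all(c("time_s", "force_pN", "extension_nm") %in% names(trace)))
  if (window < 5) stop("window must be at least 5 samples")
  x <- trace$extension_nm
  n <- length(x)
  if (n < 2 * window) stop("trace shorter than two windows")

  w <- window
  i <- seq_len(n)
  Sx <- c(0, cumsum(x))
  Six <- c(0, cumsum(i * x))
  wsum <- function(S, a, b) S[b + 1] - S[a]

  # closed-form linear fit over index window [a, b]: slope, intercept
  linfit <- function(a, b) {
    sum_x <- wsum(Sx, a, b)
    sum_ix <- wsum(Six, a, b)
    sum_i <- (a + b) * w / 2
    sum_i2 <- (b * (b + 1) * (2 * b + 1) - (a - 1) * a * (2 * a - 1)) / 6
    slope <- (w * sum_ix - sum_i * sum_x) / (w * sum_i2 - sum_i^2)
    intercept <- (sum_x - slope * sum_i) / w
    list(slope = slope, intercept = intercept)
  }

  cand <- (w + 1):(n - w + 1)  # step between samples c-1 and c
  a_l <- cand - w; b_l <- cand - 1
  a_r <- cand; b_r <- cand + w - 1
  fl <- linfit(a_l, b_l)
  fr <- linfit(a_r, b_r)
  at <- cand - 0.5
  jump <- (fr$intercept + fr$slope * at) - (fl$intercept + fl$slope * at)

  sigma <- stats::mad(diff(x)) / sqrt(2)
  # variance of the boundary-extrapolated linear fits ~ 4 sigma^2 / w per side
  se <- if (sigma > 0) sigma * sqrt(8 / w) else 0
  snr <- if (se > 0) abs(jump) / se else ifelse(abs(jump) > 0, Inf, 0)

  best <- which.max(abs(jump))
  if (snr[best] < min_snr) return(NULL)

  # check for a second well-separated candidate above threshold
  far <- abs(cand - cand[best]) > 2 * w
  if (any(far & snr >= min_snr &
          abs(jump) > 0.5 * abs(jump[best]))) {
    warning("multiple step candidates detected; returning the largest")
  }

  idx <- cand[best]
  list(
    time = (trace$time_s[idx - 1] + trace$time_s[idx]) / 2,
    force = (trace$force_pN[idx - 1] + trace$force_pN[idx]) / 2,
    delta_x = jump[best],
    snr = snr[best],
    index = idx
  )
}

#' Summarise unfolding step sizes per population
#'
#' Converts each event's extension jump to released nucleotides at its own
#' rupture force via [nt_from_step()], then averages within groups. Groups
#' can be given explicitly as labels, derived from a [fit_bell_mixture()]
#' result by maximum-posterior component assignment, or defined by fixed
#' force bins.
#'
#' @param events `data.frame` with columns `force` (pN) and `delta_x` (nm).
#' @param polymer A [polymer_params()].
#' @param assignment One of: a vector of group labels (length `nrow(events)`),
#'   a `bell_mixture_fit` (posterior assignment), or a numeric vector of
#'   force-bin breaks.
#' @return `data.frame` with one row per non-empty group: `group`, `n`,
#'   `mean_dx`, `sd_dx`, `mean_nt`, `sd_nt`, `mean_force`. Empty groups are
#'   dropped with a warning.
#' @export
summarize_steps <- function(events, polymer, assignment) {
  stopifnot(all(c("force", "delta_x") %in% names(events)))
  keep <- is.finite(events$force) & is.finite(events$delta_x)
  events <- events[keep, , drop = FALSE]
  if (nrow(events) == 0) stop("no usable events")

  if (inherits(assignment, "bell_mixture_fit")) {
    groups <- .posterior_assignment(events$force, assignment)
  } else if (is.numeric(assignment)) {
    groups <- cut(events$force, breaks = assignment, include.lowest = TRUE)
  } else {
    if (length(assignment) != nrow(events)) {
      stop("assignment labels must match the number of events")
    }
    groups <- if (is.factor(assignment)) assignment else factor(assignment)
  }

  nt <- nt_from_step(events$delta_x, events$force, polymer)
  lv <- levels(groups)
  present <- lv %in% unique(as.character(groups[!is.na(groups)]))
  if (any(!present)) {
    warning("empty groups excluded: ", paste(lv[!present], collapse = ", "))
  }
  out <- do.call(rbind, lapply(lv[present], function(g) {
    idx <- which(as.character(groups) == g)
    data.frame(
      group = g, n = length(idx),
      mean_dx = mean(events$delta_x[idx]),
      sd_dx = stats::sd(events$delta_x[idx]),
      mean_nt = mean(nt[idx]),
      sd_nt = stats::sd(nt[idx]),
      mean_force = mean(events$force[idx]),
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}

# maximum-posterior component labels for each force under a mixture fit
.posterior_assignment <- function(forces, fit) {
  K <- fit$K
  dens <- vapply(seq_len(K), function(i) {
    st <- bell_state(fit$states$k_unfold[i], fit$states$dx[i])
    fit$states$weight[i] * ramp_pdf(forces, st, fit$protocol)
  }, numeric(length(forces)))
  dens <- matrix(dens, ncol = K)
  factor(fit$states$label[max.col(dens)], levels = fit$states$label)
}
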