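# First-order refolding kinetics: binomial fit of the time-evolution folding
# probability p_fold(t) = p_st [1 - exp(-k_fold t)] measured by holding the
# tether at low force for time t and scoring the next ramp for an unfolding
# event.

#' Fit the time-evolution folding probability
#'
#' Binomial maximum-likelihood fit of
#' `p_fold(t) = p_st (1 - exp(-k_fold t))` to folded/unfolded counts at a
#' set of hold times. Parameters are optimised on the scale
#' `(logit p_st, log k_fold)`; standard errors come from the observed
#' information via the delta method. With a `tether_id` column and
#' `by = "tether"` the fit is performed per tether and the mean and SD
#' across tethers are reported.
#'
#' @param table `data.frame` with columns `t` (hold time, s), `n_folded`,
#'   `n_total` (and optionally `tether_id`).
#' @param by `"pooled"` (default) fits all counts jointly; `"tether"` fits
#'   each tether separately.
#' @return Object of class `pfold_fit`: `p_st`, `k_fold`, `se_p_st`,
#'   `se_k_fold`, `deviance`, `n_points`, `convergence`; in tether mode the
#'   per-tether fits are attached as `tether_fits` and `p_st`/`k_fold` are
#'   across-tether means with SDs as the `se_*` fields.
#' @export
fit_pfold <- function(table, by = c("pooled", "tether")) {
  by <- match.arg(by)
  stopifnot(all(c("t", "n_folded", "n_total") %in% names(table)))
  if (by == "tether") {
    if (!"tether_id" %in% names(table)) stop("tether mode needs tether_id")
    fits <- lapply(split(table, table$tether_id), fit_pfold, by = "pooled")
    ps <- vapply(fits, `[[`, numeric(1), "p_st")
    ks <- vapply(fits, `[[`, numeric(1), "k_fold")
    out <- structure(list(
      p_st = mean(ps), k_fold = mean(ks),
      se_p_st = stats::sd(ps), se_k_fold = stats::sd(ks),
      deviance = sum(vapply(fits, `[[`, numeric(1), "deviance")),
      n_points = nrow(table), convergence = 0L,
      tether_fits = fits
    ), class = "pfold_fit")
    return(out)
  }

  tab <- table[table$n_total > 0, , drop = FALSE]
  if (length(unique(tab$t)) < 3) {
    stop("need at least 3 distinct hold times to identify (p_st, k_fold)")
  }
  if (any(tab$t <= 0)) stop("hold times must be positive")
  if (all(tab$n_folded == 0)) {
    stop("all counts zero: folding parameters are not identifiable")
  }
  if (all(tab$n_folded == tab$n_total)) {
    stop("all counts saturated: k_fold is not identifiable")
  }

  nll <- function(theta) {
    p_st <- stats::plogis(theta[1])
    k <- exp(theta[2])
    p <- p_st * (1 - exp(-k * tab$t))
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(stats::dbinom(tab$n_folded, tab$n_total, p, log = TRUE))
  }

  prop <- tab$n_folded / tab$n_total
  p0 <- min(max(max(prop), 0.05), 0.99)
  # crude rate start from the earliest informative time point
  i1 <- which.min(tab$t)
  frac1 <- min(prop[i1] / p0, 0.95)
  k0 <- if (frac1 > 0) -log(1 - frac1) / tab$t[i1] else 0.1
  k0 <- min(max(k0, 1e-4), 10)

  fit <- stats::optim(c(stats::qlogis(p0), log(k0)), nll, method = "BFGS",
                      hessian = TRUE, control = list(maxit = 500))
  p_st <- stats::plogis(fit$par[1])
  k_fold <- exp(fit$par[2])

  se <- c(NA_real_, NA_real_)
  vc <- tryCatch(solve(fit$hessian), error = function(e) NULL)
  if (!is.null(vc) && all(diag(vc) > 0)) {
    se_theta <- sqrt(diag(vc))
    se <- c(se_theta[1] * p_st * (1 - p_st), se_theta[2] * k_fold)
  }

  p_hat <- pmin(pmax(p_st * (1 - exp(-k_fold * tab$t)), 1e-12), 1 - 1e-12)
  p_sat <- pmin(pmax(prop, 1e-12), 1 - 1e-12)
  dev <- 2 * (sum(stats::dbinom(tab$n_folded, tab$n_total, p_sat, log = TRUE)) -
                sum(stats::dbinom(tab$n_folded, tab$n_total, p_hat, log = TRUE)))

  structure(list(
    p_st = p_st, k_fold = k_fold,
    se_p_st = se[1], se_k_fold = se[2],
    deviance = dev, n_points = nrow(tab),
    convergence = fit$convergence
  ), class = "pfold_fit")
}

#' @export
print.pfold_fit <- function(x, ...) {
  cat(sprintf("p_st = %.3f (se %.3f), k_fold = %.4f 1/s (se %.4f), deviance %.2f on %d points\n",
              x$p_st, x$se_p_st, x$k_fold, x$se_k_fold, x$deviance,
              x$n_points))
  invisible(x)
}

#' Apportion the steady-state folding probability by mechanical stability
#'
#' Splits the folded fraction of a set of pull cycles (measured at a fixed,
#' typically saturating, hold time) into a mechanically stable part (rupture
#' force above the threshold, or survived the ramp) and a less stable part.
#' `p_st_full + p_st_partial` equals the overall folded fraction.
#'
#' @param cycles `data.frame` from [simulate_cycles()] (or equivalent, with
#'   `ruptured`, `censored`, `force` columns).
#' @param threshold Force threshold, pN. Default 40.
#' @return List with `p_st_full`, `p_st_partial`, `p_st_total`, `n_cycles`.
#' @export
split_pst_by_stability <- function(cycles, threshold = 40) {
  stopifnot(all(c("ruptured", "censored", "force") %in% names(cycles)))
  n <- nrow(cycles)
  if (n == 0) stop("no cycles")
  folded <- cycles$ruptured | cycles$censored
  # censored cycles survived past f_end > threshold: mechanically stable
  full <- (cycles$ruptured & !is.na(cycles$force) &
             cycles$force > threshold) | cycles$censored
  list(
    p_st_full = sum(full) / n,
    p_st_partial = sum(folded & !full) / n,
    p_st_total = sum(folded) / n,
    n_cycles = n
  )
}
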