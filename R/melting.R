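# Sigmoid fits of thermal melting profiles: extracts the melting temperature
# Tm as the inflection point of y(T) = y_f + (y_u - y_f)/(1 + exp(-(T-tm)/w)).

#' Fit a sigmoid melting curve
#'
#' Nonlinear least squares (Levenberg-Marquardt) of a four-parameter
#' logistic to a thermal denaturation profile, multi-started over a grid of
#' candidate melting temperatures. The fit is invariant to affine rescaling
#' of the signal, so raw ellipticity, absorbance, or normalised
#' fraction-unfolded all give the same `tm`.
#'
#' @param curve `data.frame` whose first two columns are temperature (C) and
#'   signal (columns named `temp_C`/`signal` are used when present). At
#'   least 8 points spanning the transition.
#' @return Object of class `melting_fit`: `tm` (C), `width` (C), `y_f`,
#'   `y_u`, `rss`, `n_points`, `flag` (`"ok"`, or `"extrapolated"` when `tm`
#'   falls outside the data range).
#' @export
fit_melting <- function(curve) {
  if (all(c("temp_C", "signal") %in% names(curve))) {
    tt <- curve$temp_C; y <- curve$signal
  } else {
    tt <- curve[[1]]; y <- curve[[2]]
  }
  ok <- is.finite(tt) & is.finite(y)
  tt <- tt[ok]; y <- y[ok]
  if (length(tt) < 8) stop("need at least 8 points to fit a melting curve")
  ord <- order(tt)
  tt <- tt[ord]; y <- y[ord]

  amp <- diff(range(y))
  resid_scale <- stats::mad(diff(y)) / sqrt(2)
  if (amp < 4 * max(resid_scale, .Machine$double.eps)) {
    stop("no transition detected (flat curve): tm is not identifiable")
  }

  # orient baselines from the overall trend
  increasing <- stats::cor(tt, y) >= 0
  yf0 <- if (increasing) min(y) else max(y)
  yu0 <- if (increasing) max(y) else min(y)
  width0 <- diff(range(tt)) / 15

  # candidate tm values: midpoint crossing plus a coarse grid
  mid <- (yf0 + yu0) / 2
  tm_cross <- tt[which.min(abs(y - mid))]
  tm_grid <- unique(c(tm_cross,
                      stats::quantile(tt, c(0.2, 0.35, 0.5, 0.65, 0.8),
                                      names = FALSE)))

  dat <- data.frame(tt = tt, y = y)
  best <- NULL
  for (tm0 in tm_grid) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ yf + (yu - yf) / (1 + exp(-(tt - tm) / width)),
        data = dat,
        start = list(yf = yf0, yu = yu0, tm = tm0, width = width0),
        lower = c(-Inf, -Inf, -Inf, 1e-3),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-12) {
      best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) stop("sigmoid fit failed from all starts")

  cf <- stats::coef(best$fit)
  flag <- if (cf[["tm"]] < min(tt) || cf[["tm"]] > max(tt)) {
    "extrapolated"
  } else "ok"
  structure(list(
    tm = cf[["tm"]], width = cf[["width"]],
    y_f = cf[["yf"]], y_u = cf[["yu"]],
    rss = best$rss, n_points = length(tt), flag = flag
  ), class = "melting_fit")
}

#' @export
print.melting_fit <- function(x, ...) {
  cat(sprintf("Tm = %.2f C (width %.2f C), baselines %.3g -> %.3g, rss %.3g on %d points [%s]\n",
              x$tm, x$width, x$y_f, x$y_u, x$rss, x$n_points, x$flag))
  invisible(x)
}
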