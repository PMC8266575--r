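# Censored maximum-likelihood fitting of multi-state Bell mixtures to
# rupture-force samples. The mixture has K folded Bell components plus an
# explicit never-folded class w0: an observed rupture at F contributes
# log(sum_i w_i p_i(F)); a no-rupture cycle contributes
# log(w0 + sum_i w_i S_i(f_end)), i.e. it is explained either by the
# molecule never having folded or by a folded state surviving the ramp.
# Fitted component weights are therefore fractions of *cycles*, directly
# comparable to per-peak percentages that sum to less than 100%.

# parameter vector layout: theta = c(lk0[1..K], dx[1..K], alpha[1..K])
# weights = softmax over c(alpha, 0): w_i = e^{a_i}/(1 + sum e^a), w0 = 1/(...)

.mix_unpack <- function(theta, K) {
  lk0 <- theta[seq_len(K)]
  dx <- theta[K + seq_len(K)]
  alpha <- theta[2 * K + seq_len(K)]
  ea <- exp(alpha - max(alpha, 0))
  denom <- sum(ea) + exp(-max(alpha, 0))
  list(lk0 = lk0, dx = dx, w = ea / denom,
       w0 = exp(-max(alpha, 0)) / denom)
}

# log survival at f_end per component
.mix_logS_end <- function(lk0, dx, protocol) {
  b <- dx / protocol$kBT
  a <- protocol$kBT * exp(lk0) / (protocol$loading_rate * dx)
  -a * (exp(b * protocol$f_end) - exp(b * protocol$f_start))
}

# shared pieces of the likelihood and its gradient
.mix_parts <- function(theta, forces, protocol, K) {
  par <- .mix_unpack(theta, K)
  n <- length(forces)
  b <- par$dx / protocol$kBT
  a <- protocol$kBT * exp(par$lk0) / (protocol$loading_rate * par$dx)
  ebF0 <- exp(b * protocol$f_start)
  # n x K matrices: exp(b_i F_j) and log(w_i p_i(F_j))
  ebF <- exp(outer(forces, b))
  haz_int <- sweep(sweep(ebF, 2, ebF0, "-"), 2, a, "*") # integrated hazard
  ll <- sweep(outer(forces, b), 2, log(par$w) + par$lk0, "+") -
    log(protocol$loading_rate) - haz_int
  m <- ll[, 1]
  if (K > 1) for (k in 2:K) m <- pmax(m, ll[, k])
  lse <- m + log(rowSums(exp(ll - m)))
  list(par = par, b = b, a = a, ebF0 = ebF0, ebF = ebF, ll = ll, lse = lse)
}

.mix_negloglik <- function(theta, forces, n_norupt, protocol, K) {
  pt <- .mix_parts(theta, forces, protocol, K)
  obs <- sum(pt$lse)
  cens <- 0
  if (n_norupt > 0) {
    pnr <- pt$par$w0 +
      sum(pt$par$w * exp(.mix_logS_end(pt$par$lk0, pt$par$dx, protocol)))
    cens <- n_norupt * log(pnr)
  }
  nll <- -(obs + cens)
  if (!is.finite(nll)) nll <- 1e10
  nll
}

.mix_grad <- function(theta, forces, n_norupt, protocol, K) {
  pt <- .mix_parts(theta, forces, protocol, K)
  par <- pt$par; b <- pt$b; a <- pt$a
  kBT <- protocol$kBT
  F0 <- protocol$f_start; Fe <- protocol$f_end
  resp <- exp(pt$ll - pt$lse)               # n x K responsibilities
  ebFe <- exp(b * Fe)

  # d log p_i / d lk0_i and d log p_i / d dx_i, per observation
  dint <- sweep(pt$ebF, 2, pt$ebF0, "-")    # e^{bF} - e^{bF0}
  dg_lk0 <- 1 - sweep(dint, 2, a, "*")
  t1 <- outer(forces, rep(1 / kBT, K))
  t2 <- sweep(dint, 2, a / par$dx, "*")
  t3 <- sweep(pt$ebF, 1, forces, "*")          # F_j e^{b_i F_j}
  t3 <- sweep(t3, 2, F0 * pt$ebF0, "-")        # ... - F0 e^{b_i F0}
  dg_dx <- t1 + t2 - sweep(t3, 2, a / kBT, "*")

  g_lk0 <- colSums(resp * dg_lk0)
  g_dx <- colSums(resp * dg_dx)
  g_alpha <- colSums(resp) - length(forces) * par$w

  if (n_norupt > 0) {
    hS <- .mix_logS_end(par$lk0, par$dx, protocol)  # log S_i(Fe), equals h_i
    S <- exp(hS)
    P <- par$w0 + sum(par$w * S)
    dh_lk0 <- hS                                    # h = -a(...), dh/dlk0 = h
    dh_dx <- (a / par$dx) * (ebFe - pt$ebF0) -
      (a / kBT) * (Fe * ebFe - F0 * pt$ebF0)
    g_lk0 <- g_lk0 + n_norupt * par$w * S * dh_lk0 / P
    g_dx <- g_dx + n_norupt * par$w * S * dh_dx / P
    g_alpha <- g_alpha + n_norupt * (par$w * S / P - par$w)
  }
  g <- -c(g_lk0, g_dx, g_alpha)
  g[!is.finite(g)] <- 0
  g
}

# moment-based initial values from a k-means split of the forces
.mix_init <- function(forces, n_norupt, protocol, K, seed) {
  set.seed(seed)
  if (K == 1) {
    cl <- list(cluster = rep(1L, length(forces)),
               centers = matrix(mean(forces)))
  } else {
    cl <- stats::kmeans(forces, centers = K, nstart = 5)
  }
  ord <- order(cl$centers[, 1])
  lk0 <- dx <- alpha <- numeric(K)
  n_tot <- length(forces) + n_norupt
  for (k in seq_len(K)) {
    idx <- which(cl$cluster == ord[k])
    fc <- mean(forces[idx])
    s <- stats::sd(forces[idx])
    # Gumbel-like shape: sd ~ (pi/sqrt(6)) kBT/dx
    dx[k] <- if (is.finite(s) && s > 0) {
      min(max(1.2825 * protocol$kBT / s, 0.25), 4.5)
    } else 1.0
    lk0[k] <- log(k_unfold_from_modal_force(fc, dx[k], protocol))
    w_k <- length(idx) / n_tot
    alpha[k] <- log(max(w_k, 1e-3)) - log(max(n_norupt / n_tot, 1e-3))
  }
  c(lk0, dx, alpha)
}

#' Fit a K-component Bell mixture to rupture forces
#'
#' Maximum-likelihood fit of a mixture of K Bell ramp rupture-force
#' distributions to observed unfolding forces, with no-rupture cycles
#' entering the likelihood through a never-folded class plus per-component
#' ramp survival at the force ceiling. Optimisation is multi-start L-BFGS-B
#' on `(log k_unfold, dx, weight logits)` with box constraints
#' `dx` in `dx_box`; starts come from a k-means split of the forces with
#' seeded jitter.
#'
#' @param forces Observed rupture forces, pN.
#' @param n_censored Number of cycles with no rupture below the force
#'   ceiling (never-folded molecules and folded states that survived the
#'   ramp are experimentally indistinguishable).
#' @param protocol A [ramp_protocol()].
#' @param K Number of folded components, `>= 1`.
#' @param n_starts Number of optimisation restarts. Default 10.
#' @param seed Integer seed (initialisation jitter).
#' @param dx_box Box constraint for the transition distance, nm.
#' @param init Optional warm-start parameter vector (as returned in
#'   `fit$theta`); used as one additional start.
#' @return Object of class `bell_mixture_fit`: `states` data.frame (one row
#'   per component, ordered by modal force: `label`, `k_unfold`, `dx`,
#'   `weight` of all cycles, `weight_events` renormalised over detected
#'   events, `modal_force`), `w_censored_excess` (never-folded mass),
#'   `log_likelihood`, `n_events`, `n_censored`, `BIC`, `convergence`,
#'   `theta`, `protocol`.
#' @export
fit_bell_mixture <- function(forces, n_censored = 0, protocol, K,
                             n_starts = 10, seed = 1, dx_box = c(0.2, 5),
                             init = NULL) {
  forces <- forces[is.finite(forces)]
  if (length(forces) == 0) {
    stop("no observed rupture events: mixture MLE is not defined")
  }
  if (length(forces) < 5 * K) {
    stop("need at least 5 events per component (", length(forces),
         " events for K = ", K, ")")
  }
  stopifnot(K >= 1, n_censored >= 0)
  if (any(forces < protocol$f_start) || any(forces > protocol$f_end)) {
    stop("forces must lie within [f_start, f_end]")
  }

  lower <- c(rep(-35, K), rep(dx_box[1], K), rep(-12, K))
  upper <- c(rep(5, K), rep(dx_box[2], K), rep(12, K))
  base_init <- .mix_init(forces, n_censored, protocol, K, seed)
  base_init <- pmin(pmax(base_init, lower + 1e-6), upper - 1e-6)

  set.seed(seed + 1)
  starts <- list(base_init)
  if (!is.null(init)) starts <- c(starts, list(pmin(pmax(init, lower + 1e-6),
                                                    upper - 1e-6)))
  while (length(starts) < n_starts) {
    jit <- base_init + c(stats::rnorm(K, 0, 1),
                         stats::rnorm(K, 0, 0.25),
                         stats::rnorm(K, 0, 0.5))
    starts <- c(starts, list(pmin(pmax(jit, lower + 1e-6), upper - 1e-6)))
  }

  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(s, .mix_negloglik, gr = .mix_grad, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   forces = forces, n_norupt = n_censored,
                   protocol = protocol, K = K,
                   control = list(maxit = 500)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("mixture optimisation failed for all starts")

  par <- .mix_unpack(best$par, K)
  states <- lapply(seq_len(K), function(i) {
    bell_state(exp(par$lk0[i]), par$dx[i], label = paste0("component", i))
  })
  fstar <- vapply(states, function(s) as.numeric(modal_force(s, protocol)),
                  numeric(1))
  ord <- order(fstar)
  p_detect <- 1 - exp(.mix_logS_end(par$lk0, par$dx, protocol))
  w_ev <- par$w * p_detect
  w_ev <- w_ev / sum(w_ev)

  n_tot <- length(forces) + n_censored
  npar <- 3 * K
  ll <- -best$value
  res <- structure(list(
    states = data.frame(
      label = paste0("component", seq_len(K)),
      k_unfold = exp(par$lk0)[ord],
      dx = par$dx[ord],
      weight = par$w[ord],
      weight_events = w_ev[ord],
      modal_force = fstar[ord],
      stringsAsFactors = FALSE
    ),
    K = K,
    w_censored_excess = par$w0,
    log_likelihood = ll,
    n_events = length(forces),
    n_censored = n_censored,
    BIC = -2 * ll + npar * log(n_tot),
    convergence = best$convergence,
    theta = best$par,
    protocol = protocol
  ), class = "bell_mixture_fit")
  if (best$convergence != 0) {
    warning("mixture fit did not report clean convergence (code ",
            best$convergence, ")")
  }
  res
}

#' @export
print.bell_mixture_fit <- function(x, ...) {
  cat("Bell mixture fit: K =", x$K, "components,", x$n_events, "events,",
      x$n_censored, "no-rupture cycles\n")
  st <- x$states
  st$k_unfold <- signif(st$k_unfold, 3)
  st[-1] <- lapply(st[-1], function(v) if (is.numeric(v)) round(v, 3) else v)
  print(st, row.names = FALSE)
  cat("never-folded mass:", round(x$w_censored_excess, 3),
      "| logLik:", round(x$log_likelihood, 2),
      "| BIC:", round(x$BIC, 2), "\n")
  invisible(x)
}

#' Select the number of mixture components by BIC
#'
#' Fits `K = 1..K_max` with [fit_bell_mixture()] and returns the fit with
#' the smallest BIC (ties go to the smaller K).
#'
#' @inheritParams fit_bell_mixture
#' @param K_max Largest number of components to try.
#' @return The selected `bell_mixture_fit`, with a `K_table` data.frame
#'   (`K`, `BIC`, `log_likelihood`) attached.
#' @export
select_K <- function(forces, n_censored = 0, protocol, K_max, seed = 1,
                     n_starts = 10) {
  stopifnot(K_max >= 1)
  fits <- list()
  for (K in seq_len(K_max)) {
    fits[[K]] <- tryCatch(
      fit_bell_mixture(forces, n_censored, protocol, K,
                       n_starts = n_starts, seed = seed),
      error = function(e) NULL
    )
  }
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) stop("no candidate K could be fitted")
  bic <- vapply(fits, function(f) if (is.null(f)) Inf else f$BIC, numeric(1))
  best <- which.min(bic) # which.min takes the first (smallest K) on ties
  out <- fits[[best]]
  out$K_table <- data.frame(
    K = seq_len(K_max),
    BIC = bic,
    log_likelihood = vapply(fits, function(f) {
      if (is.null(f)) NA_real_ else f$log_likelihood
    }, numeric(1))
  )
  out
}

#' Split mixture mass at a mechanical-stability threshold
#'
#' Partitions the fitted mixture by whether each component's modal force
#' exceeds a threshold (40 pN by convention separates fully-folded G4s from
#' less stable partially-folded states). Reported both as cycle-level mass
#' (fitted weights) and as fractions of detected events.
#'
#' @param fit A `bell_mixture_fit`.
#' @param threshold Force threshold, pN. Default 40.
#' @param forces Optional raw forces; if supplied an empirical event-count
#'   split is added.
#' @return List with `above`, `below` (cycle-weight mass), `above_events`,
#'   `below_events` (event-fraction mass), and when `forces` is given
#'   `above_empirical`, `below_empirical`.
#' @export
population_fractions <- function(fit, threshold = 40, forces = NULL) {
  stopifnot(inherits(fit, "bell_mixture_fit"))
  hi <- fit$states$modal_force > threshold
  out <- list(
    above = sum(fit$states$weight[hi]),
    below = sum(fit$states$weight[!hi]),
    above_events = sum(fit$states$weight_events[hi]),
    below_events = sum(fit$states$weight_events[!hi])
  )
  if (!is.null(forces)) {
    out$above_empirical <- mean(forces > threshold)
    out$below_empirical <- mean(forces <= threshold)
  }
  out
}

#' Case-resampling bootstrap confidence intervals for a mixture fit
#'
#' Resamples cycles (observed forces and no-rupture cycles jointly) with
#' replacement, refits warm-started at the original solution, and reports
#' percentile intervals for each component's modal force, weight, and
#' `log(k_unfold)`. Components are matched across replicates by modal-force
#' rank.
#'
#' @inheritParams fit_bell_mixture
#' @param fit The original `bell_mixture_fit`.
#' @param n_boot Number of bootstrap replicates, `>= 100`.
#' @param level Confidence level. Default 0.95.
#' @return List with `modal_force`, `weight`, `log_k_unfold`: each a
#'   data.frame with `component`, `lower`, `upper`; plus `n_boot`.
#' @export
bootstrap_cis <- function(forces, n_censored = 0, protocol, fit,
                          n_boot = 200, seed = 1, level = 0.95) {
  stopifnot(inherits(fit, "bell_mixture_fit"), n_boot >= 100)
  if (stats::sd(forces) == 0) {
    stop("degenerate (zero-spread) forces: bootstrap is not meaningful")
  }
  set.seed(seed)
  K <- fit$K
  n <- length(forces)
  n_tot <- n + n_censored
  fs <- ws <- lk <- matrix(NA_real_, n_boot, K)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n_tot, n_tot, replace = TRUE)
    f_b <- forces[idx[idx <= n]]
    nc_b <- sum(idx > n)
    rf <- tryCatch(
      fit_bell_mixture(f_b, nc_b, protocol, K, n_starts = 2,
                       seed = seed + b, init = fit$theta),
      error = function(e) NULL
    )
    if (is.null(rf)) next
    fs[b, ] <- rf$states$modal_force
    ws[b, ] <- rf$states$weight
    lk[b, ] <- log(rf$states$k_unfold)
  }
  alpha <- (1 - level) / 2
  ci <- function(m) data.frame(
    component = seq_len(K),
    lower = apply(m, 2, stats::quantile, alpha, na.rm = TRUE),
    upper = apply(m, 2, stats::quantile, 1 - alpha, na.rm = TRUE)
  )
  list(modal_force = ci(fs), weight = ci(ws), log_k_unfold = ci(lk),
       n_boot = n_boot)
}
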