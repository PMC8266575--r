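# Synthetic-data generator: the package's stand-in for raw magnetic-tweezers
# measurements. Each pull cycle draws a conformational outcome from a state
# mixture, a rupture force from the Bell ramp distribution, and a noisy
# extension jump from the WLC forward model.

#' Conformational ensemble of a G4-forming sequence
#'
#' A categorical mixture over folded Bell states plus an unfolded/misfolded
#' class that shows ssDNA-like behaviour (no rupture during the ramp).
#' Weights are normalised to sum to one.
#'
#' @param states List of [bell_state()] objects.
#' @param weights Non-negative weights, one per state.
#' @param w_unfolded Weight of the unfolded/misfolded (no-rupture) outcome.
#' @return Object of class `state_mixture`.
#' @export
state_mixture <- function(states, weights, w_unfolded = 0) {
  if (length(states) == 0) stop("mixture must contain at least one state")
  stopifnot(length(weights) == length(states),
            all(weights >= 0), w_unfolded >= 0,
            all(vapply(states, inherits, logical(1), "bell_state")))
  tot <- sum(weights) + w_unfolded
  if (tot <= 0) stop("mixture weights sum to zero")
  structure(list(states = states, weights = weights / tot,
                 w_unfolded = w_unfolded / tot),
            class = "state_mixture")
}

#' Measurement noise model
#'
#' @param sigma_step Gaussian sd on recorded extension jumps, nm. Default 0.6.
#' @param sigma_bead Per-sample trace noise, nm. Default 1.0.
#' @param trace_rate Trace sampling rate, Hz. Default 100.
#' @return Object of class `noise_model`.
#' @export
noise_model <- function(sigma_step = 0.6, sigma_bead = 1.0, trace_rate = 100) {
  stopifnot(sigma_step >= 0, sigma_bead >= 0, trace_rate > 0)
  structure(list(sigma_step = sigma_step, sigma_bead = sigma_bead,
                 trace_rate = trace_rate),
            class = "noise_model")
}

#' Simulate force-ramp pull cycles
#'
#' Generates one row per force-ramp cycle. Per cycle: a conformational
#' outcome is drawn from the mixture; a folded state ruptures at a force
#' drawn by exact inverse-CDF sampling of the Bell ramp distribution (draws
#' above `f_end` are censored: the structure survives the ramp and no force
#' is recorded); the recorded extension jump is the WLC forward-model step
#' for the state's released nucleotides at the rupture force plus Gaussian
#' noise. Unfolded/misfolded cycles produce no rupture.
#'
#' @param mixture A [state_mixture()].
#' @param protocol A [ramp_protocol()].
#' @param polymer A [polymer_params()].
#' @param noise A [noise_model()].
#' @param n_cycles Number of cycles, `>= 1`.
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @param n_molecules Number of tethered molecules the cycles are spread
#'   over (round-robin). Default 5.
#' @return `data.frame` with columns `cycle_id`, `molecule_id`, `hold_time`,
#'   `ruptured`, `censored`, `force` (pN, `NA` unless ruptured), `delta_x`
#'   (nm, `NA` unless ruptured), `state_truth` (generator label; `"unfolded"`
#'   for the no-rupture class).
#' @export
simulate_cycles <- function(mixture, protocol, polymer, noise, n_cycles,
                            seed = 1, n_molecules = 5) {
  stopifnot(inherits(mixture, "state_mixture"), n_cycles >= 1)
  set.seed(seed)
  K <- length(mixture$states)
  labels <- vapply(seq_len(K), function(i) {
    lab <- mixture$states[[i]]$label
    if (nzchar(lab)) lab else paste0("state", i)
  }, character(1))

  outcome <- sample.int(K + 1, n_cycles, replace = TRUE,
                        prob = c(mixture$weights, mixture$w_unfolded))
  force <- rep(NA_real_, n_cycles)
  delta_x <- rep(NA_real_, n_cycles)
  censored <- rep(FALSE, n_cycles)
  u <- stats::runif(n_cycles)
  u <- pmin(pmax(u, 1e-15), 1 - 1e-15)
  for (i in seq_len(K)) {
    idx <- which(outcome == i)
    if (!length(idx)) next
    f <- sample_force(u[idx], mixture$states[[i]], protocol)
    cens <- f > protocol$f_end
    force[idx[!cens]] <- f[!cens]
    censored[idx[cens]] <- TRUE
  }
  ruptured <- !is.na(force)
  if (any(ruptured)) {
    st <- outcome[ruptured]
    nt <- vapply(mixture$states, function(s) s$step_nt, numeric(1))[st]
    delta_x[ruptured] <- step_from_nt(nt, force[ruptured], polymer) +
      stats::rnorm(sum(ruptured), 0, noise$sigma_step)
  }
  data.frame(
    cycle_id = seq_len(n_cycles),
    molecule_id = rep_len(seq_len(n_molecules), n_cycles),
    hold_time = protocol$hold_time,
    ruptured = ruptured,
    censored = censored,
    force = force,
    delta_x = delta_x,
    state_truth = c(labels, "unfolded")[outcome],
    stringsAsFactors = FALSE
  )
}

#' Simulate a time-evolution folding-probability series
#'
#' Binomial folded/unfolded counts at a set of hold times under first-order
#' refolding kinetics `p_fold(t) = p_st (1 - exp(-k_fold t))`.
#'
#' @param p_st Steady-state folding probability in `[0, 1]`.
#' @param k_fold Apparent folding rate in 1/s, `> 0`.
#' @param hold_times Hold times in s.
#' @param n_per_time Cycles per hold time.
#' @param seed Integer seed.
#' @return `data.frame(t, n_folded, n_total)`.
#' @export
simulate_pfold_series <- function(p_st, k_fold, hold_times, n_per_time,
                                  seed = 1) {
  if (p_st < 0 || p_st > 1) stop("p_st must lie in [0, 1]")
  if (k_fold <= 0) stop("k_fold must be positive")
  set.seed(seed)
  p <- p_st * (1 - exp(-k_fold * hold_times))
  data.frame(
    t = hold_times,
    n_folded = stats::rbinom(length(hold_times), n_per_time, p),
    n_total = rep(n_per_time, length(hold_times))
  )
}

#' Simulate a full extension-versus-time ramp trace
#'
#' Baseline is the dsDNA-handle WLC extension along the ramp; if the cycle
#' ruptured, a step of its `delta_x` is added at the programmed rupture time
#' `t = (force - f_start) / loading_rate`; per-sample Gaussian bead noise on
#' top. Used to exercise the step detector.
#'
#' @param cycle One-row `data.frame` as produced by [simulate_cycles()] (or a
#'   list with `ruptured`, `force`, `delta_x`).
#' @param protocol A [ramp_protocol()].
#' @param polymer ssDNA [polymer_params()] (unused for the baseline, kept for
#'   interface symmetry with the analysis chain).
#' @param noise A [noise_model()] (uses `sigma_bead`, `trace_rate`).
#' @param handle dsDNA handle [polymer_params()]. Default Lp 50 nm,
#'   0.34 nm/nt, no folded extent.
#' @param handle_nt Handle length in nt (sets the baseline compliance).
#' @param seed Integer seed.
#' @return `data.frame(time_s, force_pN, extension_nm)`.
#' @export
simulate_trace <- function(cycle, protocol, polymer, noise,
                           handle = polymer_params(persistence_length = 50,
                                                   contour_per_nt = 0.34,
                                                   folded_extent = 0),
                           handle_nt = 1000, seed = 1) {
  set.seed(seed)
  t_end <- (protocol$f_end - protocol$f_start) / protocol$loading_rate
  time <- seq(0, t_end, by = 1 / noise$trace_rate)
  force <- protocol$f_start + protocol$loading_rate * time
  ext <- handle_nt * ss_extension_per_nt(force, handle)
  if (isTRUE(cycle$ruptured[1])) {
    t_rupt <- (cycle$force[1] - protocol$f_start) / protocol$loading_rate
    ext <- ext + cycle$delta_x[1] * (time >= t_rupt)
  }
  if (noise$sigma_bead > 0) {
    ext <- ext + stats::rnorm(length(ext), 0, noise$sigma_bead)
  }
  data.frame(time_s = time, force_pN = force, extension_nm = ext)
}

#' Simulate a thermal melting curve
#'
#' Sigmoidal denaturation profile
#' `y(T) = y_f + (y_u - y_f) / (1 + exp(-(T - tm)/width))` with additive
#' Gaussian noise, on a temperature grid (default 20-85 C as in a CD melting
#' run at 265 nm).
#'
#' @param tm Melting temperature, C.
#' @param width Transition width, C, `> 0`.
#' @param baselines Length-2 numeric `(y_f, y_u)`: folded and unfolded
#'   signal baselines.
#' @param t_grid Temperature grid, C.
#' @param noise_sd Gaussian noise sd on the signal.
#' @param seed Integer seed.
#' @return `data.frame(temp_C, signal)`.
#' @export
simulate_melting_curve <- function(tm, width, baselines = c(0, 1),
                                   t_grid = seq(20, 85, by = 1),
                                   noise_sd = 0.01, seed = 1) {
  if (width <= 0) stop("width must be positive")
  set.seed(seed)
  y <- baselines[1] + (baselines[2] - baselines[1]) /
    (1 + exp(-(t_grid - tm) / width))
  if (noise_sd > 0) y <- y + stats::rnorm(length(t_grid), 0, noise_sd)
  data.frame(temp_C = t_grid, signal = y)
}
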