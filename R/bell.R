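# Bell-model rupture kinetics under a linear force ramp. The protocol is a
# deterministic ramp F(t) = f_start + r t, so everything is formulated in the
# force domain.

#' A Bell-kinetics folded state
#'
#' One folded conformation characterised by its zero-force unfolding rate and
#' distance to the transition state, plus the number of nucleotides it
#' releases on rupture.
#'
#' @param k_unfold Zero-force unfolding rate in 1/s, `> 0`.
#' @param dx Distance to the transition state (Delta x double-dagger) in nm,
#'   `> 0`.
#' @param step_nt Nucleotides released on unfolding, `>= 0`. Default 0.
#' @param label Free-text label (e.g. `"full"`, `"gvbq_5p"`).
#' @return Object of class `bell_state`.
#' @export
bell_state <- function(k_unfold, dx, step_nt = 0, label = "") {
  stopifnot(is.numeric(k_unfold), k_unfold > 0,
            is.numeric(dx), dx > 0,
            is.numeric(step_nt), step_nt >= 0)
  structure(list(k_unfold = k_unfold, dx = dx, step_nt = step_nt,
                 label = as.character(label)),
            class = "bell_state")
}

#' Force-ramp protocol
#'
#' The measurement protocol: force ramped linearly from `f_start` to `f_end`
#' at `loading_rate`, then dropped to `hold_force` for `hold_time` seconds to
#' allow refolding. Defaults follow a 2 pN/s ramp from 1 to 60 pN with a
#' 30 s hold at 1 pN.
#'
#' @param f_start Ramp start force in pN.
#' @param f_end Ramp end force (censoring ceiling) in pN.
#' @param loading_rate Loading rate r in pN/s, `> 0`.
#' @param hold_force Refolding hold force in pN.
#' @param hold_time Refolding hold time in s.
#' @param kBT Thermal energy in pN nm.
#' @return Object of class `ramp_protocol`.
#' @export
ramp_protocol <- function(f_start = 1, f_end = 60, loading_rate = 2,
                          hold_force = 1, hold_time = 30, kBT = 4.11) {
  stopifnot(f_start < f_end, loading_rate > 0, kBT > 0)
  structure(list(f_start = f_start, f_end = f_end,
                 loading_rate = loading_rate,
                 hold_force = hold_force, hold_time = hold_time,
                 kBT = kBT),
            class = "ramp_protocol")
}

#' Bell unfolding hazard
#'
#' `k(F) = k_unfold * exp(F dx / kBT)`: log-linear force dependence with slope
#' `dx / kBT`.
#'
#' @param force Force(s) in pN, `>= 0`.
#' @param state A [bell_state()].
#' @param kBT Thermal energy in pN nm.
#' @return Rate(s) in 1/s.
#' @export
bell_hazard <- function(force, state, kBT = 4.11) {
  if (any(force < 0)) stop("force must be non-negative")
  state$k_unfold * exp(force * state$dx / kBT)
}

#' Survival probability under a linear force ramp
#'
#' Probability that a folded state survives (has not ruptured) when the ramp
#' reaches `force`, for the Bell hazard integrated along the ramp:
#' \deqn{S(F) = \exp\!\big[-\tfrac{k_BT\,k_u}{r\,\Delta x}
#'   (e^{F\Delta x/k_BT} - e^{F_0\Delta x/k_BT})\big].}
#'
#' @param force Force(s) in pN, `>= f_start`.
#' @param state A [bell_state()].
#' @param protocol A [ramp_protocol()].
#' @return Survival probability(ies) in `[0, 1]`.
#' @export
ramp_survival <- function(force, state, protocol) {
  if (any(force < protocol$f_start)) stop("force must be >= f_start")
  b <- state$dx / protocol$kBT
  a <- protocol$kBT * state$k_unfold / (protocol$loading_rate * state$dx)
  exp(-a * (exp(b * force) - exp(b * protocol$f_start)))
}

#' Rupture-force density under a linear force ramp
#'
#' `p(F) = k(F)/r * S(F)`; integrates to 1 over `[f_start, Inf)`.
#'
#' @inheritParams ramp_survival
#' @return Density(ies) per pN.
#' @export
ramp_pdf <- function(force, state, protocol) {
  bell_hazard(force, state, protocol$kBT) / protocol$loading_rate *
    ramp_survival(force, state, protocol)
}

#' Most probable rupture force
#'
#' Mode of the ramp rupture-force distribution,
#' `F* = (kBT/dx) log(r dx / (k_unfold kBT))`. If the mode falls at or below
#' `f_start` (density monotone decreasing over the ramp) the value `f_start`
#' is returned with attribute `at_boundary = TRUE`.
#'
#' @param state A [bell_state()].
#' @param protocol A [ramp_protocol()].
#' @return Modal force in pN (attribute `at_boundary` flags a boundary mode).
#' @export
modal_force <- function(state, protocol) {
  fstar <- (protocol$kBT / state$dx) *
    log(protocol$loading_rate * state$dx / (state$k_unfold * protocol$kBT))
  if (!is.finite(fstar) || fstar <= protocol$f_start) {
    return(structure(protocol$f_start, at_boundary = TRUE))
  }
  structure(fstar, at_boundary = FALSE)
}

#' Zero-force rate reproducing a given modal force
#'
#' Inverse of [modal_force()] at fixed `dx`: the `k_unfold` for which the ramp
#' rupture-force distribution peaks at `peak`. Used to build simulation
#' scenarios from reported peak forces.
#'
#' @param peak Target modal force in pN.
#' @param dx Transition distance in nm.
#' @param protocol A [ramp_protocol()].
#' @return `k_unfold` in 1/s.
#' @export
k_unfold_from_modal_force <- function(peak, dx, protocol) {
  protocol$loading_rate * dx / protocol$kBT * exp(-peak * dx / protocol$kBT)
}

#' Exact inverse-CDF sampling of rupture forces
#'
#' Maps uniform variates through the closed-form quantile function of the
#' Bell ramp distribution:
#' `F = (kBT/dx) log[exp(f_start dx/kBT) - (r dx)/(kBT k_unfold) log(1-u)]`,
#' so that `ramp_survival(F) = 1 - u` exactly. Samples may exceed `f_end`;
#' such draws are censored in a real measurement.
#'
#' @param u Uniform(0,1) variate(s), strictly inside the unit interval.
#' @param state A [bell_state()].
#' @param protocol A [ramp_protocol()].
#' @return Rupture force(s) in pN.
#' @export
sample_force <- function(u, state, protocol) {
  if (any(u <= 0) || any(u >= 1)) stop("u must lie strictly in (0, 1)")
  b <- state$dx / protocol$kBT
  (1 / b) * log(exp(b * protocol$f_start) -
                  (protocol$loading_rate * state$dx) /
                  (protocol$kBT * state$k_unfold) * log1p(-u))
}
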