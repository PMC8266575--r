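# Worm-like-chain elasticity for ssDNA released on unfolding (and for dsDNA
# handles when building simulated traces). All forces in pN, lengths in nm,
# energies in pN nm.

#' Polymer elasticity parameters
#'
#' Constants of the inextensible Marko-Siggia worm-like chain used to convert
#' extension jumps at force into released nucleotide counts. Defaults describe
#' single-stranded DNA at room temperature; for double-stranded handles use
#' e.g. `polymer_params(persistence_length = 50, contour_per_nt = 0.34,
#' folded_extent = 0)`.
#'
#' @param persistence_length Persistence length Lp in nm. Default 0.8 (ssDNA).
#' @param contour_per_nt Contour length per nucleotide in nm/nt. Default 0.56.
#' @param folded_extent End-to-end extent of the folded structure along the
#'   pulling axis in nm; this length is already spanned before rupture and is
#'   subtracted from the released contour. Default 2.0 (a G-quadruplex core).
#'   May be 0 (e.g. for handles).
#' @param kBT Thermal energy in pN nm. Default 4.11, i.e. 23-25 C.
#' @return Object of class `polymer_params`.
#' @examples
#' p <- polymer_params()
#' wlc_force(0.5, p)
#' @export
polymer_params <- function(persistence_length = 0.8, contour_per_nt = 0.56,
                           folded_extent = 2.0, kBT = 4.11) {
  stopifnot(
    is.numeric(persistence_length), persistence_length > 0,
    is.numeric(contour_per_nt), contour_per_nt > 0,
    is.numeric(folded_extent), folded_extent >= 0,
    is.numeric(kBT), kBT > 0
  )
  structure(
    list(persistence_length = persistence_length,
         contour_per_nt = contour_per_nt,
         folded_extent = folded_extent,
         kBT = kBT),
    class = "polymer_params"
  )
}

#' Marko-Siggia worm-like-chain force
#'
#' Force required to hold a worm-like chain at a given relative extension
#' `z = x / L_contour`:
#' \deqn{F(z) = (k_BT/L_p)\,[1/(4(1-z)^2) - 1/4 + z].}
#' Strictly increasing in `z` and divergent as `z -> 1`.
#'
#' @param relative_extension Relative extension(s) in `[0, 1)`.
#' @param params A [polymer_params()] object.
#' @return Force(s) in pN.
#' @export
wlc_force <- function(relative_extension, params) {
  z <- relative_extension
  if (any(!is.finite(z)) || any(z < 0) || any(z >= 1)) {
    stop("relative_extension must lie in [0, 1)")
  }
  (params$kBT / params$persistence_length) * (1 / (4 * (1 - z)^2) - 0.25 + z)
}

#' ssDNA extension per nucleotide at force
#'
#' Numerically inverts [wlc_force()] and scales by the contour length per
#' nucleotide: returns `contour_per_nt * z(F)` where `z(F)` solves
#' `wlc_force(z) = F`. The root is bracketed and polished with Newton steps to
#' a force residual below 1e-9 pN.
#'
#' @param force Force(s) in pN, strictly positive.
#' @param params A [polymer_params()] object.
#' @return Extension(s) in nm per nucleotide.
#' @export
ss_extension_per_nt <- function(force, params) {
  if (any(!is.finite(force)) || any(force <= 0)) {
    stop("force must be strictly positive")
  }
  params$contour_per_nt * vapply(force, .wlc_invert, numeric(1), params = params)
}

# invert Marko-Siggia: z such that wlc_force(z) = f
.wlc_invert <- function(f, params) {
  root <- stats::uniroot(
    function(z) wlc_force(z, params) - f,
    lower = 0, upper = 1 - 1e-12, tol = 1e-12
  )$root
  # Newton polish; dF/dz = (kBT/Lp) (1/(2(1-z)^3) + 1)
  c0 <- params$kBT / params$persistence_length
  for (i in 1:3) {
    res <- wlc_force(root, params) - f
    if (abs(res) < 1e-12) break
    dFdz <- c0 * (1 / (2 * (1 - root)^3) + 1)
    root <- min(max(root - res / dFdz, 0), 1 - 1e-12)
  }
  root
}

#' Convert an extension jump to released nucleotides
#'
#' The number of nucleotides released by an unfolding event with extension
#' jump `delta_x` observed at rupture force `force`:
#' `n = (delta_x + folded_extent) / ss_extension_per_nt(force)`. Exact inverse
#' of [step_from_nt()] at the same force.
#'
#' @param delta_x Extension jump(s) in nm.
#' @param force Rupture force(s) in pN (recycled against `delta_x`).
#' @param params A [polymer_params()] object.
#' @return Released nucleotide count(s), real-valued.
#' @export
nt_from_step <- function(delta_x, force, params) {
  if (any(delta_x <= -params$folded_extent)) {
    stop("delta_x must exceed -folded_extent")
  }
  (delta_x + params$folded_extent) / ss_extension_per_nt(force, params)
}

#' Expected extension jump for a released nucleotide count
#'
#' Forward model used by the simulator: a structure releasing `n` nucleotides
#' at force `F` produces a jump `n * ss_extension_per_nt(F) - folded_extent`.
#'
#' @param n Nucleotides released, `>= 0`.
#' @param force Force(s) in pN.
#' @param params A [polymer_params()] object.
#' @return Extension jump(s) in nm.
#' @export
step_from_nt <- function(n, force, params) {
  if (any(n < 0)) stop("n must be non-negative")
  n * ss_extension_per_nt(force, params) - params$folded_extent
}
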