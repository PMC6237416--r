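#' Construct a system state vector
#'
#' A system state is a named numeric vector of the 16 reduced coordinates:
#' the 14 contact indexes (bp slid at each half-integer SHL contact,
#' relative to the cycle-start registration) followed by the two lobe
#' registration coordinates.
#'
#' @param x numeric(14) contact indexes (bp), ordered SHL -6.5 ... +6.5.
#' @param y1,y2 lobe 1 / lobe 2 registration (bp).
#' @return named numeric(16).
#' @examples
#' systemState()                      # reference registration, open
#' systemState(y1 = 1)                # lobe 1 stepped forward
#' @export
systemState <- function(x = rep(0, 14), y1 = 0, y2 = 0) {
  stopifnot(length(x) == 14, is.finite(x), is.finite(y1), is.finite(y2))
  setNames(c(x, y1, y2), coordNames())
}

asState <- function(s) {
  if (length(s) != 16 || !all(is.finite(s)))
    stop("a system state must be 16 finite coordinates")
  as.numeric(s)
}

#' Twist-defect energy at one defect site
#'
#' Three-well potential in the defect coordinate d (bp): local minima at
#' d = -1, 0, +1 with energies \code{mu_minus}, 0, \code{mu_plus} and
#' curvature k around each, joined continuously by a softmin (log-sum-exp at
#' temperature \code{smooth}) of the three shifted harmonics.  Beyond
#' |d| ~ 2.5 the value follows the outermost harmonic branch.
#'
#' @param d defect size (bp); vectorized.
#' @param k twist stiffness (kBT/bp^2), > 0.
#' @param mu_plus,mu_minus defect penalties (kBT), >= 0.
#' @param smooth softmin temperature (kBT).
#' @return energy in kBT.
#' @examples
#' twistEnergy(0, 15, 3, 3)    # reference well: 0
#' twistEnergy(1, 15, 3, 3)    # +1 bp defect: mu_plus
#' @export
twistEnergy <- function(d, k, mu_plus, mu_minus, smooth = 0.2) {
  stopifnot(k > 0, mu_plus >= 0, mu_minus >= 0, smooth > 0)
  vapply(d, cpp_twist_energy, numeric(1), k = k, mup = mu_plus,
         mum = mu_minus, smooth = smooth)
}

#' Total reduced potential energy
#'
#' Sum of seven closed-form terms: (i) periodic histone-DNA contact wells,
#' (ii) positioning tilt, (iii) twist-defect energies over the 13 defect
#' SHLs, (iv) periodic lobe grip wells with chemical-state-dependent depth,
#' (v) the lobe-lobe double well in u = y1 - y2 (open u = 0 / closed u = 1),
#' (vi) the steric wall confining the remodeler body to its DNA binding
#' site, and (vii) the electrostatic spring between lobe 1 and the SHL -6
#' gyre.  Terms may be switched off in the ParameterSet (naked-DNA or
#' spontaneous-sliding modes).
#'
#' @param state numeric(16), see \code{\link{systemState}}.
#' @param ps a \code{\linkS4class{ParameterSet}}.
#' @return energy in kBT.
#' @seealso \code{\link{energyGradient}}
#' @export
totalEnergy <- function(state, ps) {
  cpp_energy(asState(state), asPhaseList(ps))
}

#' Analytic gradient of the reduced potential
#'
#' Partial derivatives of \code{\link{totalEnergy}} with respect to all 16
#' coordinates (kBT/bp).  Piecewise joins (steric wall edge) are handled
#' one-sidedly.
#'
#' @inheritParams totalEnergy
#' @return named numeric(16).
#' @export
energyGradient <- function(state, ps) {
  setNames(cpp_gradient(asState(state), asPhaseList(ps)), coordNames())
}
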