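#' Analytic steady state of the unexposed system
#'
#' Solves both right-hand sides for zero with all compound
#' concentrations at zero: `O_ss = supply / KE` and
#' `Psi_ss = supply * Cf * KA / (VA - supply * Cf)`. Cells are assumed
#' to be at this homeostatic state at the moment of exposure, so every
#' simulation starts here.
#'
#' @param params a [ModelParameters-class] object.
#' @return named numeric vector with elements `O` and `Psi`.
#' @examples
#' steadyState(modelParameters())  # O = 0.6, Psi = 1
#' @export
steadyState <- function(params) {
  stopifnot(is(params, "ModelParameters"))
  .ssRaw(params)
}

## steady state without S4 validity machinery; used on every
## right-hand-side evaluation inside optimization loops
.ssRaw <- function(params) {
  denom <- params@VA - params@supply * params@Cf
  if (denom <= 0 || params@KE <= 0)
    stop("no positive MMP steady state: VA must exceed supply*Cf")
  c(O = params@supply / params@KE,
    Psi = params@supply * params@Cf * params@KA / denom)
}

## Derivatives of the steady state w.r.t. a named parameter; used for
## sensitivity initial conditions.
.steadyStateGrad <- function(params, name) {
  s <- params@supply; Cf <- params@Cf; VA <- params@VA; KA <- params@KA
  den <- VA - s * Cf
  dO <- 0; dPsi <- 0
  if (name == "KE") dO <- -s / params@KE^2
  if (name == "VA") dPsi <- -s * Cf * KA / den^2
  if (name == "KA") dPsi <- s * Cf / den
  if (name == "Cf") dPsi <- s * KA * VA / den^2
  c(dO, dPsi)
}

#' Oxygen consumption rate (OCR)
#'
#' The consumption term of the oxygen equation,
#' `KE * O * KEi / (KEi + doseE)`: linear in the oxygen level, reduced
#' by an ETC inhibitor through Michaelis-Menten inhibition kinetics.
#'
#' @param O oxygen level (a.u.).
#' @param doseE effective ETC-inhibitor concentration (uM).
#' @param params a [ModelParameters-class] object.
#' @return the OCR (a.u./h); vectorized over `O` and `doseE`.
#' @export
ocr <- function(O, doseE, params) {
  stopifnot(all(O >= 0), all(doseE >= 0))
  params@KE * O * params@KEi / (params@KEi + doseE)
}

#' Right-hand side of the oxygen equation
#'
#' `r * (supply - OCR)`: constant supply balanced against
#' inhibitor-sensitive consumption.
#'
#' @param state named vector with elements `O` and `Psi`.
#' @inheritParams ocr
#' @return dO/dt (a.u./h).
#' @export
oxygenRhs <- function(state, doseE, params) {
  unname(params@r * (params@supply - ocr(state[["O"]], doseE, params)))
}

#' Right-hand side of the MMP equation
#'
#' Proton influx proportional to the OCR, depletion by ATP synthesis
#' (Michaelis-Menten in the MMP, inhibited by an ATP-synthase
#' inhibitor) and depletion by uncoupler-mediated proton flux:
#' `r * (Cf*OCR - VA*Psi/(KA+Psi) * KAi/(KAi+doseA)
#'  - VU*doseU/(KU+doseU) * Psi)`.
#'
#' @param state named vector with elements `O` and `Psi`.
#' @param doseE,doseA,doseU effective concentrations of the ETC
#'   inhibitor, ATP-synthase inhibitor and uncoupler (uM).
#' @param params a [ModelParameters-class] object.
#' @return dPsi/dt (a.u./h).
#' @export
mmpRhs <- function(state, doseE, doseA, doseU, params) {
  stopifnot(doseA >= 0, doseU >= 0)
  Psi <- state[["Psi"]]
  stopifnot(Psi >= 0)
  influx <- params@Cf * ocr(state[["O"]], doseE, params)
  synth <- params@VA * Psi / (params@KA + Psi) *
    params@KAi / (params@KAi + doseA)
  unc <- params@VU * doseU / (params@KU + doseU) * Psi
  unname(params@r * (influx - synth - unc))
}

#' Right-hand side of the MMP equation with ion leakage
#'
#' Leakage variant used for ATP-synthase inhibitors: the oxygen term is
#' the constant `supply * Cf` (oxygen stays at steady state because no
#' ETC inhibitor is present), and a linear leakage term
#' `alpha * (Psi - Psi_o) * H(t)` pulls the MMP back toward its steady
#' state once exposure has started. `H(0) = 1`.
#'
#' @param Psi MMP value (a.u.).
#' @param doseA effective ATP-synthase inhibitor concentration (uM).
#' @param t time since exposure start (hours); the leakage term is
#'   gated off for `t < 0`.
#' @param params a [ModelParameters-class] object.
#' @return dPsi/dt (a.u./h).
#' @export
leakageRhs <- function(Psi, doseA, t, params) {
  stopifnot(Psi >= 0, doseA >= 0)
  psio <- steadyState(params)[["Psi"]]
  synth <- params@VA * Psi / (params@KA + Psi) *
    params@KAi / (params@KAi + doseA)
  leak <- if (t >= 0) params@alpha * (Psi - psio) else 0
  unname(params@r * (params@supply * params@Cf - synth - leak))
}

#' Effective concentration under pharmacokinetic decay
#'
#' `D0 * exp(-gamma * t) * H(t)` with Heaviside gate `H(0) = 1`:
#' the compound is absent before exposure, appears at its applied
#' effective level at `t = 0`, and decays exponentially afterwards.
#'
#' @param D0 applied effective concentration (uM).
#' @param gamma decay rate (1/h).
#' @param t time since exposure start (hours); vectorized.
#' @return effective concentration at `t`.
#' @examples
#' effectiveConcentration(1, log(2), 3)  # three half-lives: 0.125
#' @export
effectiveConcentration <- function(D0, gamma, t) {
  stopifnot(all(D0 >= 0), all(gamma >= 0))
  D0 * exp(-gamma * t) * as.numeric(t >= 0)
}

#' Map the MMP to the observed normalized intensity
#'
#' Linear observation model `y = c1 * Psi + c0`; microscope detectors
#' are operated below saturation so intensity is linear in the MMP.
#'
#' @param Psi MMP value(s) (a.u.).
#' @param params a [ModelParameters-class] object.
#' @return observed intensity (normalized a.u.).
#' @export
observe <- function(Psi, params) {
  params@c1 * Psi + params@c0
}

## Decay rate in effect for a given variant and dose index.
.doseGamma <- function(variant, params, doseIndex) {
  switch(variant@name,
    basic = 0,
    pk_decay = params@gamma,
    pk_decay_leakage = params@gamma,
    conc_dep_decay = if (doseIndex %in% variant@lowBlock)
      params@gammaL else params@gammaH)
}
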