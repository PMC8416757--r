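## Sensitivity parameter ids shared with src/mmp_deriv.c
.SENS_IDS <- c(VA = 1L, KA = 2L, KAi = 3L, Cf = 4L, KE = 5L, KEi = 6L,
               r = 7L, gamma = 8L, alpha = 9L, D0 = 10L)

## Resolve a free-parameter name to the ODE sensitivity id active for
## this variant/dose, or NA when the observed output of this condition
## does not depend on it through the ODE (zero column / c1 / c0).
.sensIdFor <- function(name, variant, doseIndex) {
  if (name %in% c("c1", "c0")) return(NA_integer_)
  if (name == "gamma")
    return(if (variant@name %in% c("pk_decay", "pk_decay_leakage"))
      .SENS_IDS[["gamma"]] else NA_integer_)
  if (name == "gammaL")
    return(if (variant@name == "conc_dep_decay" &&
               doseIndex %in% variant@lowBlock)
      .SENS_IDS[["gamma"]] else NA_integer_)
  if (name == "gammaH")
    return(if (variant@name == "conc_dep_decay" && doseIndex > 0 &&
               !(doseIndex %in% variant@lowBlock))
      .SENS_IDS[["gamma"]] else NA_integer_)
  if (name == "alpha")
    return(if (variant@name == "pk_decay_leakage")
      .SENS_IDS[["alpha"]] else NA_integer_)
  i <- .parseD0Name(name)
  if (!is.na(i))
    return(if (i == doseIndex) .SENS_IDS[["D0"]] else NA_integer_)
  if (name %in% names(.SENS_IDS)) return(.SENS_IDS[[name]])
  stop("cannot compute sensitivities for parameter: ", name)
}

## Assemble the compiled-model parameter block.
.odeParms <- function(variant, params, doseIndex, sensIds = integer(0)) {
  D0val <- if (doseIndex == 0) 0 else {
    if (doseIndex > length(params@D0))
      stop("doseIndex exceeds length(D0)")
    params@D0[doseIndex]
  }
  gam <- if (doseIndex == 0) 0 else .doseGamma(variant, params, doseIndex)
  psio <- .ssRaw(params)[["Psi"]]
  target <- match(variant@targetClass,
                  c("etc_inhibitor", "atp_synthase_inhibitor",
                    "uncoupler"))
  p <- numeric(32)
  p[1:14] <- c(params@supply, params@KE, params@KEi, params@Cf,
               params@VA, params@KA, params@KAi, params@VU, params@KU,
               params@r, params@alpha, psio, D0val, gam)
  p[15] <- as.numeric(variant@name == "pk_decay_leakage")
  p[16] <- target
  p[17] <- length(sensIds)
  if (length(sensIds)) p[17 + seq_along(sensIds)] <- sensIds
  p
}

.integrate <- function(y0, times, parms, rtol, atol) {
  t0 <- if (times[1] > 0) c(0, times) else times
  out <- deSolve::ode(y = y0, times = t0, func = "mmp_derivs",
                      parms = parms, dllname = "mmpdyn",
                      initfunc = "mmp_init", method = "lsoda",
                      rtol = rtol, atol = atol)
  if (nrow(out) < length(t0) || any(!is.finite(out[, -1])))
    stop("ODE integration failed (variant code ",
         parms[15], ", target ", parms[16], ", D0=", parms[13], ")")
  if (times[1] > 0) out <- out[-1, , drop = FALSE]
  out
}

#' Simulate a model variant over a measurement grid
#'
#' Integrates the chosen variant from the analytic steady state with a
#' stiff-capable solver and returns the state, observed and
#' effective-concentration series. `doseIndex = 0` simulates the
#' untreated (vehicle) condition.
#'
#' @param variant a [ModelVariant-class].
#' @param params a [ModelParameters-class]; `D0` must cover
#'   `doseIndex`.
#' @param doseIndex which entry of the ascending dose sequence to
#'   apply (0 for no compound).
#' @param times ascending measurement grid in hours, all `>= 0`;
#'   integration starts at `t = 0` with the post-exposure vector field.
#' @param rtol,atol solver tolerances.
#' @return a [Trajectory-class] object.
#' @examples
#' p <- modelParameters(D0 = c(0.1, 1))
#' tr <- simulateTrajectory(modelVariant("basic"), p, 2, times = 1:23)
#' head(as.data.frame(tr))
#' @export
simulateTrajectory <- function(variant, params, doseIndex,
                               times = 1:23, rtol = 1e-8,
                               atol = 1e-10) {
  stopifnot(is(variant, "ModelVariant"), is(params, "ModelParameters"))
  if (is.unsorted(times, strictly = TRUE) || times[1] < 0)
    stop("'times' must be strictly ascending and non-negative")
  sim <- .simRaw(variant, params, doseIndex, times, rtol, atol)
  new("Trajectory", times = as.numeric(times), O = sim$O,
      Psi = sim$Psi, y = sim$y, dose = sim$dose,
      sens = matrix(numeric(0), nrow = length(times), ncol = 0))
}

## plain-list simulation core (no S4 construction); the workhorse of
## the calibration loops
.simRaw <- function(variant, params, doseIndex, times, rtol = 1e-8,
                    atol = 1e-10) {
  y0 <- .ssRaw(params)
  parms <- .odeParms(variant, params, doseIndex)
  out <- .integrate(y0, times, parms, rtol, atol)
  Psi <- unname(out[, "Psi"])
  list(O = unname(out[, "O"]), Psi = Psi,
       y = params@c1 * Psi + params@c0,
       dose = unname(effectiveConcentration(parms[13], parms[14],
                                            times)))
}

#' Simulate with forward sensitivities of the observed output
#'
#' Integrates the augmented ODE system (states plus their derivatives
#' with respect to each free parameter, including the dependence of the
#' steady-state initial condition on parameters) and assembles the
#' Jacobian dy/dtheta of the observed intensity on the measurement
#' grid. Parameters the condition's output does not depend on (another
#' dose's `D0[i]`, the inactive block's decay rate, `alpha` in
#' non-leakage variants) get exact zero columns.
#'
#' @inheritParams simulateTrajectory
#' @param freeNames character vector of free parameter names
#'   (e.g. `c("VA", "KA", "D0[3]", "c1", "c0", "r")`).
#' @return a [Trajectory-class] whose `sens` slot is the
#'   `length(times) x length(freeNames)` sensitivity matrix.
#' @export
simulateSensitivities <- function(variant, params, doseIndex, times,
                                  freeNames, rtol = 1e-8,
                                  atol = 1e-10) {
  stopifnot(is(variant, "ModelVariant"), is(params, "ModelParameters"))
  sim <- .simSensRaw(variant, params, doseIndex, times, freeNames,
                     rtol, atol)
  new("Trajectory", times = as.numeric(times), O = sim$O,
      Psi = sim$Psi, y = sim$y, dose = sim$dose, sens = sim$sens)
}

.simSensRaw <- function(variant, params, doseIndex, times, freeNames,
                        rtol = 1e-8, atol = 1e-10) {
  ids <- vapply(freeNames, .sensIdFor, integer(1), variant = variant,
                doseIndex = doseIndex)
  odeNames <- freeNames[!is.na(ids)]
  odeIds <- ids[!is.na(ids)]
  y0 <- .ssRaw(params)
  s0 <- unlist(lapply(odeNames, function(nm) {
    ## steady-state depends on VA/KA/Cf/KE only; gammaL/gammaH/D0[i]
    ## and the rest have zero initial sensitivity
    base <- sub("\\[.*", "", nm)
    if (base %in% c("VA", "KA", "Cf", "KE"))
      .steadyStateGrad(params, base) else c(0, 0)
  }))
  yy0 <- c(y0, if (length(s0)) s0 else numeric(0))
  names(yy0) <- c("O", "Psi",
                  if (length(odeNames))
                    paste0(rep(c("sO.", "sPsi."), length(odeNames)),
                           rep(odeNames, each = 2)))
  parms <- .odeParms(variant, params, doseIndex, sensIds = odeIds)
  out <- .integrate(yy0, times, parms, rtol, atol)
  Psi <- unname(out[, "Psi"])
  sens <- matrix(0, nrow = length(times), ncol = length(freeNames),
                 dimnames = list(NULL, freeNames))
  ## columns: time, O, Psi, then (sO, sPsi) pairs
  for (k in seq_along(odeNames))
    sens[, odeNames[k]] <- params@c1 * out[, 2 * k + 3]
  if ("c1" %in% freeNames) sens[, "c1"] <- Psi
  if ("c0" %in% freeNames) sens[, "c0"] <- 1
  list(O = unname(out[, "O"]), Psi = Psi,
       y = params@c1 * Psi + params@c0,
       dose = unname(effectiveConcentration(parms[13], parms[14],
                                            times)),
       sens = sens)
}

#' Predict the oxygen consumption rate under ETC inhibition
#'
#' Simulates the basic model (or, with `gamma > 0`, the decay variant)
#' for an ETC inhibitor at effective concentration `doseE` and
#' evaluates the consumption term `KE * O(t) * KEi / (KEi + D_E(t))`
#' along the trajectory. At `doseE = 0` this returns the supply rate.
#'
#' @param params a [ModelParameters-class].
#' @param doseE applied effective ETC-inhibitor concentration (uM).
#' @param t evaluation times (hours, `>= 0`).
#' @param gamma optional decay rate of the inhibitor (1/h).
#' @return OCR value(s) at `t`.
#' @examples
#' predictOcr(modelParameters(), doseE = 1, t = 0.5)
#' @export
predictOcr <- function(params, doseE, t, gamma = 0) {
  stopifnot(all(t >= 0), doseE >= 0)
  p <- params
  p@D0 <- doseE
  p@gamma <- gamma
  vr <- modelVariant(if (gamma > 0) "pk_decay" else "basic",
                     "etc_inhibitor")
  tt <- sort(unique(pmax(t, 1e-12)))
  tr <- simulateTrajectory(vr, p, doseIndex = 1, times = tt)
  Ot <- tr@O[match(pmax(t, 1e-12), tt)]
  Dt <- effectiveConcentration(doseE, gamma, t)
  ocr(Ot, Dt, p)
}

#' @describeIn simulateTrajectory coerce a trajectory to a tidy
#'   data.frame with columns `time_h`, `O`, `Psi`, `y`,
#'   `effective_concentration`.
#' @param x a [Trajectory-class] object.
#' @param ... unused.
#' @export
as.data.frame.Trajectory <- function(x, ...) {
  data.frame(time_h = x@times, O = x@O, Psi = x@Psi, y = x@y,
             effective_concentration = x@dose)
}

setMethod("as.data.frame", "Trajectory",
          function(x, ...) as.data.frame.Trajectory(x, ...))

#' Export trajectories to tidy CSV
#'
#' Writes one row per (trajectory, time) with columns `compound`,
#' `dose_index`, `time_h`, `O`, `Psi`, `y`, `effective_concentration`.
#'
#' @param trajectories list of [Trajectory-class] objects.
#' @param path output CSV path.
#' @param compound compound label(s), recycled over trajectories.
#' @param doseIndex dose index(es), recycled over trajectories.
#' @return the path, invisibly.
#' @export
exportTrajectories <- function(trajectories, path, compound,
                               doseIndex) {
  compound <- rep_len(compound, length(trajectories))
  doseIndex <- rep_len(doseIndex, length(trajectories))
  rows <- lapply(seq_along(trajectories), function(i) {
    d <- as.data.frame(trajectories[[i]])
    cbind(compound = compound[i], dose_index = doseIndex[i], d)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

setMethod("show", "Trajectory", function(object) {
  cat(sprintf("Trajectory: %d time points over [%.3g, %.3g] h\n",
              length(object@times), min(object@times),
              max(object@times)))
  cat(sprintf("  y range [%.4g, %.4g]; sensitivities: %d parameter(s)\n",
              min(object@y), max(object@y), ncol(object@sens)))
})
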