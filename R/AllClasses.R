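#' @import methods
NULL

#' Model parameters for the oxygen/MMP kinetic model
#'
#' Container for all rate, affinity, scaling and pharmacokinetic
#' constants of the two-state oxygen/MMP model and its extensions, for
#' one compound. Construct with [modelParameters()].
#'
#' @slot supply oxygen supply rate (a.u./h); fixed at 0.6 by default.
#' @slot KE maximal oxygen consumption rate (a.u.).
#' @slot KEi half-inhibition concentration of an ETC inhibitor (uM).
#' @slot Cf scaling from oxygen consumption rate to proton flux (a.u.).
#' @slot VA maximal ATP-synthesis-driven MMP depletion rate (a.u.).
#' @slot KA MMP at which ATP synthesis is half-maximal (a.u.).
#' @slot KAi half-inhibition concentration of an ATP-synthase
#'   inhibitor (uM).
#' @slot VU maximal uncoupler-mediated proton flux; fixed at 1.
#' @slot KU uncoupler half-maximal concentration; fixed at 1.
#' @slot r dimensionless time-scale factor multiplying both
#'   right-hand sides.
#' @slot c1,c0 linear observation scaling mapping MMP to normalized
#'   dye intensity.
#' @slot alpha ion-leakage rate (1/h); used by the leakage variant only.
#' @slot gamma pharmacokinetic decay rate (1/h).
#' @slot gammaL,gammaH decay rates for the low/high dose blocks of the
#'   concentration-dependent decay variant (1/h).
#' @slot D0 effective applied-dose concentrations, ascending dose
#'   index (uM).
#'
#' @seealso [steadyState()], [simulateTrajectory()]
#' @export
setClass("ModelParameters",
  representation(
    supply = "numeric", KE = "numeric", KEi = "numeric", Cf = "numeric",
    VA = "numeric", KA = "numeric", KAi = "numeric",
    VU = "numeric", KU = "numeric", r = "numeric",
    c1 = "numeric", c0 = "numeric",
    alpha = "numeric", gamma = "numeric",
    gammaL = "numeric", gammaH = "numeric",
    D0 = "numeric"
  )
)

setValidity("ModelParameters", function(object) {
  msg <- character()
  sc <- c("supply", "KE", "KEi", "Cf", "VA", "KA", "KAi", "VU", "KU",
          "r", "c1", "c0", "alpha", "gamma", "gammaL", "gammaH")
  for (s in sc) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v))
      msg <- c(msg, sprintf("'%s' must be a finite scalar", s))
  }
  if (length(msg)) return(msg)
  pos <- c("KE", "KEi", "Cf", "VA", "KA", "KAi", "VU", "KU", "r", "c1")
  for (s in pos) if (slot(object, s) <= 0)
    msg <- c(msg, sprintf("'%s' must be > 0", s))
  for (s in c("alpha", "gamma", "gammaL", "gammaH"))
    if (slot(object, s) < 0)
      msg <- c(msg, sprintf("'%s' must be >= 0", s))
  if (any(!is.finite(object@D0)) || any(object@D0 < 0))
    msg <- c(msg, "all 'D0' entries must be finite and >= 0")
  if (object@VA <= object@supply * object@Cf)
    msg <- c(msg,
      "'VA' must exceed supply*Cf (positive MMP steady state)")
  if (length(msg)) msg else TRUE
})

#' Model variant descriptor
#'
#' Identifies which right-hand side and pharmacokinetic structure a
#' simulation or fit uses, and which dose term the compound acts on.
#' The leakage and concentration-dependent-decay variants are only
#' admitted for ATP-synthase inhibitors (oligomycin-style compounds).
#'
#' @slot name one of `"basic"`, `"pk_decay"`, `"pk_decay_leakage"`,
#'   `"conc_dep_decay"`.
#' @slot targetClass one of `"etc_inhibitor"`,
#'   `"atp_synthase_inhibitor"`, `"uncoupler"`.
#' @slot lowBlock integer dose indices forming the "low" block of the
#'   concentration-dependent decay variant (default 1:4).
#'
#' @export
setClass("ModelVariant",
  representation(name = "character", targetClass = "character",
                 lowBlock = "integer")
)

setValidity("ModelVariant", function(object) {
  msg <- character()
  vn <- c("basic", "pk_decay", "pk_decay_leakage", "conc_dep_decay")
  tc <- c("etc_inhibitor", "atp_synthase_inhibitor", "uncoupler")
  if (length(object@name) != 1L || !object@name %in% vn)
    msg <- c(msg, paste0("'name' must be one of: ",
                         paste(vn, collapse = ", ")))
  if (length(object@targetClass) != 1L || !object@targetClass %in% tc)
    msg <- c(msg, paste0("'targetClass' must be one of: ",
                         paste(tc, collapse = ", ")))
  if (!length(msg) &&
      object@name %in% c("pk_decay_leakage", "conc_dep_decay") &&
      object@targetClass != "atp_synthase_inhibitor")
    msg <- c(msg, sprintf(
      "variant '%s' is only admitted with targetClass 'atp_synthase_inhibitor'",
      object@name))
  if (any(object@lowBlock < 1L))
    msg <- c(msg, "'lowBlock' indices must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Simulated trajectory of the oxygen/MMP system
#'
#' @slot times time grid (hours).
#' @slot O oxygen series (a.u.).
#' @slot Psi MMP series (a.u.).
#' @slot y observed series, `c1 * Psi + c0`.
#' @slot dose effective-concentration series for the simulated dose.
#' @slot sens matrix of sensitivities dy/dtheta (times x parameters);
#'   zero columns for parameters the condition is insensitive to.
#'
#' @export
setClass("Trajectory",
  representation(times = "numeric", O = "numeric", Psi = "numeric",
                 y = "numeric", dose = "numeric", sens = "matrix")
)

setValidity("Trajectory", function(object) {
  n <- length(object@times)
  if (length(object@O) != n || length(object@Psi) != n ||
      length(object@y) != n || length(object@dose) != n)
    return("all series must share the length of 'times'")
  if (is.unsorted(object@times, strictly = TRUE))
    return("'times' must be strictly ascending")
  TRUE
})

#' DMSO-normalized condition trajectories
#'
#' One row per compound x concentration x time point, carrying the
#' across-replicate mean and standard error of the vehicle-normalized
#' intensity. Construct with [conditionSet()] or [preprocessCells()].
#'
#' @slot data data.frame with columns `compound`, `concentration`,
#'   `time_h`, `mean_norm`, `se_norm`, `n_rep`.
#'
#' @export
setClass("ConditionSet", representation(data = "data.frame"))

setValidity("ConditionSet", function(object) {
  need <- c("compound", "concentration", "time_h", "mean_norm",
            "se_norm", "n_rep")
  miss <- setdiff(need, names(object@data))
  if (length(miss))
    return(paste("missing columns:", paste(miss, collapse = ", ")))
  d <- object@data
  ok <- is.finite(d$se_norm)
  if (any(d$se_norm[ok] < 0)) return("'se_norm' must be >= 0")
  if (any(d$n_rep < 1)) return("'n_rep' must be >= 1")
  TRUE
})

#' Calibration problem definition
#'
#' Bundles the data, model variant, base parameter values, free
#' parameters with bounds, and multistart settings for one compound.
#' Construct with [fitProblem()].
#'
#' @slot data a [ConditionSet-class] restricted to one compound.
#' @slot variant a [ModelVariant-class].
#' @slot params a [ModelParameters-class] holding fixed values and
#'   nominal values for the free parameters.
#' @slot free data.frame with columns `name`, `lower`, `upper`.
#' @slot compound compound name fitted by this problem.
#' @slot nStarts number of multistart initializations.
#' @slot seed RNG seed for start sampling.
#' @slot sigmaFloor floor on the weighting SE, as a fraction of the
#'   condition mean signal, applied where the SE is zero or missing.
#'
#' @export
setClass("FitProblem",
  representation(data = "ConditionSet", variant = "ModelVariant",
                 params = "ModelParameters", free = "data.frame",
                 compound = "character", nStarts = "integer",
                 seed = "integer", sigmaFloor = "numeric")
)

setValidity("FitProblem", function(object) {
  msg <- character()
  if (nrow(object@free) == 0L) msg <- c(msg, "'free' must be non-empty")
  if (!all(c("name", "lower", "upper") %in% names(object@free)))
    msg <- c(msg, "'free' needs columns name, lower, upper")
  else {
    bad <- !is.finite(object@free$lower) | !is.finite(object@free$upper) |
      object@free$lower >= object@free$upper
    if (any(bad))
      msg <- c(msg, "bounds must be finite with lower < upper")
  }
  cmp <- unique(object@data@data$compound)
  if (length(object@compound) != 1L || !object@compound %in% cmp)
    msg <- c(msg, "'compound' must name a compound present in 'data'")
  if (object@nStarts < 1L) msg <- c(msg, "'nStarts' must be >= 1")
  if (object@sigmaFloor <= 0) msg <- c(msg, "'sigmaFloor' must be > 0")
  if (length(msg)) msg else TRUE
})

#' Result of a maximum-likelihood fit
#'
#' @slot theta named vector of best-fit free parameter values.
#' @slot params updated parameter object(s): a
#'   [ModelParameters-class] for a single-compound fit, a named list
#'   of them for a joint fit.
#' @slot cost negative log-likelihood at the optimum (half the total
#'   weighted SSR).
#' @slot perConditionSSR weighted SSR per condition (and per compound
#'   for joint fits).
#' @slot startTrace data.frame of (start, cost, converged) over the
#'   multistart runs.
#' @slot converged whether the reported optimum converged.
#' @slot seed RNG seed used for start sampling.
#' @slot candidates list of distinct leading optima (named theta
#'   vectors) found by the multistart; profile likelihoods use them as
#'   additional warm starts so that compensating parameter movements
#'   across distant basins are tracked.
#'
#' @export
setClass("FitResult",
  representation(theta = "numeric", params = "ANY", cost = "numeric",
                 perConditionSSR = "numeric", startTrace = "data.frame",
                 converged = "logical", seed = "integer",
                 candidates = "list")
)

setValidity("FitResult", function(object) {
  if (length(object@cost) != 1L || !is.finite(object@cost))
    return("'cost' must be a finite scalar")
  if (nrow(object@startTrace)) {
    cs <- object@startTrace$cost
    if (min(cs, na.rm = TRUE) < object@cost - 1e-6)
      return("'cost' must be the minimum over the start trace")
  }
  TRUE
})

#' Profile-likelihood curve
#'
#' @slot name profiled parameter or derived-quantity label.
#' @slot grid profiled values.
#' @slot npl re-optimized negative profile likelihood (2 x cost) on
#'   the grid.
#' @slot threshold chi-square cut Delta above min(NPL).
#' @slot ciLow,ciHigh confidence bounds (may be -Inf/Inf when the
#'   curve never crosses on that side).
#' @slot identifiable TRUE when both sides cross the threshold.
#' @slot mle maximum-likelihood value of the profiled quantity.
#' @slot nplMin minimum NPL (2 x best cost).
#'
#' @export
setClass("ProfileCurve",
  representation(name = "character", grid = "numeric", npl = "numeric",
                 threshold = "numeric", ciLow = "numeric",
                 ciHigh = "numeric", identifiable = "logical",
                 mle = "numeric", nplMin = "numeric")
)

setValidity("ProfileCurve", function(object) {
  if (length(object@grid) != length(object@npl))
    return("'grid' and 'npl' must have equal length")
  if (length(object@npl) &&
      min(object@npl, na.rm = TRUE) < object@nplMin - 1e-6)
    return("NPL values must not undercut the reported minimum")
  TRUE
})

#' Two-level bootstrap result
#'
#' @slot estimates data.frame of refitted free-parameter estimates,
#'   one row per bootstrap sample.
#' @slot ci95,ci99 matrices (2 x parameters) of quantile confidence
#'   bounds.
#' @slot nBoot number of bootstrap samples.
#' @slot nFailed number of redrawn samples whose refit failed.
#' @slot seed RNG seed.
#'
#' @export
setClass("BootstrapResult",
  representation(estimates = "data.frame", ci95 = "matrix",
                 ci99 = "matrix", nBoot = "integer", nFailed = "integer",
                 seed = "integer")
)

setValidity("BootstrapResult", function(object) {
  if (nrow(object@estimates) != object@nBoot)
    return("'estimates' must have one row per bootstrap sample")
  if (ncol(object@ci95) != ncol(object@estimates) ||
      ncol(object@ci99) != ncol(object@estimates))
    return("CI matrices must cover every estimated parameter")
  wide <- object@ci99[1, ] <= object@ci95[1, ] + 1e-12 &
          object@ci99[2, ] >= object@ci95[2, ] - 1e-12
  if (!all(wide)) return("99% CI must contain the 95% CI")
  TRUE
})

#' Synthetic experiment design
#'
#' Describes a multi-plate live-cell imaging study: compounds with
#' their true model parameters and applied concentrations, plate and
#' technical replicate structure, cell counts, noise and drift.
#' Construct with [experimentDesign()].
#'
#' @slot compounds list; each element a list with entries `name`,
#'   `variant` ([ModelVariant-class]), `params`
#'   ([ModelParameters-class]) and `concentrations` (ascending).
#' @slot nPlates number of biological replicates (one per plate).
#' @slot nTechReps technical replicate wells per condition per plate.
#' @slot cellsPerWell mean cell count per well (negative binomial).
#' @slot cellsDispersion negative-binomial size parameter.
#' @slot times measurement grid (hours).
#' @slot sigmaCell log-scale SD of per-cell intensities.
#' @slot driftInterceptSD SD of the per-plate log drift intercept.
#' @slot driftSlopeSD SD of the per-plate log-linear drift slope
#'   (1/h).
#' @slot plateJitterSD log-scale SD of the per-plate, per-compound
#'   scale jitter applied to treated wells.
#' @slot controlWells vehicle-control wells per plate.
#'
#' @export
setClass("ExperimentDesign",
  representation(compounds = "list", nPlates = "integer",
                 nTechReps = "integer", cellsPerWell = "numeric",
                 cellsDispersion = "numeric", times = "numeric",
                 sigmaCell = "numeric", driftInterceptSD = "numeric",
                 driftSlopeSD = "numeric",
                 plateJitterSD = "numeric", controlWells = "integer")
)

setValidity("ExperimentDesign", function(object) {
  msg <- character()
  if (!length(object@compounds)) msg <- c(msg, "no compounds")
  for (cc in object@compounds) {
    if (!all(c("name", "variant", "params", "concentrations") %in%
             names(cc))) {
      msg <- c(msg, "each compound needs name/variant/params/concentrations")
      next
    }
    if (is.unsorted(cc$concentrations, strictly = TRUE))
      msg <- c(msg, sprintf("concentrations for '%s' must be strictly ascending",
                            cc$name))
    if (length(cc$params@D0) != length(cc$concentrations))
      msg <- c(msg, sprintf("'%s': D0 must match the concentration count",
                            cc$name))
  }
  if (object@nPlates < 1L || object@nTechReps < 1L ||
      object@controlWells < 1L)
    msg <- c(msg, "plate/replicate/control counts must be >= 1")
  if (object@cellsPerWell < 1) msg <- c(msg, "'cellsPerWell' must be >= 1")
  if (object@sigmaCell < 0) msg <- c(msg, "'sigmaCell' must be >= 0")
  if (length(msg)) msg else TRUE
})
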