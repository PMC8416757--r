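#' Profile-likelihood threshold
#'
#' The NPL cut above its minimum defining a confidence interval: the
#' chi-square quantile at the given confidence level with one degree
#' of freedom.
#'
#' @param confidence confidence level in (0, 1).
#' @return the threshold Delta.
#' @examples
#' plThreshold(0.95)  # 3.8415
#' @export
plThreshold <- function(confidence) {
  if (!is.numeric(confidence) || any(confidence <= 0) ||
      any(confidence >= 1))
    stop("'confidence' must lie strictly between 0 and 1")
  qchisq(confidence, df = 1)
}

## Robust re-optimization with parameters pinned: descend from every
## supplied warm start, and when the result would put the point above
## the threshold, confirm with a small multistart of the reduced
## problem -- a single warm descent can fail to track compensating
## parameter movements across valleys, which would fake a likelihood
## rise and hence fake identifiability.
.refitRobust <- function(problem, fix, warms, nplRef = NULL,
                         threshold = NULL) {
  best <- NULL
  for (w in warms) {
    r <- .refitFixed(problem, fix, w)
    if (is.finite(r$npl) && (is.null(best) || r$npl < best$npl))
      best <- r
  }
  if (is.null(best)) return(list(npl = NA_real_, theta = warms[[1]]))
  if (!is.null(nplRef) && is.finite(best$npl) &&
      best$npl > nplRef + threshold &&
      sum(!problem@free$name %in% names(fix)) > 0L) {
    pr <- problem
    pr@params <- applyTheta(problem@params, fix)
    pr@free <- problem@free[!problem@free$name %in% names(fix), ,
                            drop = FALSE]
    pr@nStarts <- 8L
    pr@seed <- problem@seed + 7L
    ms <- tryCatch(
      suppressWarnings(fitMultistart(pr, explIter = 150L,
                                     polish = FALSE)),
      error = function(e) NULL)
    if (!is.null(ms) && is.finite(ms@cost) && 2 * ms@cost < best$npl)
      best <- list(npl = 2 * ms@cost, theta = c(ms@theta, fix))
  }
  best
}

## Re-optimize a problem with some parameters pinned; warm start from
## 'warm'. Returns list(npl, theta) or npl = NA on failure.
.refitFixed <- function(problem, fix, warm) {
  pr <- problem
  pr@params <- applyTheta(problem@params, fix)
  keep <- !problem@free$name %in% names(fix)
  pr@free <- problem@free[keep, , drop = FALSE]
  if (!nrow(pr@free)) {
    cost <- totalCost(setNames(numeric(0), character(0)), pr)
    return(list(npl = 2 * cost, theta = fix))
  }
  warm <- pmin(pmax(warm[pr@free$name], pr@free$lower), pr@free$upper)
  run <- tryCatch(.runStart(warm, pr, control = .lmControl(80L)),
                  error = function(e) NULL)
  if (is.null(run) || !is.finite(run$cost))
    return(list(npl = NA_real_, theta = warm))
  list(npl = 2 * run$cost, theta = c(run$theta, fix))
}

## Adaptive outward walk from the MLE: multiplicative steps for
## positive values, additive otherwise; stops 2 points after the
## threshold crossing, at the hard range, or at maxPoints per side.
.profileWalk <- function(v0, npl0, theta0, refit, threshold,
                         stepFactor, hardRange, maxPoints) {
  onePoint <- function(v, warm) refit(v, warm)
  side <- function(dir) {
    vs <- numeric(0); npls <- numeric(0)
    warm <- theta0; extra <- 0L
    addStep <- max(abs(v0), 0.05) * (stepFactor - 1)
    for (k in seq_len(maxPoints)) {
      v <- if (v0 > 0) v0 * stepFactor^(dir * k)
           else v0 + dir * k * addStep
      if (v < hardRange[1] || v > hardRange[2]) break
      res <- onePoint(v, warm)
      vs <- c(vs, v); npls <- c(npls, res$npl)
      if (is.finite(res$npl)) {
        warm <- res$theta
        if (res$npl > npl0 + threshold) {
          extra <- extra + 1L
          if (extra > 2L) break
        } else extra <- 0L
      }
    }
    list(v = vs, npl = npls)
  }
  lo <- side(-1); hi <- side(1)
  ord <- order(c(lo$v, v0, hi$v))
  list(grid = c(lo$v, v0, hi$v)[ord],
       npl = c(lo$npl, npl0, hi$npl)[ord])
}

## Interpolation of the threshold crossing nearest the MLE on each
## side; +/-Inf when a side never crosses. Interpolation is linear in
## sqrt(NPL - min), which is exact when the NPL is locally quadratic.
.profileCI <- function(grid, npl, v0, cut) {
  ok <- is.finite(npl)
  g <- grid[ok]; n <- npl[ok]
  nplMin <- min(n)
  s <- sqrt(pmax(n - nplMin, 0))
  sCut <- sqrt(max(cut - nplMin, 0))
  below <- n <= cut
  interp <- function(i, j) {
    if (abs(s[j] - s[i]) < 1e-300) return(g[j])
    g[i] + (g[j] - g[i]) * (sCut - s[i]) / (s[j] - s[i])
  }
  lo <- -Inf; hi <- Inf
  left <- which(g < v0); right <- which(g > v0)
  if (length(left)) {
    for (i in rev(left)) {
      if (!below[i]) {
        lo <- interp(i + 1, i)
        break
      }
    }
  }
  if (length(right)) {
    for (i in right) {
      if (!below[i]) {
        hi <- interp(i - 1, i)
        break
      }
    }
  }
  c(lo, hi)
}

#' Profile likelihood of a single model parameter
#'
#' Fixes the named parameter on an adaptive grid walked outward from
#' the MLE (multiplicative steps, warm-started re-optimization of all
#' remaining free parameters at each point), producing the NPL curve,
#' the threshold-crossing confidence interval by linear interpolation,
#' and a structural-identifiability flag: when the curve never rises
#' above `min(NPL) + Delta` on one side within the search range, the
#' parameter is flagged non-identifiable and that bound is open.
#'
#' @param problem a [FitProblem-class].
#' @param name free parameter to profile.
#' @param fit optional [FitResult-class] MLE (computed via
#'   [fitMultistart()] when missing).
#' @param confidence confidence level of the interval.
#' @param stepFactor multiplicative step of the outward walk.
#' @param maxDecades hard search range, in decades around the MLE.
#' @param maxPoints maximum grid points per side.
#' @return a [ProfileCurve-class].
#' @export
profileParameter <- function(problem, name, fit = NULL,
                             confidence = 0.95, stepFactor = 1.3,
                             maxDecades = 6, maxPoints = 60L) {
  if (!name %in% problem@free$name)
    stop("'", name, "' is not a free parameter of the problem")
  if (is.null(fit)) fit <- fitMultistart(problem)
  v0 <- fit@theta[[name]]
  npl0 <- 2 * fit@cost
  thr <- plThreshold(confidence)
  hardRange <- if (v0 > 0) c(v0 * 10^-maxDecades, v0 * 10^maxDecades)
               else c(-Inf, Inf)
  refit <- function(v, warm)
    .refitRobust(problem, setNames(v, name),
                 warms = c(list(warm), fit@candidates),
                 nplRef = npl0, threshold = thr)
  walk <- .profileWalk(v0, npl0, fit@theta, refit, thr, stepFactor,
                       hardRange, maxPoints)
  nplMin <- min(c(npl0, walk$npl), na.rm = TRUE)
  ci <- .profileCI(walk$grid, walk$npl, v0, nplMin + thr)
  new("ProfileCurve", name = name, grid = walk$grid, npl = walk$npl,
      threshold = thr, ciLow = ci[1], ciHigh = ci[2],
      identifiable = is.finite(ci[1]) && is.finite(ci[2]),
      mle = v0, nplMin = nplMin)
}

#' Describe a derived quantity for profiling
#'
#' Helper constructing the quantity descriptor used by
#' [profileDerived()]: a function of the free parameters plus,
#' optionally, an inverse substituting the quantity's value back into
#' one parameter (the efficient profiling route for monotone
#' one-parameter quantities).
#'
#' @param name label for the quantity.
#' @param fn function mapping a named theta vector to the quantity.
#' @param invert optional function `(value, theta)` returning a named
#'   vector of parameter values to pin so that the quantity equals
#'   `value`.
#' @return a list understood by [profileDerived()].
#' @export
derivedQuantity <- function(name, fn, invert = NULL) {
  list(name = name, fn = fn, invert = invert)
}

#' Pharmacokinetic concentration ratio as a derived quantity
#'
#' The model predicts `R_T2/T1 = exp(-gamma (T2 - T1))` for the ratio
#' of effective concentrations at two sampling times; this builds the
#' corresponding [derivedQuantity()] over the decay-rate parameter.
#'
#' @param T1,T2 sampling times (hours), `T2 >= T1`.
#' @param param name of the decay-rate parameter (default
#'   `"gamma"`).
#' @return a derived-quantity descriptor.
#' @export
ratioQuantity <- function(T1, T2, param = "gamma") {
  stopifnot(T2 >= T1, T1 >= 0)
  derivedQuantity(
    name = sprintf("R_%g/%g", T2, T1),
    fn = function(theta) exp(-theta[[param]] * (T2 - T1)),
    invert = function(value, theta)
      setNames(-log(value) / (T2 - T1), param))
}

#' Profile likelihood of a derived quantity
#'
#' Exploits the invariance of maximum likelihood: the confidence
#' interval of any smooth function of the parameters can be profiled
#' directly. When the quantity has a declared inverse in one parameter
#' the profile is computed by substitution (fix that parameter at the
#' value reproducing the quantity); otherwise a quadratic-penalty
#' constraint with escalating weight is used.
#'
#' @inheritParams profileParameter
#' @param quantity a [derivedQuantity()] descriptor.
#' @return a [ProfileCurve-class] over the quantity's value.
#' @export
profileDerived <- function(problem, quantity, fit = NULL,
                           confidence = 0.95, stepFactor = 1.3,
                           maxDecades = 6, maxPoints = 60L) {
  if (is.null(fit)) fit <- fitMultistart(problem)
  v0 <- quantity$fn(fit@theta)
  npl0 <- 2 * fit@cost
  thr <- plThreshold(confidence)

  ## degenerate (constant) quantities cannot be profiled
  probe <- vapply(seq_along(fit@theta), function(j) {
    th <- fit@theta
    th[j] <- th[j] + max(abs(th[j]), 1e-3) * 1e-4
    quantity$fn(th)
  }, numeric(1))
  if (all(abs(probe - v0) < 1e-12 * max(1, abs(v0)))) {
    warning("derived quantity is constant in the free parameters; ",
            "profile is degenerate")
    return(new("ProfileCurve", name = quantity$name, grid = v0,
               npl = npl0, threshold = thr, ciLow = -Inf,
               ciHigh = Inf, identifiable = FALSE, mle = v0,
               nplMin = npl0))
  }

  refit <- if (!is.null(quantity$invert)) {
    function(v, warm)
      .refitRobust(problem, quantity$invert(v, fit@theta),
                   warms = c(list(warm), fit@candidates),
                   nplRef = npl0, threshold = thr)
  } else {
    function(v, warm) .refitPenalty(problem, quantity, v, warm)
  }
  hardRange <- if (v0 > 0) c(v0 * 10^-maxDecades, v0 * 10^maxDecades)
               else c(-Inf, Inf)
  walk <- .profileWalk(v0, npl0, fit@theta, refit, thr, stepFactor,
                       hardRange, maxPoints)
  nplMin <- min(c(npl0, walk$npl), na.rm = TRUE)
  ci <- .profileCI(walk$grid, walk$npl, v0, nplMin + thr)
  new("ProfileCurve", name = quantity$name, grid = walk$grid,
      npl = walk$npl, threshold = thr, ciLow = ci[1], ciHigh = ci[2],
      identifiable = is.finite(ci[1]) && is.finite(ci[2]),
      mle = v0, nplMin = nplMin)
}

## Quadratic-penalty constrained re-optimization for derived
## quantities without a declared inverse: escalate the penalty weight
## until the constraint holds to 1e-4 relative.
.refitPenalty <- function(problem, quantity, value, warm) {
  conds <- .problemConditions(problem)
  freeN <- problem@free$name
  warm <- pmin(pmax(warm[freeN], problem@free$lower),
               problem@free$upper)
  qgrad <- function(th) {
    vapply(seq_along(th), function(j) {
      h <- max(abs(th[j]), 1e-3) * 1e-6
      tp <- th; tp[j] <- tp[j] + h
      tm <- th; tm[j] <- tm[j] - h
      (quantity$fn(tp) - quantity$fn(tm)) / (2 * h)
    }, numeric(1))
  }
  th <- warm
  for (w in c(1e2, 1e4, 1e6)) {
    sw <- sqrt(w)
    fn <- function(t2)
      c(.residJac(t2, problem, jac = FALSE, conds = conds),
        sw * (quantity$fn(t2) - value))
    jf <- function(t2)
      rbind(.residJac(t2, problem, jac = TRUE, conds = conds)$J,
            sw * qgrad(t2))
    run <- .boundedLM(th, problem@free$lower, problem@free$upper,
                      freeN, fn, jf, control = .lmControl(80L))
    if (!is.finite(run$cost)) return(list(npl = NA_real_, theta = warm))
    th <- run$theta
    if (abs(quantity$fn(th) - value) <= 1e-4 * max(1, abs(value)))
      break
  }
  r <- .residJac(th, problem, jac = FALSE, conds = conds)
  list(npl = sum(r^2), theta = th)
}

#' Predicted effective-concentration ratio between two times
#'
#' Under exponential pharmacokinetic decay the ratio of effective
#' concentrations at two times is `exp(-gamma (T2 - T1))`,
#' independent of the applied dose. The default sampling pairs used in
#' compound-level measurements are (2, 8), (2, 24) and (8, 24) hours.
#'
#' @param gamma decay rate (1/h).
#' @param T1,T2 times (hours) with `T2 >= T1 >= 0`.
#' @return the predicted ratio.
#' @examples
#' predictRatio(0.1, 2, 24)  # exp(-2.2)
#' @export
predictRatio <- function(gamma, T1, T2) {
  if (any(T2 < T1)) stop("'T2' must be >= 'T1'")
  if (any(T1 < 0)) stop("times must be non-negative")
  stopifnot(all(gamma >= 0))
  exp(-gamma * (T2 - T1))
}

## Precompute per-(plate, condition, time) pooled log-intensity
## vectors for fast hierarchical resampling. Technical replicate
## wells are pooled here, mirroring preprocessCells().
.bootPools <- function(cells, compound) {
  .checkCellTable(cells)
  keep <- is.finite(cells$intensity) & cells$intensity > 0 &
    (cells$is_control | cells$compound == compound)
  cells <- cells[keep, , drop = FALSE]
  logI <- log(cells$intensity)
  plates <- sort(unique(cells$plate_id))
  times <- sort(unique(cells$time_h))
  concs <- sort(unique(cells$concentration[!cells$is_control]))
  key <- paste(cells$plate_id,
               ifelse(cells$is_control, "CTRL", cells$concentration),
               cells$time_h, sep = "\r")
  pools <- split(logI, key)
  list(pools = pools, plates = plates, times = times, concs = concs)
}

## One hierarchical bootstrap draw -> ConditionSet (fast path of the
## generate -> preprocess chain on resampled cells).
.bootResample <- function(bp, compound) {
  nP <- length(bp$plates)
  sel <- sample(bp$plates, nP, replace = TRUE)
  nT <- length(bp$times); nC <- length(bp$concs)
  norm <- array(NA_real_, dim = c(nP, nC, nT))
  for (p in seq_len(nP)) {
    plate <- sel[p]
    ctrl <- vapply(bp$times, function(t) {
      v <- bp$pools[[paste(plate, "CTRL", t, sep = "\r")]]
      mean(sample(v, length(v), replace = TRUE))
    }, numeric(1))
    for (ci in seq_len(nC)) {
      tr <- vapply(bp$times, function(t) {
        v <- bp$pools[[paste(plate, bp$concs[ci], t, sep = "\r")]]
        mean(sample(v, length(v), replace = TRUE))
      }, numeric(1))
      norm[p, ci, ] <- exp(tr - ctrl)
    }
  }
  m <- apply(norm, c(2, 3), mean)
  se <- apply(norm, c(2, 3), sd) / sqrt(nP)
  conditionSet(data.frame(
    compound = compound,
    concentration = rep(bp$concs, times = nT),
    time_h = rep(bp$times, each = nC),
    mean_norm = as.vector(m), se_norm = as.vector(se),
    n_rep = nP, stringsAsFactors = FALSE))
}

#' Two-level (inter/intra-plate) bootstrap confidence intervals
#'
#' For each bootstrap sample: plates (biological replicates) are
#' resampled with replacement to their original count; within each
#' selected plate, the single-cell objects pooled across technical
#' replicate wells are resampled with replacement to their original
#' count for every condition and time point (vehicle controls
#' included); the resampled cells are pushed through the
#' quantification chain (geometric means, control normalization,
#' replicate mean and SE); and the model is refitted warm-started at
#' the original MLE. Confidence intervals are sample quantiles (order
#' statistics) of the refitted estimates at 95% and 99%.
#'
#' @param cells single-cell table ([preprocessCells()] layout)
#'   containing the plate structure.
#' @param problem the [FitProblem-class] used for the original fit.
#' @param fit the original [FitResult-class] (its `theta` is the warm
#'   start).
#' @param nBoot number of bootstrap samples.
#' @param seed RNG seed.
#' @param multistart use full multistart for each refit instead of
#'   the warm start only (slow; for robustness studies).
#' @return a [BootstrapResult-class].
#' @export
bootstrapCI <- function(cells, problem, fit, nBoot = 200L, seed = 1L,
                        multistart = FALSE) {
  set.seed(seed)
  bp <- .bootPools(cells, problem@compound)
  est <- vector("list", nBoot)
  nFailed <- 0L; b <- 0L; attempts <- 0L
  while (b < nBoot && attempts < 2L * nBoot) {
    attempts <- attempts + 1L
    cs <- .bootResample(bp, problem@compound)
    pr <- problem
    pr@data <- cs
    run <- if (multistart) {
      f <- tryCatch(fitMultistart(pr), error = function(e) NULL)
      if (is.null(f)) NULL else list(theta = f@theta, cost = f@cost,
                                     converged = f@converged)
    } else {
      ## bootstrap refits need quantile-level precision only
      ctrl <- minpack.lm::nls.lm.control(ftol = 1e-8, ptol = 1e-8,
                                         gtol = 0, maxiter = 40L)
      tryCatch(.runStart(fit@theta, pr, control = ctrl),
               error = function(e) NULL)
    }
    if (is.null(run) || !is.finite(run$cost)) {
      nFailed <- nFailed + 1L
      next
    }
    b <- b + 1L
    est[[b]] <- run$theta
  }
  if (b < nBoot)
    stop("bootstrap refits failed too often (", nFailed, " failures)")
  estimates <- as.data.frame(do.call(rbind, est))
  ci95 <- apply(estimates, 2, quantile, probs = c(0.025, 0.975),
                type = 1)
  ci99 <- apply(estimates, 2, quantile, probs = c(0.005, 0.995),
                type = 1)
  new("BootstrapResult", estimates = estimates, ci95 = ci95,
      ci99 = ci99, nBoot = as.integer(nBoot),
      nFailed = as.integer(nFailed), seed = as.integer(seed))
}

#' Compare model-predicted ratios with measured ratios
#'
#' Reports externally measured per-replicate concentration ratios
#' against the model prediction and its profile-likelihood and
#' bootstrap confidence intervals, flagging whether the measured mean
#' falls inside each available interval.
#'
#' @param prediction list with elements `ratio` (point prediction)
#'   and any of `plCI95`, `plCI99`, `bootCI95`, `bootCI99` (each
#'   `c(low, high)`).
#' @param measured numeric vector of measured per-replicate ratios
#'   (may be empty for a prediction-only report).
#' @return list with the measured values, their mean, per-interval
#'   membership flags and an overall flag: `"consistent"` (inside all
#'   available 95% intervals), `"mixed"` (inside some) or
#'   `"inconsistent"` (inside none); `"prediction_only"` without
#'   measurements.
#' @export
compareMeasuredRatios <- function(prediction, measured = numeric(0)) {
  if (length(measured) && any(measured <= 0))
    stop("measured ratios must be positive")
  inside <- function(x, ci)
    if (is.null(ci)) NA else x >= ci[1] & x <= ci[2]
  if (!length(measured))
    return(list(prediction = prediction$ratio, measured = measured,
                measuredMean = NA_real_, flags = logical(0),
                overall = "prediction_only"))
  mm <- mean(measured)
  flags <- c(pl95 = inside(mm, prediction$plCI95),
             pl99 = inside(mm, prediction$plCI99),
             boot95 = inside(mm, prediction$bootCI95),
             boot99 = inside(mm, prediction$bootCI99))
  at95 <- flags[c("pl95", "boot95")]
  at95 <- at95[!is.na(at95)]
  overall <- if (!length(at95)) "prediction_only"
             else if (all(at95)) "consistent"
             else if (any(at95)) "mixed"
             else "inconsistent"
  list(prediction = prediction$ratio, measured = measured,
       measuredMean = mm, flags = flags, overall = overall)
}

#' Confidence interval of a profile curve
#'
#' @param curve a [ProfileCurve-class].
#' @return `c(low, high)`; open ends are `-Inf`/`Inf`.
#' @export
profileCI <- function(curve) c(curve@ciLow, curve@ciHigh)

setMethod("show", "ProfileCurve", function(object) {
  cat(sprintf("ProfileCurve '%s': %d points, MLE %.4g\n", object@name,
              length(object@grid), object@mle))
  cat(sprintf("  %s; CI [%.4g, %.4g] at Delta = %.3f\n",
              if (object@identifiable) "identifiable"
              else "NOT identifiable within search range",
              object@ciLow, object@ciHigh, object@threshold))
})

setMethod("show", "BootstrapResult", function(object) {
  cat(sprintf("BootstrapResult: %d samples (%d failed redraws)\n",
              object@nBoot, object@nFailed))
  for (nm in colnames(object@ci95))
    cat(sprintf("  %s: 95%% [%.4g, %.4g], 99%% [%.4g, %.4g]\n", nm,
                object@ci95[1, nm], object@ci95[2, nm],
                object@ci99[1, nm], object@ci99[2, nm]))
})
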