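#' Weighted sum of squared residuals for one condition
#'
#' `sum((y_model - y_data)^2 / sigma^2)` over the time points of one
#' compound x concentration condition; the building block of the
#' negative log-likelihood.
#'
#' @param yModel,yData model output and observed normalized intensity
#'   on the same grid.
#' @param sigma per-time-point standard errors (post-floor, > 0).
#' @return the weighted SSR.
#' @export
weightedSSR <- function(yModel, yData, sigma) {
  if (length(yModel) != length(yData) || length(yData) != length(sigma))
    stop("series lengths differ")
  if (any(!is.finite(sigma)) || any(sigma <= 0))
    stop("all sigma must be positive")
  sum(((yModel - yData) / sigma)^2)
}

## Default start/bound ranges: four decades around the nominal value
## for positive parameters, a symmetric linear range for c0 (which may
## sit near zero), and wide non-negative ranges for rates whose nominal
## is zero.
.defaultBounds <- function(name, params) {
  if (name == "c0") return(c(-2, 2))
  nominal <- tryCatch(getParam(params, name), error = function(e) NA)
  bounds <- if (is.finite(nominal) && nominal > 0)
    c(nominal * 1e-2, nominal * 1e2)
  else if (name %in% c("gamma", "gammaL", "gammaH")) c(1e-4, 10)
  else if (name == "alpha") c(1e-4, 100)
  else c(1e-6, 1e3)
  ## a positive MMP steady state requires VA > supply*Cf
  if (name == "VA")
    bounds[1] <- max(bounds[1], params@supply * params@Cf * 1.02)
  bounds
}

#' Define a calibration problem for one compound
#'
#' Binds a [ConditionSet-class], a model variant, base parameter
#' values, the free parameters with bounds, and multistart settings.
#' The shorthand `"D0"` in `free` expands to one `D0[i]` per
#' concentration; when `params@D0` is empty it is initialized with the
#' compound's applied concentrations (the natural nominal scale for
#' effective concentrations).
#'
#' @param data a [ConditionSet-class] (or its data.frame).
#' @param variant a [ModelVariant-class].
#' @param params a [ModelParameters-class] of fixed and nominal values.
#' @param free character vector of free parameter names (default
#'   bounds), or data.frame with columns `name`, `lower`, `upper`.
#' @param compound compound to fit; defaults to the only compound in
#'   `data`.
#' @param nStarts multistart initializations.
#' @param seed RNG seed for start sampling.
#' @param sigmaFloor weighting floor as a fraction of the condition
#'   mean signal, applied where the SE is zero or unavailable.
#' @return a [FitProblem-class] object.
#' @export
fitProblem <- function(data, variant, params,
                       free = c("VA", "KA", "D0", "c1", "c0", "r"),
                       compound = NULL, nStarts = 100L, seed = 1L,
                       sigmaFloor = 0.05) {
  if (is.data.frame(data)) data <- conditionSet(data)
  cmp <- unique(data@data$compound)
  if (is.null(compound)) {
    if (length(cmp) != 1L)
      stop("multiple compounds in 'data'; give 'compound'")
    compound <- cmp
  }
  conc <- sort(unique(data@data$concentration[
    data@data$compound == compound]))
  if (!length(params@D0)) params@D0 <- conc
  if (length(params@D0) != length(conc))
    stop("params@D0 must have one entry per concentration")
  if (is.character(free)) {
    if ("D0" %in% free)
      free <- c(setdiff(free, "D0"),
                sprintf("D0[%d]", seq_along(conc)))
    bounds <- t(vapply(free, .defaultBounds, numeric(2),
                       params = params))
    free <- data.frame(name = free, lower = bounds[, 1],
                       upper = bounds[, 2], stringsAsFactors = FALSE)
  }
  new("FitProblem", data = data, variant = variant, params = params,
      free = free, compound = compound, nStarts = as.integer(nStarts),
      seed = as.integer(seed), sigmaFloor = sigmaFloor)
}

## Split a problem's data into per-condition blocks with floored sigma.
.problemConditions <- function(problem) {
  d <- problem@data@data
  d <- d[d$compound == problem@compound, , drop = FALSE]
  conc <- sort(unique(d$concentration))
  lapply(seq_along(conc), function(i) {
    di <- d[d$concentration == conc[i], , drop = FALSE]
    di <- di[order(di$time_h), , drop = FALSE]
    sigma <- di$se_norm
    floor <- problem@sigmaFloor * mean(abs(di$mean_norm))
    ## an SE below ~sqrt(machine eps) relative to the signal is zero up
    ## to floating rounding; treat it as unavailable
    zero <- !is.finite(sigma) |
      sigma <= 1e-7 * mean(abs(di$mean_norm))
    sigma[zero] <- floor
    list(doseIndex = i, concentration = conc[i], times = di$time_h,
         y = di$mean_norm, sigma = sigma)
  })
}

## Stacked weighted residuals (and optionally the Jacobian) for a
## named theta vector. Integration failures yield a large finite
## pseudo-residual plus a gentle pull back toward the feasible box.
.residJac <- function(theta, problem, jac = FALSE,
                      conds = .problemConditions(problem),
                      rtol = 1e-8, atol = 1e-10) {
  ntot <- sum(lengths(lapply(conds, `[[`, "times")))
  params <- applyTheta(problem@params, theta)
  freeNames <- problem@free$name
  res <- NULL; J <- NULL
  out <- tryCatch({
    blocks <- lapply(conds, function(cd) {
      if (jac) {
        tr <- .simSensRaw(problem@variant, params, cd$doseIndex,
                          cd$times, freeNames, rtol = rtol,
                          atol = atol)
        list(r = (tr$y - cd$y) / cd$sigma, J = tr$sens / cd$sigma)
      } else {
        tr <- .simRaw(problem@variant, params, cd$doseIndex,
                      cd$times, rtol = rtol, atol = atol)
        list(r = (tr$y - cd$y) / cd$sigma, J = NULL)
      }
    })
    res <- unlist(lapply(blocks, `[[`, "r"))
    if (jac) J <- do.call(rbind, lapply(blocks, `[[`, "J"))
    TRUE
  }, error = function(e) FALSE)
  if (!isTRUE(out) || any(!is.finite(res))) {
    mid <- (problem@free$lower + problem@free$upper) / 2
    span <- problem@free$upper - problem@free$lower
    reg <- sum(((unlist(theta) - mid) / span)^2)
    res <- rep(sqrt(2 * (1e10 + reg) / ntot), ntot)
    if (jac) J <- matrix(0, nrow = ntot, ncol = length(freeNames))
    attr(res, "failed") <- TRUE
  }
  if (jac) list(res = res, J = J) else res
}

#' Negative log-likelihood of a parameter vector
#'
#' `sum_j R2_j / 2` over the problem's conditions, with model outputs
#' from the simulation engine. Integration failures are mapped to a
#' large finite penalty so optimizers can back out of bad regions.
#'
#' @param theta named numeric vector covering the problem's free
#'   parameters (unnamed vectors are taken in the order of
#'   `problem@free$name`).
#' @param problem a [FitProblem-class].
#' @return the cost (half the total weighted SSR).
#' @export
totalCost <- function(theta, problem) {
  if (is.null(names(theta))) names(theta) <- problem@free$name
  r <- .residJac(theta, problem, jac = FALSE)
  sum(r^2) / 2
}

#' Per-condition weighted SSR at a parameter vector
#'
#' @inheritParams totalCost
#' @return named numeric vector of weighted SSRs, one per
#'   concentration.
#' @export
perConditionSSR <- function(theta, problem) {
  if (is.null(names(theta))) names(theta) <- problem@free$name
  params <- applyTheta(problem@params, theta)
  conds <- .problemConditions(problem)
  out <- vapply(conds, function(cd) {
    tr <- .simRaw(problem@variant, params, cd$doseIndex, cd$times)
    weightedSSR(tr$y, cd$y, cd$sigma)
  }, numeric(1))
  names(out) <- vapply(conds, function(cd)
    as.character(cd$concentration), character(1))
  out
}

## Log-uniform starts for positive-bounded parameters, linear-uniform
## otherwise (c0 and any bound spanning zero).
.sampleStarts <- function(free, n) {
  p <- nrow(free)
  m <- matrix(NA_real_, nrow = n, ncol = p,
              dimnames = list(NULL, free$name))
  for (j in seq_len(p)) {
    lo <- free$lower[j]; hi <- free$upper[j]
    m[, j] <- if (lo > 0) exp(runif(n, log(lo), log(hi)))
              else runif(n, lo, hi)
  }
  m
}

.lmControl <- function(maxiter = 200L)
  minpack.lm::nls.lm.control(ftol = 1e-10, ptol = 1e-10, gtol = 1e-10,
                             maxiter = maxiter)

## Bounded Levenberg-Marquardt descent. Strictly positive-bounded
## parameters are optimized on the log scale (relative steps), which
## conditions the rate/affinity/concentration directions much better
## than linear stepping; residFn/jacFn always see the natural scale.
.boundedLM <- function(par, lower, upper, names, residFn, jacFn,
                       control = .lmControl()) {
  lg <- lower > 0
  fwd <- function(x) { x[lg] <- log(x[lg]); x }
  bwd <- function(x) { x[lg] <- exp(x[lg]); x }
  fn <- function(ph) residFn(setNames(bwd(ph), names))
  jf <- function(ph) {
    th <- bwd(ph)
    J <- jacFn(setNames(th, names))
    if (any(lg))
      J[, lg] <- sweep(J[, lg, drop = FALSE], 2, th[lg], `*`)
    J
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = fwd(par), lower = fwd(lower),
                       upper = fwd(upper), fn = fn, jac = jf,
                       control = control),
    error = function(e) NULL)
  if (is.null(fit))
    return(list(theta = setNames(par, names), cost = Inf,
                converged = FALSE))
  list(theta = setNames(bwd(coef(fit)), names),
       cost = fit$deviance / 2, converged = fit$info %in% 1:4)
}

## Tight-tolerance polishing of a candidate optimum: repeated
## restarted descents until convergence or stalled improvement.
.polishRun <- function(run, problem, conds) {
  pol <- .runStart(run$theta, problem, control = .lmControl(250L),
                   conds = conds, rtol = 1e-11, atol = 1e-13)
  if (!is.finite(pol$cost)) return(run)
  ## keep restarting while restarts still help: the LM convergence
  ## flag can trip inside a shallow valley where a damping reset
  ## finds further descent
  for (i in 1:10) {
    p2 <- .runStart(pol$theta, problem, control = .lmControl(250L),
                    conds = conds, rtol = 1e-11, atol = 1e-13)
    if (!is.finite(p2$cost)) break
    improved <- p2$cost < pol$cost * 0.999
    if (p2$cost < pol$cost) pol <- p2
    if (!improved) break
  }
  list(theta = pol$theta, cost = pol$cost,
       converged = run$converged || pol$converged)
}

## One descent of a FitProblem from a given start.
.runStart <- function(par, problem, control = .lmControl(),
                      conds = .problemConditions(problem),
                      rtol = 1e-8, atol = 1e-10) {
  .boundedLM(par, problem@free$lower, problem@free$upper,
             problem@free$name,
             function(th) .residJac(th, problem, jac = FALSE,
                                    conds = conds, rtol = rtol,
                                    atol = atol),
             function(th) .residJac(th, problem, jac = TRUE,
                                    conds = conds, rtol = rtol,
                                    atol = atol)$J,
             control = control)
}

#' Multi-start maximum-likelihood calibration
#'
#' Runs bounded least squares on the stacked weighted residuals from
#' `nStarts` random starting vectors (log-uniform over each free
#' parameter's range; linear-uniform where the range spans zero), with
#' the analytic Jacobian from the forward sensitivity equations, and
#' reports the best converged optimum ranked by cost. Equal-cost
#' optima are tie-broken toward the lexicographically smallest
#' parameter vector for determinism.
#'
#' @param problem a [FitProblem-class].
#' @param startAt optional matrix (or single named vector) of starting
#'   values to use instead of random sampling.
#' @param explIter iteration cap for the exploration descents; the
#'   winner is then polished to convergence at tight solver
#'   tolerances.
#' @param polish polish the best start with tightened integration
#'   tolerances and restarted descents.
#' @return a [FitResult-class].
#' @export
fitMultistart <- function(problem, startAt = NULL, explIter = 100L,
                          polish = TRUE) {
  stopifnot(is(problem, "FitProblem"))
  methods::validObject(problem)
  if (is.null(startAt)) {
    set.seed(problem@seed)
    starts <- .sampleStarts(problem@free, problem@nStarts)
  } else {
    starts <- if (is.matrix(startAt)) startAt else
      matrix(startAt, nrow = 1,
             dimnames = list(NULL, problem@free$name))
  }
  conds <- .problemConditions(problem)
  runs <- lapply(seq_len(nrow(starts)), function(i)
    .runStart(starts[i, ], problem, control = .lmControl(explIter),
              conds = conds))
  costs <- vapply(runs, `[[`, numeric(1), "cost")
  conv <- vapply(runs, `[[`, logical(1), "converged")
  if (!any(is.finite(costs)))
    stop("no multistart run converged to a finite cost")
  if (mean(conv) < 0.5)
    warning(sprintf("only %d/%d starts converged", sum(conv),
                    length(conv)))
  ## the capped exploration ranks basins only coarsely -- a start still
  ## descending can outrun one already settled in a shallow local
  ## optimum -- so continue the leading candidates to full depth
  ## before the final ranking
  if (polish) {
    for (ci in utils::head(order(costs), 6L)) {
      deep <- .runStart(runs[[ci]]$theta, problem,
                        control = .lmControl(200L), conds = conds)
      if (is.finite(deep$cost) && deep$cost < runs[[ci]]$cost) {
        runs[[ci]] <- deep
        costs[ci] <- deep$cost
      }
    }
  }
  ## rank by cost; among (numerically) equal costs take the
  ## lexicographically smallest theta
  best <- which(costs <= min(costs) + 1e-12)
  if (length(best) > 1L) {
    thetas <- do.call(rbind, lapply(runs[best], `[[`, "theta"))
    best <- best[do.call(order, as.data.frame(thetas))[1]]
  }
  run <- runs[[best]]
  ## polish the leading candidates with tighter integration tolerances
  ## so the optimizer can follow shallow valleys below the solver
  ## noise floor; restarting resets the LM damping, which descends
  ## curved valleys far faster than one long run
  if (polish) {
    cand <- unique(c(best,
                     order(costs)[seq_len(min(2L, length(costs)))]))
    for (ci in cand) {
      pol <- .polishRun(runs[[ci]], problem, conds)
      if (is.finite(pol$cost) && pol$cost < run$cost)
        run <- pol
    }
  }
  ssr <- perConditionSSR(run$theta, problem)
  ## distinct leading optima (possible alternative basins)
  cand <- list(run$theta)
  for (ci in order(costs)) {
    th <- runs[[ci]]$theta
    if (!is.finite(runs[[ci]]$cost)) next
    distinct <- all(vapply(cand, function(x)
      max(abs(th - x) / pmax(abs(x), 1e-8)) > 0.2, logical(1)))
    if (distinct) cand <- c(cand, list(th))
    if (length(cand) >= 3L) break
  }
  new("FitResult", theta = run$theta,
      params = applyTheta(problem@params, run$theta),
      cost = run$cost, perConditionSSR = ssr,
      startTrace = data.frame(start = seq_along(costs), cost = costs,
                              converged = conv),
      converged = run$converged, seed = problem@seed,
      candidates = cand)
}

#' Joint calibration with parameters shared across compounds
#'
#' Minimizes the concatenated weighted residuals of several
#' single-compound problems in one optimization, with the named
#' parameters shared (one common value) and all remaining free
#' parameters compound-specific. With a single problem this reduces
#' exactly to [fitMultistart()].
#'
#' @param problems named (or name-carrying) list of
#'   [FitProblem-class] objects, one per compound.
#' @param shared free parameter names constrained to a common value
#'   across compounds (default `VA`, `KA`, `r`).
#' @param nStarts,seed multistart settings (default: taken from the
#'   first problem).
#' @return a [FitResult-class]; `theta` holds shared names as-is and
#'   compound-specific entries as `"<compound>.<name>"`; `params` is a
#'   named list of per-compound parameter objects; `perConditionSSR`
#'   is named `"<compound>:<concentration>"`.
#' @export
fitJoint <- function(problems, shared = c("VA", "KA", "r"),
                     nStarts = NULL, seed = NULL) {
  if (length(problems) == 1L) return(fitMultistart(problems[[1]]))
  cmps <- vapply(problems, slot, character(1), "compound")
  names(problems) <- cmps
  if (is.null(nStarts)) nStarts <- problems[[1]]@nStarts
  if (is.null(seed)) seed <- problems[[1]]@seed

  shared <- intersect(shared, problems[[1]]@free$name)
  rowsOf <- function(pr, nms) pr@free[pr@free$name %in% nms, ,
                                      drop = FALSE]
  freeJ <- rowsOf(problems[[1]], shared)
  maps <- list()
  for (cmp in cmps) {
    own <- problems[[cmp]]@free[
      !problems[[cmp]]@free$name %in% shared, , drop = FALSE]
    loc <- own$name
    own$name <- paste0(cmp, ".", own$name)
    maps[[cmp]] <- setNames(c(shared, own$name), c(shared, loc))
    freeJ <- rbind(freeJ, own)
  }
  splitTheta <- function(theta, cmp) {
    m <- maps[[cmp]]
    setNames(theta[m], names(m))
  }
  condsBy <- lapply(problems, .problemConditions)
  makeFns <- function(rtol, atol) {
    fn <- function(th) {
      names(th) <- freeJ$name
      unlist(lapply(cmps, function(cmp)
        .residJac(splitTheta(th, cmp), problems[[cmp]], jac = FALSE,
                  conds = condsBy[[cmp]], rtol = rtol, atol = atol)))
    }
    jf <- function(th) {
      names(th) <- freeJ$name
      do.call(rbind, lapply(cmps, function(cmp) {
        pr <- problems[[cmp]]
        Jc <- .residJac(splitTheta(th, cmp), pr, jac = TRUE,
                        conds = condsBy[[cmp]], rtol = rtol,
                        atol = atol)$J
        J <- matrix(0, nrow = nrow(Jc), ncol = nrow(freeJ),
                    dimnames = list(NULL, freeJ$name))
        J[, maps[[cmp]]] <- Jc[, names(maps[[cmp]])]
        J
      }))
    }
    list(fn = fn, jf = jf)
  }
  expl <- makeFns(1e-8, 1e-10)
  set.seed(seed)
  starts <- .sampleStarts(freeJ, nStarts)
  runs <- lapply(seq_len(nrow(starts)), function(i)
    .boundedLM(starts[i, ], freeJ$lower, freeJ$upper, freeJ$name,
               expl$fn, expl$jf, control = .lmControl(100L)))
  costs <- vapply(runs, `[[`, numeric(1), "cost")
  if (!any(is.finite(costs)))
    stop("no multistart run converged to a finite cost")
  ## deep-continue the leading candidates (see fitMultistart)
  for (ci in utils::head(order(costs), 4L)) {
    deep <- .boundedLM(runs[[ci]]$theta, freeJ$lower, freeJ$upper,
                       freeJ$name, expl$fn, expl$jf,
                       control = .lmControl(200L))
    if (is.finite(deep$cost) && deep$cost < costs[ci]) {
      runs[[ci]] <- deep
      costs[ci] <- deep$cost
    }
  }
  run <- runs[[which.min(costs)]]
  ## restarted tight-tolerance polish (see fitMultistart)
  tight <- makeFns(1e-11, 1e-13)
  pol <- run
  for (i in 1:10) {
    p2 <- .boundedLM(pol$theta, freeJ$lower, freeJ$upper, freeJ$name,
                     tight$fn, tight$jf, control = .lmControl(250L))
    if (!is.finite(p2$cost)) break
    improved <- p2$cost < pol$cost * 0.999
    if (p2$cost < pol$cost)
      pol <- list(theta = p2$theta, cost = p2$cost,
                  converged = run$converged || p2$converged)
    if (!improved) break
  }
  if (pol$cost <= run$cost) run <- pol
  paramsList <- lapply(cmps, function(cmp)
    applyTheta(problems[[cmp]]@params, splitTheta(run$theta, cmp)))
  names(paramsList) <- cmps
  ssr <- unlist(lapply(cmps, function(cmp) {
    s <- perConditionSSR(splitTheta(run$theta, cmp), problems[[cmp]])
    setNames(s, paste0(cmp, ":", names(s)))
  }))
  new("FitResult", theta = run$theta, params = paramsList,
      cost = run$cost, perConditionSSR = ssr,
      startTrace = data.frame(start = seq_along(costs), cost = costs,
                              converged = vapply(runs, `[[`,
                                                 logical(1),
                                                 "converged")),
      converged = run$converged, seed = as.integer(seed),
      candidates = list(run$theta))
}

#' Per-compound cost of a joint fit
#'
#' @param fit a [FitResult-class] from [fitJoint()].
#' @return named numeric vector of half the per-compound weighted SSR.
#' @export
perCompoundCost <- function(fit) {
  nm <- sub(":.*$", "", names(fit@perConditionSSR))
  vapply(split(fit@perConditionSSR, nm), sum, numeric(1)) / 2
}

#' Compare fit quality between inhibitor classes
#'
#' Two-sample two-sided Kolmogorov-Smirnov tests on per-compound cost
#' values for every pair of classes (exact p-values for the small
#' per-class compound counts typical of inhibitor panels).
#'
#' @param costs numeric per-compound cost values.
#' @param classes inhibitor class label per compound.
#' @return data.frame with columns `class1`, `class2`, `D`, `p`.
#' @export
compareClasses <- function(costs, classes) {
  if (length(costs) != length(classes))
    stop("'costs' and 'classes' lengths differ")
  groups <- split(costs, classes)
  if (any(!lengths(groups)))
    stop("every class needs at least one compound")
  cls <- names(groups)
  pairs <- utils::combn(cls, 2)
  out <- apply(pairs, 2, function(pr) {
    kt <- suppressWarnings(ks.test(groups[[pr[1]]], groups[[pr[2]]],
                                   exact = TRUE))
    data.frame(class1 = pr[1], class2 = pr[2],
               D = unname(kt$statistic), p = kt$p.value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

setMethod("show", "FitProblem", function(object) {
  cat(sprintf(
    "FitProblem: compound '%s', variant '%s', %d free parameter(s), %d start(s)\n",
    object@compound, object@variant@name, nrow(object@free),
    object@nStarts))
})

setMethod("show", "FitResult", function(object) {
  cat(sprintf("FitResult: cost %.6g (%d/%d starts converged)\n",
              object@cost, sum(object@startTrace$converged),
              nrow(object@startTrace)))
  print(signif(object@theta, 4))
})

#' @describeIn fitMultistart best-fit free parameters of a fit.
#' @param object a [FitResult-class].
#' @param ... unused.
#' @export
setMethod("coef", "FitResult", function(object, ...) object@theta)
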