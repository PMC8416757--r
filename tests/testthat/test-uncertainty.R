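test_that("profile-likelihood thresholds equal chi-square quantiles", {
  expect_equal(plThreshold(0.95), qchisq(0.95, 1), tolerance = 1e-12)
  expect_lt(abs(plThreshold(0.95) - 3.8415), 1e-3)
  expect_lt(abs(plThreshold(0.99) - 6.6349), 1e-3)
  expect_lt(plThreshold(1e-6), 1e-5)  # Delta -> 0 as confidence -> 0
  expect_error(plThreshold(0), "between 0 and 1")
  expect_error(plThreshold(1), "between 0 and 1")
})

test_that("the profile engine reproduces the analytic CI of a linear model", {
  ## y = theta * t + eps, known sigma: NPL(theta) = SSR/sigma^2,
  ## analytic CI = thetaHat +/- 1.96 * sigma / sqrt(sum(t^2))
  set.seed(51)
  tt <- 1:23
  sigma <- 0.4
  theta0 <- 1.7
  y <- theta0 * tt + rnorm(length(tt), 0, sigma)
  thetaHat <- sum(tt * y) / sum(tt^2)
  nplFun <- function(th) sum((y - th * tt)^2) / sigma^2
  refit <- function(v, warm) list(npl = nplFun(v), theta = warm)
  walk <- mmpdyn:::.profileWalk(thetaHat, nplFun(thetaHat),
                                c(theta = thetaHat), refit,
                                threshold = plThreshold(0.95),
                                stepFactor = 1.005,
                                hardRange = c(thetaHat / 10,
                                              thetaHat * 10),
                                maxPoints = 200L)
  ci <- mmpdyn:::.profileCI(walk$grid, walk$npl, thetaHat,
                            nplFun(thetaHat) + plThreshold(0.95))
  half <- 1.959964 * sigma / sqrt(sum(tt^2))
  expect_lt(abs(ci[1] - (thetaHat - half)) / half, 0.01)
  expect_lt(abs(ci[2] - (thetaHat + half)) / half, 0.01)
})

## shared small uncoupler fit used by the profile/ratio tests
uncFitFixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    des <- smallUncDesign(nDoses = 3, cellsPerWell = 25,
                          sigmaCell = 0.25)
    gen <- generateExperiment(des, seed = 52)
    cs <- preprocessCells(gen$cells)
    pr <- fitProblem(cs, modelVariant("pk_decay", "uncoupler"),
                     gen$truth$compounds$uncX$params,
                     free = c("gamma", "D0", "c1", "c0"),
                     nStarts = 8L, seed = 5L)
    fit <- suppressWarnings(fitMultistart(pr))
    cache <<- list(gen = gen, pr = pr, fit = fit)
    cache
  }
})

test_that("the decay-rate profile is identifiable with a finite CI near the truth", {
  fx <- uncFitFixture()
  pc <- profileParameter(fx$pr, "gamma", fit = fx$fit)
  expect_equal(min(pc@npl, na.rm = TRUE), pc@nplMin, tolerance = 1e-6)
  expect_true(all(pc@npl >= pc@nplMin - 1e-6, na.rm = TRUE))
  expect_true(pc@identifiable)
  # the CI brackets the MLE and sits at the truth's scale (coverage of
  # the truth itself is checked by the bootstrap coverage study)
  expect_lt(pc@ciLow, pc@mle)
  expect_gt(pc@ciHigh, pc@mle)
  expect_gt(pc@ciHigh, 0.2 / 2)   # truth gamma = 0.2
  expect_lt(pc@ciLow, 0.2 * 2)
  expect_gt(pc@ciLow, 0)
})

test_that("derived-quantity profiles obey monotone-transform equivariance", {
  fx <- uncFitFixture()
  pcG <- profileParameter(fx$pr, "gamma", fit = fx$fit,
                          stepFactor = 1.1)
  q <- ratioQuantity(2, 24)
  pcR <- profileDerived(fx$pr, q, fit = fx$fit, stepFactor = 1.1)
  ## R = exp(-22 gamma) is decreasing in gamma: CI ends swap
  expect_equal(pcR@mle, exp(-22 * pcG@mle), tolerance = 1e-8)
  expect_lt(abs(pcR@ciLow - exp(-22 * pcG@ciHigh)) /
            max(pcR@ciLow, 1e-12), 0.05)
  expect_lt(abs(pcR@ciHigh - exp(-22 * pcG@ciLow)) /
            max(pcR@ciHigh, 1e-12), 0.05)
})

test_that("profiling the identity of a free parameter matches profileParameter", {
  fx <- uncFitFixture()
  q <- derivedQuantity("gamma_id",
                       fn = function(theta) theta[["gamma"]],
                       invert = function(v, theta)
                         setNames(v, "gamma"))
  pcI <- profileDerived(fx$pr, q, fit = fx$fit)
  pcG <- profileParameter(fx$pr, "gamma", fit = fx$fit)
  expect_equal(pcI@mle, pcG@mle, tolerance = 1e-10)
  expect_equal(pcI@ciLow, pcG@ciLow, tolerance = 1e-6)
  expect_equal(pcI@ciHigh, pcG@ciHigh, tolerance = 1e-6)
})

test_that("a constant derived quantity is flagged as degenerate", {
  fx <- uncFitFixture()
  q <- derivedQuantity("const", fn = function(theta) 42)
  expect_warning(pc <- profileDerived(fx$pr, q, fit = fx$fit),
                 "constant")
  expect_false(pc@identifiable)
})

test_that("predicted PK ratios follow the exponential decay law", {
  expect_equal(predictRatio(0.5, 8, 8), 1)
  expect_equal(predictRatio(0, 2, 24), 1)
  expect_equal(predictRatio(0.1, 2, 24), exp(-2.2))
  expect_lt(abs(predictRatio(0.1, 2, 24) - 0.11080), 1e-5)
  expect_error(predictRatio(0.1, 24, 2), "T2")
  expect_error(predictRatio(0.1, -1, 2), "non-negative")
})

test_that("bootstrap on degenerate data yields zero-width intervals", {
  ## one plate, all cells identical: every resample is identical
  des <- smallUncDesign(nDoses = 2, nPlates = 1L, cellsPerWell = 8,
                        sigmaCell = 0, times = seq(1, 23, by = 3))
  gen <- generateExperiment(des, seed = 53)
  cs <- preprocessCells(gen$cells)
  pr <- fitProblem(cs, modelVariant("pk_decay", "uncoupler"),
                   gen$truth$compounds$uncX$params,
                   free = c("gamma", "c1", "c0"), nStarts = 1L)
  fit <- suppressWarnings(
    fitMultistart(pr, startAt = truthTheta(gen, "uncX", pr)))
  bt <- bootstrapCI(gen$cells, pr, fit, nBoot = 12L, seed = 54L)
  expect_equal(bt@nBoot, 12L)
  expect_lt(max(bt@ci95[2, ] - bt@ci95[1, ]), 1e-8)
  expect_lt(max(apply(bt@estimates, 2, sd)), 1e-8)
})

test_that("bootstrap intervals widen with per-cell noise", {
  widths <- vapply(c(0.1, 0.6), function(sg) {
    des <- smallUncDesign(nDoses = 2, nPlates = 3L, cellsPerWell = 12,
                          sigmaCell = sg, times = seq(1, 23, by = 3))
    gen <- generateExperiment(des, seed = 55)
    cs <- preprocessCells(gen$cells)
    pr <- fitProblem(cs, modelVariant("pk_decay", "uncoupler"),
                     gen$truth$compounds$uncX$params,
                     free = c("gamma", "c1", "c0"), nStarts = 1L)
    fit <- suppressWarnings(
      fitMultistart(pr, startAt = truthTheta(gen, "uncX", pr)))
    bt <- bootstrapCI(gen$cells, pr, fit, nBoot = 25L, seed = 56L)
    bt@ci95[2, "gamma"] - bt@ci95[1, "gamma"]
  }, numeric(1))
  expect_gt(widths[2], widths[1])
})

test_that("the fast bootstrap resampler agrees with preprocessCells on degenerate pools", {
  ## with all cells in a pool identical, resampling is the identity and
  ## the fast path must equal the full preprocessing chain exactly
  des <- smallUncDesign(nDoses = 2, nPlates = 2L, cellsPerWell = 6,
                        sigmaCell = 0, times = seq(1, 23, by = 4))
  gen <- generateExperiment(des, seed = 57)
  full <- conditionData(preprocessCells(gen$cells))
  full <- full[order(full$concentration, full$time_h), ]
  bp <- mmpdyn:::.bootPools(gen$cells, "uncX")
  set.seed(58)
  fast <- conditionData(mmpdyn:::.bootResample(bp, "uncX"))
  fast <- fast[order(fast$concentration, fast$time_h), ]
  expect_equal(fast$mean_norm, full$mean_norm, tolerance = 1e-12)
  expect_equal(fast$se_norm, full$se_norm, tolerance = 1e-10)
})

test_that("measured-ratio comparison flags interval membership", {
  pred <- list(ratio = 0.2, plCI95 = c(0.15, 0.3),
               plCI99 = c(0.1, 0.35), bootCI95 = c(0.05, 0.5),
               bootCI99 = c(0.02, 0.6))
  rep1 <- compareMeasuredRatios(pred, c(0.18, 0.22))
  expect_equal(rep1$overall, "consistent")
  # below the PL interval but inside the wider bootstrap interval
  rep2 <- compareMeasuredRatios(pred, c(0.06, 0.09))
  expect_equal(rep2$overall, "mixed")
  expect_false(rep2$flags[["pl95"]])
  expect_true(rep2$flags[["boot95"]])
  rep3 <- compareMeasuredRatios(pred, c(0.001))
  expect_equal(rep3$overall, "inconsistent")
  rep4 <- compareMeasuredRatios(pred)
  expect_equal(rep4$overall, "prediction_only")
  expect_error(compareMeasuredRatios(pred, c(-1)), "positive")
})
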