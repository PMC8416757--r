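test_that("weighted SSR matches hand computations", {
  expect_equal(weightedSSR(rep(1, 23), rep(1, 23), rep(0.1, 23)), 0)
  y <- rnorm(23)
  expect_equal(weightedSSR(y + 0.1, y, rep(0.1, 23)), 23)
  expect_equal(weightedSSR(c(0.1, -0.2), c(0, 0), c(0.1, 0.1)), 5)
  expect_error(weightedSSR(1:3, 1:2, c(1, 1)), "lengths")
  expect_error(weightedSSR(1:2, 1:2, c(1, 0)), "positive")
})

test_that("total cost is half the summed per-condition SSR", {
  des <- smallEtcDesign(nDoses = 3, sigmaCell = 0.2, cellsPerWell = 15)
  gen <- generateExperiment(des, seed = 9)
  pr <- fitProblem(preprocessCells(gen$cells),
                   modelVariant("basic", "etc_inhibitor"),
                   gen$truth$compounds$etcX$params, nStarts = 2L)
  th <- truthTheta(gen, "etcX", pr)
  expect_equal(totalCost(th, pr), sum(perConditionSSR(th, pr)) / 2,
               tolerance = 1e-9)
  # perfect-match cost on noiseless data is essentially zero
  des0 <- smallEtcDesign(nDoses = 3, sigmaCell = 0)
  gen0 <- generateExperiment(des0, seed = 10)
  pr0 <- fitProblem(preprocessCells(gen0$cells),
                    modelVariant("basic", "etc_inhibitor"),
                    gen0$truth$compounds$etcX$params, nStarts = 2L)
  expect_lt(totalCost(truthTheta(gen0, "etcX", pr0), pr0), 1e-10)
})

test_that("optimization started at the truth stays at the truth", {
  des <- smallEtcDesign(nDoses = 4, sigmaCell = 0)
  gen <- generateExperiment(des, seed = 12)
  pr <- fitProblem(preprocessCells(gen$cells),
                   modelVariant("basic", "etc_inhibitor"),
                   gen$truth$compounds$etcX$params, nStarts = 1L)
  th <- truthTheta(gen, "etcX", pr)
  fit <- suppressWarnings(fitMultistart(pr, startAt = th))
  expect_lt(sqrt(sum((fit@theta - th)^2)) / sqrt(sum(th^2)), 1e-4)
  expect_lt(fit@cost, 1e-8)
})

test_that("multistart refits recover the generating parameters", {
  des <- smallEtcDesign(nDoses = 4, sigmaCell = 0,
                        times = seq(1, 23, by = 2))
  gen <- generateExperiment(des, seed = 13)
  pr <- fitProblem(preprocessCells(gen$cells),
                   modelVariant("basic", "etc_inhibitor"),
                   gen$truth$compounds$etcX$params,
                   nStarts = 6L, seed = 2L)
  fit <- suppressWarnings(fitMultistart(pr, explIter = 40L))
  th <- truthTheta(gen, "etcX", pr)
  expect_lt(max(abs(fit@theta - th) / pmax(abs(th), 1e-8)), 0.01)
  expect_lt(fit@cost, 1e-6)
  # reported cost is the minimum over the start trace
  expect_lte(fit@cost, min(fit@startTrace$cost) + 1e-9)
  expect_true(all(cummin(fit@startTrace$cost) <=
                  fit@startTrace$cost))
})

test_that("the minimized cost matches the chi-square expectation under known noise", {
  des <- smallEtcDesign(nDoses = 3, sigmaCell = 0,
                        times = seq(1, 23, by = 2))
  gen <- generateExperiment(des, seed = 14)
  cs <- preprocessCells(gen$cells)
  d <- conditionData(cs)
  sigma <- 0.02
  set.seed(140)
  costs <- replicate(3, {
    d2 <- d
    d2$mean_norm <- d$mean_norm + rnorm(nrow(d), 0, sigma)
    d2$se_norm <- sigma
    pr <- fitProblem(conditionSet(d2),
                     modelVariant("basic", "etc_inhibitor"),
                     gen$truth$compounds$etcX$params, nStarts = 1L)
    fit <- suppressWarnings(
      fitMultistart(pr, startAt = truthTheta(gen, "etcX", pr)))
    fit@cost
  })
  n <- nrow(d); p <- 3 + 2 + 3  # VA,KA,r + c1,c0 + one D0 per dose
  expected <- (n - p) / 2
  mcSD <- sqrt(2 * (n - p)) / 2 / sqrt(length(costs))
  expect_lt(abs(mean(costs) - expected), 4 * mcSD)
})

test_that("joint fitting nests separate fits and recovers shared parameters", {
  conc <- 10^seq(-1, 1, length.out = 3)
  mkPar <- function(c1, c0) modelParameters(KE = 1e-5, VA = 1.2,
                                            KA = 1, r = 1, c1 = c1,
                                            c0 = c0, D0 = conc)
  des <- experimentDesign(
    list(list(name = "cmpA",
              variant = modelVariant("basic", "etc_inhibitor"),
              params = mkPar(0.9, 0.1), concentrations = conc),
         list(name = "cmpB",
              variant = modelVariant("basic", "etc_inhibitor"),
              params = mkPar(1.1, 0.05), concentrations = conc)),
    nPlates = 2L, nTechReps = 1L, cellsPerWell = 5, sigmaCell = 0,
    controlWells = 1L, times = seq(1, 23, by = 2),
    driftInterceptSD = 0.05, driftSlopeSD = 0.02, plateJitterSD = 0)
  gen <- generateExperiment(des, seed = 15)
  cs <- preprocessCells(gen$cells)
  vr <- modelVariant("basic", "etc_inhibitor")
  prA <- fitProblem(cs, vr, mkPar(0.9, 0.1), compound = "cmpA",
                    nStarts = 5L, seed = 4L)
  prB <- fitProblem(cs, vr, mkPar(1.1, 0.05), compound = "cmpB",
                    nStarts = 5L, seed = 4L)
  fitA <- suppressWarnings(fitMultistart(prA, explIter = 40L))
  fitB <- suppressWarnings(fitMultistart(prB, explIter = 40L))
  joint <- suppressWarnings(fitJoint(list(prA, prB),
                                     shared = c("VA", "KA", "r"),
                                     nStarts = 8L))
  # nested-model inequality
  expect_gte(joint@cost, fitA@cost + fitB@cost - 1e-6)
  # truly shared generation: joint recovers the shared values
  expect_lt(abs(joint@theta[["VA"]] - 1.2) / 1.2, 0.02)
  expect_lt(abs(joint@theta[["KA"]] - 1) / 1, 0.02)
  expect_lt(abs(joint@theta[["r"]] - 1) / 1, 0.02)
  pcc <- perCompoundCost(joint)
  expect_named(pcc, c("cmpA", "cmpB"))
  expect_lt(abs(sum(pcc) - joint@cost), 1e-4)
  # degenerate single-compound call reduces to fitMultistart
  single <- suppressWarnings(fitJoint(list(prA)))
  expect_equal(single@cost, fitA@cost, tolerance = 1e-8)
})

test_that("KS class comparison matches the exhaustive permutation oracle", {
  same <- c(0.3, 1.1, 2.2)
  res <- compareClasses(c(same, same),
                        rep(c("I", "II"), each = 3))
  expect_equal(res$D, 0)
  expect_equal(res$p, 1)

  x <- c(1, 2, 3); y <- c(4, 5, 6)
  res2 <- suppressWarnings(compareClasses(c(x, y),
                                          rep(c("I", "III"), each = 3)))
  expect_equal(res2$D, 1)
  # brute-force permutation null of the KS statistic
  pooled <- c(x, y)
  combos <- combn(6, 3)
  dStat <- function(a, b) {
    grid <- sort(c(a, b))
    max(abs(ecdf(a)(grid) - ecdf(b)(grid)))
  }
  dObs <- dStat(x, y)
  dPerm <- apply(combos, 2, function(ix)
    dStat(pooled[ix], pooled[-ix]))
  pPerm <- mean(dPerm >= dObs - 1e-12)
  expect_equal(res2$p, pPerm, tolerance = 1e-12)
  # rank invariance under scaling
  res3 <- suppressWarnings(compareClasses(c(2 * x, 2 * y),
                                          rep(c("I", "III"), each = 3)))
  expect_equal(res3$D, res2$D)
  expect_equal(res3$p, res2$p)
  expect_error(compareClasses(1:3, c("a", "a")), "lengths")
})

test_that("three-class panels produce all pairwise comparisons", {
  set.seed(16)
  costs <- c(rchisq(4, 3), rchisq(4, 3) + 2, rchisq(4, 3))
  cls <- rep(c("I", "II", "III"), each = 4)
  res <- suppressWarnings(compareClasses(costs, cls))
  expect_equal(nrow(res), 3)
  expect_setequal(paste(res$class1, res$class2),
                  c("I II", "I III", "II III"))
  expect_true(all(res$p >= 0 & res$p <= 1))
})
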