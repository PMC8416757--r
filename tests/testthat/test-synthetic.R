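test_that("the generator is deterministic in its seed", {
  des <- smallUncDesign(nDoses = 2, cellsPerWell = 10)
  g1 <- generateExperiment(des, seed = 61)
  g2 <- generateExperiment(des, seed = 61)
  g3 <- generateExperiment(des, seed = 62)
  expect_identical(g1$cells, g2$cells)
  expect_false(identical(g1$cells$intensity, g3$cells$intensity))
})

test_that("noise-free cells equal the MMP trajectory when scaling is trivial", {
  conc <- c(0.5, 5)
  par <- modelParameters(c1 = 1, c0 = 0, gamma = 0.3, D0 = conc)
  des <- experimentDesign(
    list(list(name = "uX",
              variant = modelVariant("pk_decay", "uncoupler"),
              params = par, concentrations = conc)),
    nPlates = 2L, nTechReps = 1L, cellsPerWell = 4, sigmaCell = 0,
    controlWells = 1L, times = seq(1, 13, by = 3),
    driftInterceptSD = 0, driftSlopeSD = 0, plateJitterSD = 0)
  gen <- generateExperiment(des, seed = 63)
  psio <- steadyState(par)[["Psi"]]
  for (i in seq_along(conc)) {
    tr <- simulateTrajectory(modelVariant("pk_decay", "uncoupler"),
                             par, i, times = des@times)
    sub <- gen$cells[gen$cells$concentration == conc[i] &
                     !gen$cells$is_control, ]
    expect_equal(sub$intensity,
                 tr@Psi[match(sub$time_h, des@times)],
                 tolerance = 1e-12)
  }
  cs <- conditionData(preprocessCells(gen$cells))
  tr1 <- simulateTrajectory(modelVariant("pk_decay", "uncoupler"),
                            par, 1, times = des@times)
  expect_equal(cs$mean_norm[cs$concentration == conc[1]],
               tr1@Psi / psio, tolerance = 1e-12)
})

test_that("well geometric means converge to the well signal", {
  conc <- 1
  par <- modelParameters(gamma = 0.2, D0 = conc)
  sigma <- 0.4
  des <- experimentDesign(
    list(list(name = "uX",
              variant = modelVariant("pk_decay", "uncoupler"),
              params = par, concentrations = conc)),
    nPlates = 1L, nTechReps = 1L, cellsPerWell = 4000,
    cellsDispersion = 1e6, sigmaCell = sigma, controlWells = 1L,
    times = c(1, 5), driftInterceptSD = 0, driftSlopeSD = 0,
    plateJitterSD = 0)
  gen <- generateExperiment(des, seed = 64)
  tr <- simulateTrajectory(modelVariant("pk_decay", "uncoupler"),
                           par, 1, times = des@times)
  sub <- gen$cells[!gen$cells$is_control & gen$cells$time_h == 1, ]
  n <- nrow(sub)
  gm <- wellGeometricMean(sub$intensity)
  expect_lt(abs(log(gm) - log(tr@y[1])), 3 * sigma / sqrt(n))
})

test_that("study panels reproduce the class-specific response shapes", {
  panels <- makeStudyPanels()
  ## (a) ETC inhibition: y non-increasing at every dose over the window
  etc <- panels$etc@compounds[[1]]
  for (i in seq_along(etc$concentrations)) {
    tr <- simulateTrajectory(etc$variant, etc$params, i,
                             times = 0:23)
    expect_true(all(diff(tr@y) <= 1e-3 * max(abs(tr@y))),
                label = sprintf("etc dose %d monotone", i))
  }
  ## (b) uncoupler with decay: dip then partial recovery at high dose
  unc <- panels$uncoupler@compounds[[1]]
  iTop <- length(unc$concentrations)
  trU <- simulateTrajectory(unc$variant, unc$params, iTop,
                            times = seq(0.5, 23, by = 0.5))
  iMin <- which.min(trU@y)
  expect_gt(trU@times[iMin], 1)
  expect_lt(trU@times[iMin], 23)
  expect_gt(trU@y[length(trU@y)], trU@y[iMin] * 1.2)  # recovery
  ## (c) ATP-synthase inhibitor, concentration-dependent decay:
  ## low doses rise then fall; the top dose stays hyperpolarized
  atp <- panels$atp@compounds[[1]]
  base <- observe(steadyState(atp$params)[["Psi"]], atp$params)
  for (i in 3:4) {  # upper low-block doses with visible response
    trA <- simulateTrajectory(atp$variant, atp$params, i,
                              times = seq(0.5, 23, by = 0.5))
    iMax <- which.max(trA@y)
    expect_gt(trA@y[iMax], base * 1.02)
    expect_lt(trA@times[iMax], 12)
    expect_lt(trA@y[length(trA@y)], trA@y[iMax] * 0.98)
  }
  iTopA <- length(atp$concentrations)
  trTop <- simulateTrajectory(atp$variant, atp$params, iTopA,
                              times = 0:23)
  expect_true(all(trTop@y[-1] > base))
})

test_that("design validity catches malformed inputs", {
  conc <- c(1, 0.5)  # not ascending
  par <- modelParameters(D0 = conc)
  expect_error(experimentDesign(
    list(list(name = "x", variant = modelVariant("basic"),
              params = par, concentrations = conc)),
    nPlates = 2L), "ascending")
  expect_error(experimentDesign(
    list(list(name = "x", variant = modelVariant("basic"),
              params = modelParameters(D0 = 1),
              concentrations = c(0.1, 1))),
    nPlates = 2L), "concentration count")
})
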