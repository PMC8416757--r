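test_that("the steady state is a fixpoint of every variant", {
  set.seed(31)
  for (k in 1:5) {
    p <- randomParams()
    base <- observe(steadyState(p)[["Psi"]], p)
    for (vr in allVariants()) {
      tr <- simulateTrajectory(vr, p, doseIndex = 0, times = 1:24)
      expect_lt(max(abs(tr@y - base)), 1e-7)
      expect_lt(max(abs(tr@O - steadyState(p)[["O"]])), 1e-7)
    }
  }
})

test_that("compiled trajectories match an independent R integration", {
  set.seed(32)
  for (k in 1:4) {
    p <- randomParams()
    for (vr in allVariants()) {
      tr <- simulateTrajectory(vr, p, doseIndex = 2, times = 1:23)
      or <- oracleSimulate(vr, p, doseIndex = 2, times = 1:23)
      expect_lt(max(abs(tr@y - or$y)), 1e-6)
      expect_lt(max(abs(tr@Psi - or$Psi)), 1e-6)
    }
  }
})

test_that("fast compound decay lets the MMP relax back to baseline", {
  p <- modelParameters(gamma = 2, D0 = 5)
  vr <- modelVariant("pk_decay", "uncoupler")
  tr <- simulateTrajectory(vr, p, 1, times = c(1, 4, 12, 24))
  base <- observe(steadyState(p)[["Psi"]], p)
  expect_gt(abs(tr@y[1] - base) / base, 0.05)  # initial suppression
  expect_lt(abs(tr@y[4] - base) / base, 0.01)  # recovered at 24 h
})

test_that("analytic sensitivities match central finite differences", {
  p <- modelParameters(VA = 1.4, KA = 0.8, Cf = 1.1, r = 1.3,
                       c1 = 0.9, c0 = 0.15, gamma = 0.25, alpha = 0.4,
                       gammaL = 0.5, gammaH = 0.05, D0 = c(0.1, 1, 5))
  tt <- c(1, 3, 7, 15, 23)
  cases <- list(
    list(vr = modelVariant("basic", "etc_inhibitor"), di = 2,
         free = c("VA", "KA", "Cf", "KE", "KEi", "r", "c1", "c0",
                  "D0[2]")),
    list(vr = modelVariant("pk_decay", "uncoupler"), di = 2,
         free = c("VA", "KA", "r", "gamma", "D0[2]", "c1")),
    list(vr = modelVariant("pk_decay_leakage",
                           "atp_synthase_inhibitor"), di = 2,
         free = c("VA", "KA", "Cf", "alpha", "gamma", "KAi",
                  "D0[2]")),
    list(vr = modelVariant("conc_dep_decay", "atp_synthase_inhibitor",
                           lowBlock = 1:2), di = 3,
         free = c("gammaL", "gammaH", "VA")),
    list(vr = modelVariant("conc_dep_decay", "atp_synthase_inhibitor",
                           lowBlock = 1:2), di = 1,
         free = c("gammaL", "gammaH", "VA")))
  for (cs in cases) {
    st <- simulateSensitivities(cs$vr, p, cs$di, times = tt,
                                freeNames = cs$free)
    for (nm in cs$free) {
      th <- getParam(p, nm)
      h <- max(abs(th), 1e-3) * 1e-6
      yp <- simulateTrajectory(cs$vr, setParam(p, nm, th + h), cs$di,
                               times = tt, rtol = 1e-11,
                               atol = 1e-13)@y
      ym <- simulateTrajectory(cs$vr, setParam(p, nm, th - h), cs$di,
                               times = tt, rtol = 1e-11,
                               atol = 1e-13)@y
      fd <- (yp - ym) / (2 * h)
      scale <- max(abs(fd), 1e-8)
      expect_lt(max(abs(st@sens[, nm] - fd)) / scale, 1e-4,
                label = sprintf("sensitivity %s (%s)", nm,
                                cs$vr@name))
    }
  }
})

test_that("observation-scaling sensitivities are exact", {
  p <- modelParameters(D0 = 2)
  vr <- modelVariant("basic", "etc_inhibitor")
  st <- simulateSensitivities(vr, p, 1, times = 1:10,
                              freeNames = c("c1", "c0"))
  expect_equal(st@sens[, "c0"], rep(1, 10))
  expect_equal(st@sens[, "c1"], st@Psi)
})

test_that("sensitivities of the fixpoint equal the analytic steady-state derivative", {
  p <- modelParameters(VA = 1.5, KA = 0.9, Cf = 1.2, c1 = 0.8,
                       c0 = 0.1)
  vr <- modelVariant("basic", "etc_inhibitor")
  st <- simulateSensitivities(vr, p, 0, times = 1:8,
                              freeNames = c("VA", "KA"))
  s <- p@supply; den <- p@VA - s * p@Cf
  dVA <- -s * p@Cf * p@KA / den^2 * p@c1
  dKA <- s * p@Cf / den * p@c1
  expect_equal(unname(st@sens[, "VA"]), rep(dVA, 8), tolerance = 1e-7)
  expect_equal(unname(st@sens[, "KA"]), rep(dKA, 8), tolerance = 1e-7)
})

test_that("refining the output grid leaves shared time points unchanged", {
  p <- modelParameters(gamma = 0.3, D0 = c(1, 4))
  vr <- modelVariant("pk_decay", "uncoupler")
  coarse <- simulateTrajectory(vr, p, 2, times = seq(1, 23, by = 2))
  fine <- simulateTrajectory(vr, p, 2, times = seq(0.5, 23, by = 0.5))
  shared <- match(coarse@times, fine@times)
  expect_lt(max(abs(coarse@y - fine@y[shared])), 1e-7)
})

test_that("oxygen stays at steady state without ETC inhibition", {
  set.seed(33)
  p <- randomParams()
  Oss <- steadyState(p)[["O"]]
  for (nm in c("pk_unc", "pk_atp", "leak_atp", "concdep_atp")) {
    vr <- allVariants()[[nm]]
    tr <- simulateTrajectory(vr, p, 2, times = 1:23)
    expect_lt(max(abs(tr@O - Oss)), 1e-7)
  }
})

test_that("predicted OCR follows dose and baseline expectations", {
  p <- modelParameters()
  expect_equal(predictOcr(p, 0, t = 3), 0.6, tolerance = 1e-8)
  # hand evaluation at t -> 0 where O = O_ss = 0.6
  expect_equal(predictOcr(p, 1, t = 0), 0.3, tolerance = 1e-6)
  # non-increasing in dose at fixed early time
  doses <- c(0, 0.1, 0.5, 2, 10)
  o30min <- vapply(doses, function(d) predictOcr(p, d, t = 0.5),
                   numeric(1))
  expect_true(all(diff(o30min) < 1e-10))
})

test_that("trajectories export to tidy CSV", {
  p <- modelParameters(gamma = 0.2, D0 = c(0.5, 2))
  vr <- modelVariant("pk_decay", "uncoupler")
  trs <- lapply(1:2, function(i)
    simulateTrajectory(vr, p, i, times = 1:5))
  d <- as.data.frame(trs[[1]])
  expect_named(d, c("time_h", "O", "Psi", "y",
                    "effective_concentration"))
  expect_equal(d$y, p@c1 * d$Psi + p@c0)
  f <- tempfile(fileext = ".csv")
  exportTrajectories(trs, f, compound = "uncX", doseIndex = 1:2)
  back <- read.csv(f)
  expect_equal(nrow(back), 10)
  expect_named(back, c("compound", "dose_index", "time_h", "O", "Psi",
                       "y", "effective_concentration"))
  expect_true(all(diff(back$effective_concentration[back$dose_index ==
                                                    2]) < 0))
  unlink(f)
})
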