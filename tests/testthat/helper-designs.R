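## Small study designs shared across tests. Sizes are reduced relative
## to the full panels to keep simulation studies quick; the end-to-end
## tests use the full study sizes where the design itself is the claim
## under test.

smallEtcDesign <- function(nDoses = 5, times = seq(1, 23, by = 2),
                           sigmaCell = 0, nPlates = 2L,
                           cellsPerWell = 5, drift = TRUE,
                           jitter = FALSE) {
  conc <- 10^seq(-1.5, 1, length.out = nDoses)
  par <- modelParameters(KE = 1e-5, VA = 1.2, KA = 1, r = 1,
                         c1 = 0.9, c0 = 0.1, D0 = conc)
  experimentDesign(
    list(list(name = "etcX",
              variant = modelVariant("basic", "etc_inhibitor"),
              params = par, concentrations = conc)),
    nPlates = nPlates, nTechReps = 1L, cellsPerWell = cellsPerWell,
    sigmaCell = sigmaCell, controlWells = 1L, times = times,
    driftInterceptSD = if (drift) 0.05 else 0,
    driftSlopeSD = if (drift) 0.02 else 0,
    plateJitterSD = if (jitter) 0.1 else 0)
}

smallUncDesign <- function(nDoses = 3, times = seq(1, 23, by = 2),
                           sigmaCell = 0.3, nPlates = 4L,
                           cellsPerWell = 40, gamma = 0.2) {
  conc <- 10^seq(-0.5, 0.7, length.out = nDoses)
  par <- modelParameters(VA = 1.2, KA = 1, r = 1, c1 = 0.9, c0 = 0.1,
                         gamma = gamma, D0 = conc)
  experimentDesign(
    list(list(name = "uncX",
              variant = modelVariant("pk_decay", "uncoupler"),
              params = par, concentrations = conc)),
    nPlates = nPlates, nTechReps = 2L, cellsPerWell = cellsPerWell,
    sigmaCell = sigmaCell, controlWells = 1L, times = times,
    driftInterceptSD = 0.05, driftSlopeSD = 0.02, plateJitterSD = 0)
}

## Truth vector on the DMSO-normalized observation scale, aligned with
## a problem's free-parameter order.
truthTheta <- function(gen, compound, problem) {
  tr <- gen$truth$compounds[[compound]]
  p <- tr$params
  full <- c(VA = p@VA, KA = p@KA, KAi = p@KAi, Cf = p@Cf, KE = p@KE,
            KEi = p@KEi, r = p@r, gamma = p@gamma, gammaL = p@gammaL,
            gammaH = p@gammaH, alpha = p@alpha,
            c1 = tr$c1_norm, c0 = tr$c0_norm,
            setNames(p@D0, sprintf("D0[%d]", seq_along(p@D0))))
  full[problem@free$name]
}
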