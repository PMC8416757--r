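#' Describe a synthetic imaging experiment
#'
#' Defines a multi-plate live-cell MMP imaging study: for each compound
#' a model variant, true parameters and an ascending concentration
#' series; plate (biological replicate) and technical replicate
#' structure; per-well cell-count distribution; per-cell log-normal
#' intensity noise; per-plate multiplicative dye drift (quenching and
#' uptake act plate-wise on treated and control wells alike); and a
#' per-plate, per-compound scale jitter applied to treated wells only,
#' reproducing the compound-specific baseline scatter seen at
#' non-responsive low concentrations.
#'
#' @param compounds list; each element a list with entries `name`,
#'   `variant` ([ModelVariant-class]), `params`
#'   ([ModelParameters-class], `D0` aligned with `concentrations`) and
#'   `concentrations` (ascending, uM).
#' @param nPlates biological replicates, one plate each.
#' @param nTechReps technical replicate wells per condition per plate.
#' @param cellsPerWell mean cells per well (negative binomial).
#' @param cellsDispersion negative binomial size parameter.
#' @param times measurement grid (hours).
#' @param sigmaCell log-scale SD of single-cell intensities.
#' @param driftInterceptSD SD of the per-plate log drift intercept.
#' @param driftSlopeSD SD of the per-plate log-linear drift slope (1/h).
#' @param plateJitterSD log-scale SD of the treated-well scale jitter.
#' @param controlWells vehicle-control wells per plate.
#' @return an [ExperimentDesign-class] object.
#' @export
experimentDesign <- function(compounds, nPlates = 4L, nTechReps = 2L,
                             cellsPerWell = 300, cellsDispersion = 20,
                             times = 1:23, sigmaCell = 0.35,
                             driftInterceptSD = 0.05,
                             driftSlopeSD = 0.02, plateJitterSD = 0.1,
                             controlWells = 2L) {
  new("ExperimentDesign", compounds = compounds,
      nPlates = as.integer(nPlates), nTechReps = as.integer(nTechReps),
      cellsPerWell = cellsPerWell, cellsDispersion = cellsDispersion,
      times = as.numeric(times), sigmaCell = sigmaCell,
      driftInterceptSD = driftInterceptSD,
      driftSlopeSD = driftSlopeSD, plateJitterSD = plateJitterSD,
      controlWells = as.integer(controlWells))
}

#' Generate a synthetic single-cell imaging dataset
#'
#' Simulates each compound's trajectories from its variant and true
#' parameters, applies plate drift and treated-well jitter, and draws
#' per-cell intensities log-normally around the well signal (median
#' equal to the signal, log-scale SD `sigmaCell`; with
#' `sigmaCell = 0` every cell equals the well signal exactly). The
#' ground-truth record carries everything needed to score downstream
#' recovery, including the observation scaling re-expressed on the
#' DMSO-normalized scale actually seen by calibration
#' (`c1_norm = c1 / y_base`, `c0_norm = c0 / y_base` with
#' `y_base = c1 * Psi_o + c0`).
#'
#' @param design an [ExperimentDesign-class].
#' @param seed RNG seed; identical seeds give identical tables.
#' @return list with elements `cells` (single-cell data.frame with the
#'   [preprocessCells()] layout) and `truth` (per-compound parameters,
#'   trajectories, drift and jitter).
#' @export
generateExperiment <- function(design, seed = 1L) {
  stopifnot(is(design, "ExperimentDesign"))
  methods::validObject(design)
  set.seed(seed)
  times <- design@times
  nT <- length(times)

  drift <- lapply(seq_len(design@nPlates), function(p) {
    a <- rnorm(1, 0, design@driftInterceptSD)
    b <- rnorm(1, 0, design@driftSlopeSD)
    list(intercept = a, slope = b, series = exp(a + b * times))
  })

  truthCompounds <- list()
  rows <- list(); nr <- 0L
  addBlock <- function(block) {
    nr <<- nr + 1L
    rows[[nr]] <<- block
  }
  ## the vehicle wells carry the common unexposed baseline; observation
  ## scaling is shared plate hardware, taken from the first compound
  yCtrl <- local({
    cc <- design@compounds[[1]]
    observe(steadyState(cc$params)[["Psi"]], cc$params)
  })
  drawWell <- function(signal, plate, well, compound, conc, isCtrl) {
    ncell <- max(1L, rnbinom(1, mu = design@cellsPerWell,
                             size = design@cellsDispersion))
    inten <- if (design@sigmaCell > 0)
      rlnorm(ncell * nT, meanlog = rep(log(signal), each = ncell),
             sdlog = design@sigmaCell)
    else rep(signal, each = ncell)
    addBlock(data.frame(
      plate_id = plate, well_id = well, compound = compound,
      concentration = conc,
      time_h = rep(times, each = ncell),
      cell_id = paste0(well, "_c", seq_len(ncell)),
      intensity = inten, is_control = isCtrl,
      stringsAsFactors = FALSE))
  }

  for (cc in design@compounds) {
    params <- cc$params
    psio <- steadyState(params)[["Psi"]]
    yBase <- observe(psio, params)
    ySig <- vapply(seq_along(cc$concentrations), function(i)
      simulateTrajectory(cc$variant, params, i, times = times)@y,
      numeric(nT))
    jit <- exp(rnorm(design@nPlates, 0, design@plateJitterSD))
    for (p in seq_len(design@nPlates)) {
      plate <- sprintf("plate%02d", p)
      dr <- drift[[p]]$series
      for (i in seq_along(cc$concentrations)) {
        sig <- dr * jit[p] * ySig[, i]
        for (w in seq_len(design@nTechReps))
          drawWell(sig, plate,
                   sprintf("%s_%s_d%02d_t%d", plate, cc$name, i, w),
                   cc$name, cc$concentrations[i], FALSE)
      }
    }
    truthCompounds[[cc$name]] <- list(
      params = params, variant = cc$variant,
      concentrations = cc$concentrations,
      psio = psio, y_base = yBase,
      c1_norm = params@c1 / yCtrl, c0_norm = params@c0 / yCtrl,
      y_norm = ySig / yCtrl, jitter = jit)
  }

  for (p in seq_len(design@nPlates)) {
    plate <- sprintf("plate%02d", p)
    dr <- drift[[p]]$series
    for (w in seq_len(design@controlWells))
      drawWell(dr * yCtrl, plate, sprintf("%s_DMSO_w%d", plate, w),
               "DMSO", 0, TRUE)
  }

  cells <- do.call(rbind, rows[seq_len(nr)])
  rownames(cells) <- NULL
  list(cells = cells,
       truth = list(seed = seed, compounds = truthCompounds,
                    drift = drift, times = times))
}

#' Canned study panels for the three inhibitor classes
#'
#' Three ready-made designs mirroring the study's exposure scenarios:
#' \describe{
#'   \item{etc}{ETC-inhibitor panel (rotenone-like), basic variant,
#'     10 concentrations, 4 plates. The oxygen constants put the
#'     system in a large-oxygen-reservoir regime (`KE` small) so
#'     consumption inhibition -- and hence MMP suppression -- persists
#'     over the 23 h window.}
#'   \item{uncoupler}{FCCP-like uncoupler with pharmacokinetic decay
#'     (`gamma = 0.2`/h), 10 concentrations, 4 plates: the MMP drops
#'     and partially recovers as the compound decays.}
#'   \item{atp}{oligomycin-like ATP-synthase inhibitor with
#'     concentration-dependent decay (`gammaL = 0.6 > gammaH = 0.04`),
#'     8 concentrations, 3 plates: hyperpolarization that reverses at
#'     low doses and persists at high doses.}
#' }
#'
#' @param cellsPerWell,nTechReps,sigmaCell,controlWells overrides
#'   applied to all three designs (smaller values keep simulation
#'   studies fast).
#' @return named list of [ExperimentDesign-class] objects.
#' @export
makeStudyPanels <- function(cellsPerWell = 300, nTechReps = 2L,
                            sigmaCell = 0.35, controlWells = 2L) {
  concE <- 10^seq(-2, 2.5, by = 0.5)
  etcPar <- modelParameters(KE = 1e-5, KEi = 1, VA = 1.2, KA = 1,
                            Cf = 1, r = 1, c1 = 0.9, c0 = 0.1,
                            D0 = concE)
  concU <- 10^seq(-3.5, 1, by = 0.5)
  uncPar <- modelParameters(VA = 1.2, KA = 1, Cf = 1, r = 1,
                            c1 = 0.9, c0 = 0.1, gamma = 0.2,
                            D0 = concU)
  concA <- 10^seq(-2, 1.5, by = 0.5)
  atpPar <- modelParameters(VA = 1.2, KA = 1, KAi = 1, Cf = 1, r = 1,
                            c1 = 0.9, c0 = 0.1, gammaL = 0.6,
                            gammaH = 0.04, D0 = concA)
  list(
    etc = experimentDesign(
      list(list(name = "etcA", variant = modelVariant("basic",
                "etc_inhibitor"), params = etcPar,
                concentrations = concE)),
      nPlates = 4L, nTechReps = nTechReps, cellsPerWell = cellsPerWell,
      sigmaCell = sigmaCell, controlWells = controlWells),
    uncoupler = experimentDesign(
      list(list(name = "uncA", variant = modelVariant("pk_decay",
                "uncoupler"), params = uncPar,
                concentrations = concU)),
      nPlates = 4L, nTechReps = nTechReps, cellsPerWell = cellsPerWell,
      sigmaCell = sigmaCell, controlWells = controlWells),
    atp = experimentDesign(
      list(list(name = "atpA",
                variant = modelVariant("conc_dep_decay",
                "atp_synthase_inhibitor", lowBlock = 1:4),
                params = atpPar, concentrations = concA)),
      nPlates = 3L, nTechReps = nTechReps, cellsPerWell = cellsPerWell,
      sigmaCell = sigmaCell, controlWells = controlWells))
}

setMethod("show", "ExperimentDesign", function(object) {
  cat(sprintf(
    "ExperimentDesign: %d compound(s), %d plate(s) x %d tech rep(s), %d time point(s)\n",
    length(object@compounds), object@nPlates, object@nTechReps,
    length(object@times)))
  for (cc in object@compounds)
    cat(sprintf("  %s [%s/%s], %d concentrations\n", cc$name,
                cc$variant@name, cc$variant@targetClass,
                length(cc$concentrations)))
})
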