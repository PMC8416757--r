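## Pipeline configuration schema: top-level fields and the stages the
## runner knows, in execution order.
.pipelineStages <- c("generate", "preprocess", "fit", "profile",
                     "bootstrap", "predict_ratios", "compare_ratios")

.knownVariants <- c("basic", "pk_decay", "pk_decay_leakage",
                    "conc_dep_decay")
.knownPanels <- c("etc", "uncoupler", "atp")

#' Read a pipeline configuration file
#'
#' YAML or JSON, chosen by extension; see [runPipeline()] for the
#' recognized fields.
#'
#' @param path config file path.
#' @return the configuration list.
#' @export
readPipelineConfig <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
  else if (ext == "json")
    jsonlite::read_json(path, simplifyVector = TRUE)
  else stop("unsupported config extension: ", ext)
}

.validatePipelineConfig <- function(config) {
  if (is.null(config$outdir))
    stop("pipeline config: field 'outdir' is required")
  if (is.null(config$seed)) stop("pipeline config: field 'seed' is required")
  stages <- config$stages %||% .pipelineStages
  bad <- setdiff(stages, .pipelineStages)
  if (length(bad))
    stop("pipeline config: unknown stage(s) in 'stages': ",
         paste(bad, collapse = ", "))
  if ("generate" %in% stages) {
    panel <- config$generate$panel
    if (is.null(panel) || !panel %in% .knownPanels)
      stop("pipeline config: 'generate$panel' must be one of ",
           paste(.knownPanels, collapse = ", "))
  } else if (any(c("preprocess", "bootstrap") %in% stages)) {
    if (is.null(config$input$cells_csv))
      stop("pipeline config: 'input$cells_csv' required when the ",
           "generate stage is disabled")
    if (!file.exists(config$input$cells_csv))
      stop("pipeline config: 'input$cells_csv' does not exist: ",
           config$input$cells_csv)
  }
  if (!is.null(config$fit$variant) &&
      !config$fit$variant %in% .knownVariants)
    stop("pipeline config: unknown 'fit$variant': ",
         config$fit$variant)
  invisible(stages)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.writeJSON <- function(x, path)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order -- generate (synthetic panel),
#' preprocess, fit, profile, bootstrap, predict_ratios,
#' compare_ratios -- writing per-stage artifacts (CSV for tables, JSON
#' for structured results) plus a manifest with the seed, package
#' version, configuration and MD5 checksum of every artifact.
#' Identical configuration and seed give identical artifact checksums.
#'
#' Recognized configuration fields:
#' \describe{
#'   \item{outdir, seed, stages}{output directory, global seed, stage
#'     subset (default: all).}
#'   \item{generate}{`panel` (one of `"etc"`, `"uncoupler"`, `"atp"`),
#'     optional `cells_per_well`, `sigma_cell`, `n_tech_reps`.}
#'   \item{input}{`cells_csv` when the generate stage is disabled.}
#'   \item{fit}{`variant`, `target_class`, `low_block`, `free`,
#'     `n_starts`, `sigma_floor`, `compound`.}
#'   \item{profile}{`parameters` (names to profile), `confidence`.}
#'   \item{bootstrap}{`n_boot`.}
#'   \item{ratios}{`pairs` (list of `c(T1, T2)`), `param`.}
#'   \item{compare}{`measured_csv` with columns `compound`, `T1_h`,
#'     `T2_h`, `replicate_ratio`.}
#' }
#'
#' @param config configuration list or path to a YAML/JSON file.
#' @return the manifest list, invisibly.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- readPipelineConfig(config)
  stages <- .validatePipelineConfig(config)
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)
  artifacts <- character(0)
  log <- function(...) message("[pipeline] ", sprintf(...))
  addArtifact <- function(path) artifacts <<- c(artifacts, path)

  cells <- NULL; truth <- NULL; cs <- NULL
  fitRes <- NULL; problem <- NULL; profiles <- list()
  bootRes <- NULL; ratios <- NULL

  if ("generate" %in% stages) {
    log("generate: panel '%s'", config$generate$panel)
    panels <- makeStudyPanels(
      cellsPerWell = config$generate$cells_per_well %||% 300,
      nTechReps = config$generate$n_tech_reps %||% 2L,
      sigmaCell = config$generate$sigma_cell %||% 0.35)
    design <- panels[[config$generate$panel]]
    gen <- generateExperiment(design, seed = seed)
    cells <- gen$cells; truth <- gen$truth
    p <- file.path(outdir, "cells.csv")
    write.csv(cells, p, row.names = FALSE); addArtifact(p)
  } else if (!is.null(config$input$cells_csv)) {
    cells <- read.csv(config$input$cells_csv, stringsAsFactors = FALSE)
  }

  if ("preprocess" %in% stages) {
    if (is.null(cells)) stop("preprocess stage: no cells available")
    log("preprocess: %d cell rows", nrow(cells))
    cs <- preprocessCells(cells)
    p <- file.path(outdir, "conditions.csv")
    writeConditionCSV(cs, p); addArtifact(p)
  }

  needFit <- any(c("fit", "profile", "bootstrap", "predict_ratios",
                   "compare_ratios") %in% stages)
  if (needFit) {
    if (is.null(cs)) stop("fit stage: no preprocessed conditions")
    fc <- config$fit %||% list()
    compound <- fc$compound %||%
      setdiff(unique(conditionData(cs)$compound), "DMSO")[1]
    variant <- modelVariant(fc$variant %||% "basic",
                            fc$target_class %||% "etc_inhibitor",
                            lowBlock = as.integer(fc$low_block %||% 1:4))
    basePar <- if (!is.null(truth))
      truth$compounds[[compound]]$params else modelParameters()
    free <- fc$free %||% c("VA", "KA", "D0", "c1", "c0", "r")
    problem <- fitProblem(cs, variant, basePar, free = free,
                          compound = compound,
                          nStarts = fc$n_starts %||% 100L,
                          seed = seed,
                          sigmaFloor = fc$sigma_floor %||% 0.05)
    log("fit: compound '%s', %d starts", compound, problem@nStarts)
    fitRes <- fitMultistart(problem)
    p <- file.path(outdir, "fit.json")
    .writeJSON(list(compound = compound, variant = variant@name,
                    theta = as.list(fitRes@theta), cost = fitRes@cost,
                    per_condition_ssr =
                      as.list(fitRes@perConditionSSR),
                    converged = fitRes@converged, seed = seed), p)
    addArtifact(p)
    traj <- lapply(seq_along(unique(conditionData(cs)$concentration[
      conditionData(cs)$compound == compound])), function(i)
        simulateTrajectory(variant, fitRes@params, i,
                           times = sort(unique(
                             conditionData(cs)$time_h))))
    p <- file.path(outdir, "fit_trajectories.csv")
    exportTrajectories(traj, p, compound, seq_along(traj))
    addArtifact(p)
  }

  if ("profile" %in% stages) {
    for (nm in config$profile$parameters %||% "gamma") {
      log("profile: %s", nm)
      pc <- profileParameter(problem, nm, fit = fitRes,
                             confidence =
                               config$profile$confidence %||% 0.95)
      profiles[[nm]] <- pc
      p <- file.path(outdir, sprintf("profile_%s.csv", nm))
      write.csv(data.frame(value = pc@grid, npl = pc@npl), p,
                row.names = FALSE)
      addArtifact(p)
    }
    p <- file.path(outdir, "profiles.json")
    .writeJSON(lapply(profiles, function(pc)
      list(name = pc@name, mle = pc@mle, ci_low = pc@ciLow,
           ci_high = pc@ciHigh, identifiable = pc@identifiable,
           threshold = pc@threshold)), p)
    addArtifact(p)
  }

  if ("bootstrap" %in% stages) {
    if (is.null(cells)) stop("bootstrap stage: no cells available")
    nb <- config$bootstrap$n_boot %||% 200L
    log("bootstrap: %d samples", nb)
    bootRes <- bootstrapCI(cells, problem, fitRes, nBoot = nb,
                           seed = seed)
    p <- file.path(outdir, "bootstrap.json")
    .writeJSON(list(n_boot = bootRes@nBoot, n_failed = bootRes@nFailed,
                    ci95 = as.data.frame(bootRes@ci95),
                    ci99 = as.data.frame(bootRes@ci99)), p)
    addArtifact(p)
    p <- file.path(outdir, "bootstrap_estimates.csv")
    write.csv(bootRes@estimates, p, row.names = FALSE); addArtifact(p)
  }

  if ("predict_ratios" %in% stages) {
    param <- config$ratios$param %||% "gamma"
    pairs <- config$ratios$pairs %||% list(c(2, 8), c(2, 24), c(8, 24))
    gammaHat <- fitRes@theta[[param]]
    ratios <- lapply(pairs, function(pr) {
      q <- ratioQuantity(pr[1], pr[2], param = param)
      out <- list(T1 = pr[1], T2 = pr[2],
                  ratio = predictRatio(gammaHat, pr[1], pr[2]))
      if (!is.null(profiles[[param]])) {
        ci <- profileCI(profiles[[param]])
        out$pl_ci95 <- sort(predictRatio(ci, pr[1], pr[2]))
      }
      if (!is.null(bootRes) && param %in% colnames(bootRes@ci95)) {
        out$boot_ci95 <- sort(predictRatio(bootRes@ci95[, param],
                                           pr[1], pr[2]))
        out$boot_ci99 <- sort(predictRatio(bootRes@ci99[, param],
                                           pr[1], pr[2]))
      }
      out
    })
    log("predict_ratios: %d pairs", length(ratios))
    p <- file.path(outdir, "ratios.json")
    .writeJSON(ratios, p); addArtifact(p)
  }

  if ("compare_ratios" %in% stages) {
    if (is.null(config$compare$measured_csv))
      stop("compare_ratios stage: 'compare$measured_csv' required")
    meas <- read.csv(config$compare$measured_csv,
                     stringsAsFactors = FALSE)
    comp <- lapply(ratios, function(rt) {
      mi <- meas$replicate_ratio[meas$T1_h == rt$T1 &
                                 meas$T2_h == rt$T2]
      compareMeasuredRatios(
        list(ratio = rt$ratio, plCI95 = rt$pl_ci95,
             bootCI95 = rt$boot_ci95, bootCI99 = rt$boot_ci99),
        mi)
    })
    log("compare_ratios: %d measured sets", length(comp))
    p <- file.path(outdir, "ratio_comparison.json")
    .writeJSON(comp, p); addArtifact(p)
  }

  manifest <- list(
    package = "mmpdyn",
    version = as.character(utils::packageVersion("mmpdyn")),
    seed = seed, stages = stages, config = config,
    checksums = as.list(tools::md5sum(sort(artifacts))))
  .writeJSON(manifest, file.path(outdir, "manifest.json"))
  invisible(manifest)
}
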