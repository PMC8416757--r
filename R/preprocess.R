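#' Geometric mean of single-cell intensities in a well
#'
#' Per-well summary `exp(mean(log(x)))`, appropriate for the
#' approximately log-normal distribution of integrated single-cell dye
#' intensities. Cells with non-positive or missing intensity must be
#' filtered upstream (see [preprocessCells()]).
#'
#' @param x positive intensities.
#' @return the geometric mean.
#' @examples
#' wellGeometricMean(c(1, 10, 100))  # 10
#' @export
wellGeometricMean <- function(x) {
  if (!length(x)) stop("empty intensity collection")
  if (any(!is.finite(x)) || any(x <= 0))
    stop("all intensities must be positive and finite")
  exp(mean(log(x)))
}

#' Normalize treated well summaries to the vehicle control
#'
#' Divides the treated geometric-mean series by the DMSO control
#' series from the same plate, time point by time point. Because dye
#' quenching and uptake drift act multiplicatively and identically on
#' all wells of a plate, the ratio cancels plate drift exactly.
#'
#' @param treated,control per-time geometric means from the same
#'   plate, on aligned time grids.
#' @return the elementwise ratio.
#' @export
normalizeToControl <- function(treated, control) {
  if (length(treated) != length(control))
    stop("treated and control series must share the time grid")
  if (any(!is.finite(control)) || any(control <= 0))
    stop("control series must be positive at every time point")
  treated / control
}

#' Aggregate normalized replicate series
#'
#' Arithmetic mean and standard error of the mean across biological
#' replicates, per time point.
#'
#' @param replicates matrix (replicates x times) or list of aligned
#'   numeric vectors.
#' @return list with elements `mean`, `se` (NA when a single
#'   replicate is supplied) and `n`.
#' @export
aggregateReplicates <- function(replicates) {
  if (is.list(replicates)) {
    len <- lengths(replicates)
    if (length(unique(len)) != 1L)
      stop("replicate series must be aligned on one time grid")
    replicates <- do.call(rbind, replicates)
  }
  n <- nrow(replicates)
  if (n < 1L) stop("at least one replicate required")
  m <- colMeans(replicates)
  se <- if (n >= 2L) apply(replicates, 2, sd) / sqrt(n)
        else rep(NA_real_, ncol(replicates))
  list(mean = m, se = se, n = n)
}

#' Construct a ConditionSet
#'
#' @param data data.frame with columns `compound`, `concentration`,
#'   `time_h`, `mean_norm`, `se_norm`, `n_rep`.
#' @return a [ConditionSet-class] object.
#' @export
conditionSet <- function(data) {
  data <- data[order(data$compound, data$concentration, data$time_h), ,
               drop = FALSE]
  rownames(data) <- NULL
  new("ConditionSet", data = data)
}

#' @describeIn conditionSet accessor for the underlying data.frame.
#' @param x a [ConditionSet-class] object.
#' @export
conditionData <- function(x) x@data

#' Read/write condition summaries as CSV
#'
#' Columns: `compound`, `concentration`, `time_h`, `mean_norm`,
#' `se_norm`, `n_rep`.
#'
#' @param x a [ConditionSet-class] object.
#' @param path CSV path.
#' @return `readConditionCSV` returns a [ConditionSet-class];
#'   `writeConditionCSV` the path, invisibly.
#' @export
writeConditionCSV <- function(x, path) {
  write.csv(conditionData(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeConditionCSV
#' @export
readConditionCSV <- function(path) {
  conditionSet(read.csv(path, stringsAsFactors = FALSE))
}

## Required columns of a single-cell intensity table.
.cellCols <- c("plate_id", "well_id", "compound", "concentration",
               "time_h", "cell_id", "intensity", "is_control")

.checkCellTable <- function(cells) {
  miss <- setdiff(.cellCols, names(cells))
  if (length(miss))
    stop("single-cell table lacks columns: ", paste(miss, collapse = ", "))
  invisible(TRUE)
}

## Grouped geometric means: exp of group-mean of logs, via rowsum.
.groupGeomean <- function(logI, key) {
  s <- rowsum(logI, key)
  n <- rowsum(rep(1, length(logI)), key)
  setNames(exp(s[, 1] / n[, 1]), rownames(s))
}

#' Preprocess a single-cell intensity table into condition summaries
#'
#' Implements the quantification chain: drop cells with non-positive
#' or missing intensity (count reported via a message), pool technical
#' replicate wells within a plate, take per-(plate, condition, time)
#' geometric means, divide treated by vehicle-control means from the
#' same plate and time point, then aggregate across plates to a mean
#' and standard error per compound, concentration and time.
#'
#' @param cells data.frame with columns `plate_id`, `well_id`,
#'   `compound`, `concentration`, `time_h`, `cell_id`, `intensity`,
#'   `is_control`.
#' @return a [ConditionSet-class] object.
#' @seealso [generateExperiment()] for tables with this layout.
#' @export
preprocessCells <- function(cells) {
  .checkCellTable(cells)
  bad <- !is.finite(cells$intensity) | cells$intensity <= 0
  if (any(bad)) {
    message(sum(bad), " cell(s) with non-positive or missing intensity dropped")
    cells <- cells[!bad, , drop = FALSE]
  }
  if (!nrow(cells)) stop("no usable cells")
  logI <- log(cells$intensity)

  ctrl <- cells$is_control
  keyC <- paste(cells$plate_id[ctrl], cells$time_h[ctrl], sep = "\r")
  gmC <- .groupGeomean(logI[ctrl], keyC)

  tr <- !ctrl
  keyT <- paste(cells$plate_id[tr], cells$compound[tr],
                cells$concentration[tr], cells$time_h[tr], sep = "\r")
  gmT <- .groupGeomean(logI[tr], keyT)

  ## map keys back to exact metadata via first occurrence (string
  ## round-trips would lose floating-point precision)
  idx <- match(names(gmT), keyT)
  trRows <- which(tr)[idx]
  plate <- cells$plate_id[trRows]
  compound <- cells$compound[trRows]
  conc <- cells$concentration[trRows]
  time <- cells$time_h[trRows]
  ctrlKey <- paste(plate, time, sep = "\r")
  if (any(!ctrlKey %in% names(gmC)))
    stop("missing vehicle control for some plate/time combinations")
  norm <- unname(gmT) / unname(gmC[ctrlKey])

  condKey <- paste(compound, conc, time, sep = "\r")
  n <- rowsum(rep(1, length(norm)), condKey)[, 1]
  mean_norm <- rowsum(norm, condKey)[, 1] / n
  ## two-pass variance: the one-pass formula loses all precision when
  ## replicates agree to near machine accuracy
  dev2 <- rowsum((norm - mean_norm[condKey])^2, condKey)[, 1]
  v <- dev2 / pmax(n - 1, 1)
  se <- ifelse(n >= 2, sqrt(v / n), NA_real_)

  idx2 <- match(names(mean_norm), condKey)
  conditionSet(data.frame(
    compound = compound[idx2],
    concentration = conc[idx2],
    time_h = time[idx2],
    mean_norm = unname(mean_norm),
    se_norm = unname(se),
    n_rep = unname(as.integer(n)),
    stringsAsFactors = FALSE))
}

setMethod("show", "ConditionSet", function(object) {
  d <- object@data
  cat(sprintf("ConditionSet: %d compound(s), %d condition(s), %d rows\n",
              length(unique(d$compound)),
              nrow(unique(d[c("compound", "concentration")])), nrow(d)))
})
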