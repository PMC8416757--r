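#' Construct a model parameter set
#'
#' Creates a validated [ModelParameters-class] object. Defaults follow
#' the model's reference configuration: oxygen supply fixed at 0.6,
#' uncoupler constants `VU = KU = 1`, and unit values for the oxygen
#' constants `KE`, `KEi` (their scale is absorbed into the arbitrary
#' units of the intensity readout); `VA = 1.2`, `KA = 1`, `Cf = 1` give
#' a baseline MMP steady state of 1.
#'
#' @param supply oxygen supply rate (a.u./h).
#' @param KE,KEi maximal oxygen consumption rate and ETC-inhibitor
#'   half-inhibition concentration.
#' @param Cf OCR-to-proton-flux scaling.
#' @param VA,KA,KAi ATP-synthesis depletion kinetics and inhibitor
#'   half-inhibition concentration.
#' @param VU,KU uncoupler flux kinetics (fixed at 1 by convention).
#' @param r dimensionless time-scale factor.
#' @param c1,c0 observation scaling (intensity = c1 * Psi + c0).
#' @param alpha ion-leakage rate (1/h), leakage variant only.
#' @param gamma pharmacokinetic decay rate (1/h).
#' @param gammaL,gammaH decay rates of the low/high dose blocks for
#'   concentration-dependent decay.
#' @param D0 effective applied-dose concentrations, ascending dose
#'   index.
#' @return a [ModelParameters-class] object.
#' @examples
#' p <- modelParameters(VA = 1.2, KA = 1)
#' steadyState(p)
#' @export
modelParameters <- function(supply = 0.6, KE = 1, KEi = 1, Cf = 1,
                            VA = 1.2, KA = 1, KAi = 1, VU = 1, KU = 1,
                            r = 1, c1 = 1, c0 = 0, alpha = 0,
                            gamma = 0, gammaL = 0, gammaH = 0,
                            D0 = numeric(0)) {
  new("ModelParameters", supply = supply, KE = KE, KEi = KEi, Cf = Cf,
      VA = VA, KA = KA, KAi = KAi, VU = VU, KU = KU, r = r, c1 = c1,
      c0 = c0, alpha = alpha, gamma = gamma, gammaL = gammaL,
      gammaH = gammaH, D0 = as.numeric(D0))
}

#' Construct a model variant descriptor
#'
#' @param name variant name: `"basic"`, `"pk_decay"`,
#'   `"pk_decay_leakage"` or `"conc_dep_decay"`.
#' @param targetClass inhibitor class the compound belongs to:
#'   `"etc_inhibitor"`, `"atp_synthase_inhibitor"` or `"uncoupler"`.
#' @param lowBlock dose indices forming the low-concentration block of
#'   the concentration-dependent decay variant.
#' @return a [ModelVariant-class] object.
#' @examples
#' modelVariant("pk_decay", "uncoupler")
#' @export
modelVariant <- function(name = "basic",
                         targetClass = c("etc_inhibitor",
                                         "atp_synthase_inhibitor",
                                         "uncoupler"),
                         lowBlock = 1:4) {
  targetClass <- match.arg(targetClass)
  new("ModelVariant", name = name, targetClass = targetClass,
      lowBlock = as.integer(lowBlock))
}

## Names addressable through getParam/setParam; "D0[i]" addresses the
## i-th effective concentration.
.scalarParamNames <- c("supply", "KE", "KEi", "Cf", "VA", "KA", "KAi",
                       "VU", "KU", "r", "c1", "c0", "alpha", "gamma",
                       "gammaL", "gammaH")

.parseD0Name <- function(name) {
  n <- nchar(name)
  if (n > 4L && substr(name, 1L, 3L) == "D0[" &&
      substr(name, n, n) == "]")
    as.integer(substr(name, 4L, n - 1L))
  else NA_integer_
}

#' Get or set a single parameter by name
#'
#' Free parameters in calibration are addressed by name; entries of the
#' effective-concentration vector use the form `"D0[i]"`.
#'
#' @param params a [ModelParameters-class] object.
#' @param name parameter name.
#' @param value replacement value.
#' @return `getParam` returns a numeric scalar; `setParam` returns the
#'   updated object (without re-running validity, so intermediate
#'   states during optimization are allowed; use [methods::validObject()]
#'   to re-check).
#' @export
getParam <- function(params, name) {
  if (name %in% .scalarParamNames) return(slot(params, name))
  i <- .parseD0Name(name)
  if (!is.na(i)) {
    if (i > length(params@D0)) stop("D0 index out of range: ", name)
    return(params@D0[i])
  }
  stop("unknown parameter name: ", name)
}

#' @rdname getParam
#' @export
setParam <- function(params, name, value) {
  if (name %in% .scalarParamNames) {
    slot(params, name) <- as.numeric(value)
    return(params)
  }
  i <- .parseD0Name(name)
  if (!is.na(i)) {
    if (i > length(params@D0)) stop("D0 index out of range: ", name)
    params@D0[i] <- as.numeric(value)
    return(params)
  }
  stop("unknown parameter name: ", name)
}

## Apply a named theta vector (free parameters) onto a parameter set.
applyTheta <- function(params, theta) {
  for (nm in names(theta)) params <- setParam(params, nm, theta[[nm]])
  params
}

#' Serialize parameters and variant to a flat config file
#'
#' Writes/reads a flat key-value representation (YAML or JSON chosen by
#' file extension). `D0` round-trips as a vector; the variant's name and
#' target class are stored as strings.
#'
#' @param params a [ModelParameters-class] object.
#' @param variant optional [ModelVariant-class] stored alongside.
#' @param path file path ending in `.yaml`, `.yml` or `.json`.
#' @return `readModelConfig` returns a list with elements `params` and
#'   (when present in the file) `variant`.
#' @export
writeModelConfig <- function(params, path, variant = NULL) {
  x <- lapply(.scalarParamNames, function(s) slot(params, s))
  names(x) <- .scalarParamNames
  x$D0 <- params@D0
  if (!is.null(variant)) {
    x$variant <- variant@name
    x$target_class <- variant@targetClass
    x$low_block <- variant@lowBlock
  }
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(x, path)
  } else if (ext == "json") {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else stop("unsupported config extension: ", ext)
  invisible(path)
}

#' @rdname writeModelConfig
#' @export
readModelConfig <- function(path) {
  ext <- tolower(tools::file_ext(path))
  x <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
       else if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
       else stop("unsupported config extension: ", ext)
  args <- x[intersect(names(x), .scalarParamNames)]
  args$D0 <- as.numeric(unlist(x$D0))
  params <- do.call(modelParameters, args)
  out <- list(params = params)
  if (!is.null(x$variant))
    out$variant <- modelVariant(x$variant, x$target_class,
                                lowBlock = if (is.null(x$low_block)) 1:4
                                           else as.integer(unlist(x$low_block)))
  out
}

setMethod("show", "ModelParameters", function(object) {
  ss <- tryCatch(steadyState(object), error = function(e) NULL)
  cat("ModelParameters\n")
  cat(sprintf("  supply=%.3g KE=%.3g KEi=%.3g Cf=%.3g\n",
              object@supply, object@KE, object@KEi, object@Cf))
  cat(sprintf("  VA=%.3g KA=%.3g KAi=%.3g VU=%.3g KU=%.3g r=%.3g\n",
              object@VA, object@KA, object@KAi, object@VU, object@KU,
              object@r))
  cat(sprintf("  c1=%.3g c0=%.3g alpha=%.3g gamma=%.3g gammaL=%.3g gammaH=%.3g\n",
              object@c1, object@c0, object@alpha, object@gamma,
              object@gammaL, object@gammaH))
  cat(sprintf("  D0: %s\n", if (length(object@D0))
    paste(signif(object@D0, 3), collapse = " ") else "(none)"))
  if (!is.null(ss))
    cat(sprintf("  steady state: O=%.4g Psi=%.4g\n", ss["O"], ss["Psi"]))
})

setMethod("show", "ModelVariant", function(object) {
  cat(sprintf("ModelVariant '%s' (%s)\n", object@name, object@targetClass))
  if (object@name == "conc_dep_decay")
    cat("  low block:", paste(object@lowBlock, collapse = " "), "\n")
})
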