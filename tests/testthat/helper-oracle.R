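## Independent R-level implementation of the model equations, used as
## an oracle against the package's compiled integrator. Deliberately
## written from the equations, not from the package internals.

oracleSimulate <- function(variant, params, doseIndex, times,
                           rtol = 1e-11, atol = 1e-13) {
  p <- params
  psio <- p@supply * p@Cf * p@KA / (p@VA - p@supply * p@Cf)
  D0 <- if (doseIndex == 0) 0 else p@D0[doseIndex]
  g <- if (doseIndex == 0 || variant@name == "basic") 0
  else if (variant@name == "conc_dep_decay") {
    if (doseIndex %in% variant@lowBlock) p@gammaL else p@gammaH
  } else p@gamma
  leak <- variant@name == "pk_decay_leakage"
  rhs <- function(t, y, parms) {
    D <- D0 * exp(-g * t)
    DE <- if (variant@targetClass == "etc_inhibitor") D else 0
    DA <- if (variant@targetClass == "atp_synthase_inhibitor") D else 0
    DU <- if (variant@targetClass == "uncoupler") D else 0
    O <- y[1]; Psi <- y[2]
    cons <- p@KE * O * p@KEi / (p@KEi + DE)
    dep <- p@VA * Psi / (p@KA + Psi) * p@KAi / (p@KAi + DA)
    if (leak) {
      dO <- p@r * (p@supply - p@KE * O)
      dPsi <- p@r * (p@supply * p@Cf - dep - p@alpha * (Psi - psio))
    } else {
      dO <- p@r * (p@supply - cons)
      dPsi <- p@r * (p@Cf * cons - dep - p@VU * DU / (p@KU + DU) * Psi)
    }
    list(c(dO, dPsi))
  }
  y0 <- c(p@supply / p@KE, psio)
  tt <- if (times[1] > 0) c(0, times) else times
  out <- deSolve::ode(y = y0, times = tt, func = rhs, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol)
  if (times[1] > 0) out <- out[-1, , drop = FALSE]
  list(times = times, O = unname(out[, 2]), Psi = unname(out[, 3]),
       y = unname(p@c1 * out[, 3] + p@c0))
}

## Random admissible parameter set (moderate, well-scaled ranges).
randomParams <- function(nDoses = 3) {
  Cf <- runif(1, 0.5, 2)
  VA <- runif(1, 1.2, 3) * 0.6 * Cf  # keeps VA > supply*Cf
  modelParameters(
    KE = exp(runif(1, log(0.2), log(5))),
    KEi = exp(runif(1, log(0.2), log(5))),
    Cf = Cf, VA = VA,
    KA = exp(runif(1, log(0.3), log(3))),
    KAi = exp(runif(1, log(0.3), log(3))),
    r = exp(runif(1, log(0.3), log(3))),
    c1 = runif(1, 0.5, 2), c0 = runif(1, -0.2, 0.4),
    alpha = runif(1, 0.05, 1), gamma = runif(1, 0.02, 0.8),
    gammaL = runif(1, 0.2, 1), gammaH = runif(1, 0.01, 0.2),
    D0 = sort(exp(runif(nDoses, log(0.05), log(20)))))
}

allVariants <- function(lowBlock = 1:2) list(
  basic_etc = modelVariant("basic", "etc_inhibitor"),
  basic_atp = modelVariant("basic", "atp_synthase_inhibitor"),
  basic_unc = modelVariant("basic", "uncoupler"),
  pk_unc = modelVariant("pk_decay", "uncoupler"),
  pk_atp = modelVariant("pk_decay", "atp_synthase_inhibitor"),
  leak_atp = modelVariant("pk_decay_leakage", "atp_synthase_inhibitor"),
  concdep_atp = modelVariant("conc_dep_decay", "atp_synthase_inhibitor",
                             lowBlock = lowBlock))
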