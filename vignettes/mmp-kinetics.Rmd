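---
title: "Modelling mitochondrial membrane potential dynamics under OXPHOS inhibition"
author: "mmpdyn authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling mitochondrial membrane potential dynamics under OXPHOS inhibition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmpdyn)
```

## The model

`mmpdyn` models the mitochondrial membrane potential (MMP, $\Psi$) of
cultured cells exposed to inhibitors of oxidative phosphorylation, as
read out by an MMP-sensitive dye (rhodamine 123) in hourly live-cell
imaging. The core is a two-state ODE system in the oxygen level $[O]$
and the MMP:

$$
\frac{d[O]}{dt} = r\left(s - K_E [O]\,
  \frac{K_{Ei}}{K_{Ei} + [D_E]}\right),
$$

$$
\frac{d\Psi}{dt} = r\left(C_f\,\mathrm{OCR}
  - V_A \frac{\Psi}{K_A + \Psi}\,\frac{K_{Ai}}{K_{Ai} + [D_A]}
  - V_U \frac{[D_U]}{K_U + [D_U]}\,\Psi\right),
$$

where $\mathrm{OCR} = K_E [O]\, K_{Ei}/(K_{Ei} + [D_E])$ is the oxygen
consumption rate. Oxygen is supplied at a constant rate $s = 0.6$
(a.u./h) and consumed by the electron transport chain (ETC), whose
proton pumping builds the MMP in proportion ($C_f$) to the OCR. The MMP
is depleted by ATP synthesis through complex V (Michaelis–Menten in
$\Psi$, half-maximal at $K_A$, maximal rate $V_A$) and, for
protonophore uncouplers, by a carrier-mediated proton backflow
(Michaelis–Menten in the uncoupler concentration with $V_U = K_U = 1$
by convention). The three inhibitor classes act through the three
effective concentrations: ETC inhibitors on $[D_E]$, ATP-synthase
inhibitors on $[D_A]$, uncouplers on $[D_U]$. A dimensionless factor
$r$ rescales time for both equations, so rate parameters are in
arbitrary units.

Before exposure cells are at homeostasis, so every simulation starts
at the analytic steady state $[O]^o = s/K_E$,
$\Psi^o = s C_f K_A / (V_A - s C_f)$, which requires $V_A > s C_f$.
The imaging readout is linear in the MMP, $y = c_1 \Psi + c_0$.

Four variants are provided (`modelVariant()`):

* **basic** — effective concentrations constant after exposure;
* **pk_decay** — exponential pharmacokinetic decay,
  $[D_X](t) = [D_X^o] e^{-\gamma t} H(t)$, describing loss of compound
  to degradation, metabolism or plastic binding;
* **pk_decay_leakage** — decay plus a linear ion-leakage term
  $-\alpha\,(\Psi - \Psi^o)\,H(t)$ in the MMP equation (ATP-synthase
  inhibitors only), which caps hyperpolarization while leaving the
  pre-exposure steady state unchanged; in this variant the oxygen term
  is the constant $s\,C_f$ because no ETC inhibitor is present;
* **conc_dep_decay** — decay with separate rates for a low-dose block
  ($\gamma_L$, by default the four lowest concentrations) and a
  high-dose block ($\gamma_H$), capturing saturable elimination.

The Heaviside gate uses $H(0) = 1$: the effective concentration equals
the applied effective dose at the moment exposure starts. Integration
always begins at $t = 0$ with the post-exposure vector field, so no
event handling is needed; pre-exposure queries of the closed-form
terms are gated at the R level.

### Fixed constants

$s = 0.6$ and $V_U = K_U = 1$ are fixed by convention. $K_E$ and
$K_{Ei}$ are additionally fixed (default 1) because the readout's
arbitrary units absorb them: only $V_A$, $K_A$, the effective
concentrations, $c_1$, $c_0$ and $r$ are estimated by default, plus
$\gamma$ ($\gamma_L$, $\gamma_H$) and $\alpha$ in the extended
variants. All constants remain overridable.

### A note on the oxygen pool

With $[D_E] > 0$ the oxygen equation has a new steady state at which
consumption again balances supply, so after ETC inhibition the model
MMP ultimately recovers as oxygen accumulates, on a time scale
$(K_{Ei} + [D_E])/(r K_E K_{Ei})$. Experimentally, ETC-inhibited cells
show MMP suppression that persists over the whole 23 h window; the
synthetic ETC panel therefore uses a small $K_E$ (a large effective
oxygen reservoir), which makes the suppression effectively permanent
on the measurement window while leaving the baseline OCR at $s$.

## Preprocessing

Raw data are per-cell integrated dye intensities keyed by plate, well,
compound, concentration and time. Because single-cell intensities are
approximately log-normal, wells are summarized by the geometric mean
(`wellGeometricMean()`), after dropping non-positive intensities (the
count is reported). Technical replicate wells of one plate are pooled
before summarizing. Dye quenching and uptake drift act
multiplicatively and plate-wide, so dividing each treated summary by
the same plate's vehicle (DMSO) control summary at the same time point
cancels drift exactly; this is tested as an exact invariance.
Normalized per-plate series are then averaged across plates
(biological replicates) with a standard error
(`aggregateReplicates()`, `preprocessCells()`).

## Calibration

For one condition (compound $\times$ concentration) the weighted SSR
is $R^2 = \sum_i (y^M_i - y^D_i)^2/\sigma_i^2$ over the $n_t = 23$
hourly time points, with $\sigma_i$ the standard error across
replicates; the cost is the negative log-likelihood
$\log L = \sum_j R_j^2/2$ over conditions. Where a standard error is
zero or unavailable (a single replicate, or noise-free synthetic
data — any SE below $10^{-7}$ of the signal is treated as a numerical
zero), the weight falls back to a floor of 5% of the condition's mean
signal (`sigmaFloor`), keeping the objective finite without letting
rounding-level SEs dominate.

Estimation (`fitMultistart()`) is bounded nonlinear least squares on
the stacked weighted residuals with an analytic Jacobian from forward
sensitivity equations: the ODE system is augmented with
$\partial(O,\Psi)/\partial\theta$ for every free parameter, including
the dependence of the steady-state initial condition on $V_A$, $K_A$,
$C_f$ and $K_E$. Parameters that a condition's output cannot depend on
(another dose's $[D^o]$, the inactive block's decay rate, $\alpha$
outside the leakage variant) get exact zero columns. The right-hand
sides, including the sensitivity block, are compiled C code driven
through `deSolve`'s compiled-model interface with the stiff-capable
`lsoda` solver (default tolerances `rtol = 1e-8`, `atol = 1e-10`; the
hyperpolarization phase can be stiff).

The global search draws 100 starting vectors (default) log-uniformly
over each positive parameter's range — four decades around its nominal
value — and linear-uniformly for $c_0$, whose range spans zero. Each
start descends with a Levenberg–Marquardt trust-region iteration under
box bounds (`minpack.lm`); strictly positive parameters are optimized
on the log scale, which conditions rate/affinity/concentration
directions far better than linear stepping. The best-ranked optima are
then *polished*: repeated restarted descents at tightened integration
tolerances (`1e-11`/`1e-13`). Restarting resets the trust-region
damping, which traverses the long, shallow, curved valleys typical of
this model class (correlated changes of $K_A$, $c_1$, $r$ and the dose
scale) orders of magnitude faster than one long run, and the tighter
tolerances push the solver-noise floor below the curvature that
distinguishes those valley points. Equal-cost optima are tie-broken
lexicographically for determinism. Integration failures during
optimization yield a large finite penalty with a gentle pull back into
the feasible box instead of an exception.

`fitJoint()` concatenates several compounds' residuals with $V_A$,
$K_A$ and $r$ (configurable) shared and the observation scaling and
effective concentrations compound-specific; a single compound reduces
exactly to the separate fit, and the joint optimum can never beat the
sum of separate optima (a nested-model inequality used as a test).
Per-compound cost distributions across inhibitor classes are compared
with two-sample two-sided Kolmogorov–Smirnov tests (exact p-values at
the small per-class counts typical of such panels).

## Uncertainty

**Profile likelihood.** `profileParameter()` fixes one parameter on an
adaptive grid walked multiplicatively (default step 1.3) outward from
the MLE, re-optimizing all other parameters warm-started from the
neighbouring grid point, and cuts the resulting NPL curve (twice the
cost) at $\min(\mathrm{NPL}) + \chi^2(\alpha_{CI}, df = 1)$ — 3.8415
at 95%. The crossing is located by interpolation linear in
$\sqrt{\mathrm{NPL} - \min}$, exact for locally quadratic curves. A
side that never crosses within the search range (default six decades)
leaves that bound open and flags the parameter non-identifiable over
that range. Because a single warm-started descent can fail to track
compensating parameter movements across distant basins -- which would
fake a likelihood rise and hence fake identifiability -- every profile
point descends from the walk's warm start *and* from each of the
multistart's distinct leading optima, and any point that would sit
above the threshold is re-checked with a small multistart before the
rise is accepted. Under relative-scale observation the leakage rate
$\alpha$ is the canonical weakly-identified parameter: correlated
changes of the synthesis kinetics, time scale and observation scaling
compensate it over several decades, so its profile stays below the
threshold across a $>10^4$-fold range, while the decay rate $\gamma$
keeps a finite interval within a decade; the acceptance suite
reproduces this dichotomy on synthetic data. `profileDerived()` profiles any smooth
function of the parameters (maximum-likelihood invariance), by
substitution when the quantity is invertible in one parameter — the
pharmacokinetic ratio $R_{T_2/T_1} = e^{-\gamma (T_2 - T_1)}$ is the
canonical case (`ratioQuantity()`) — and by a quadratic-penalty
constraint with escalating weight otherwise. Constant quantities are
flagged degenerate rather than profiled.

**Bootstrap.** `bootstrapCI()` mirrors the two-level structure of the
imaging design: plates (biological replicates) are resampled with
replacement to their original count, then within each selected plate
the single-cell objects pooled over technical replicate wells are
resampled with replacement per condition and time point — vehicle
control wells included, since the normalization is recomputed from the
resampled data. Each bootstrap dataset is pushed through the same
quantification chain and refitted warm-started at the original MLE
(full multistart is available behind a flag for robustness studies).
Failed refits are redrawn, capped at twice the requested number of
samples. Confidence intervals are order-statistic quantiles of the
refitted estimates at 95% and 99%. A coverage study in the acceptance
suite (50 repetitions of 100 bootstrap samples on a scaled-down
uncoupler study) checks that the 95% interval covers the generating
$\gamma$ at its nominal rate.

Model-predicted ratios with their PL and bootstrap intervals can be
compared against externally measured per-replicate concentration
ratios (`compareMeasuredRatios()`), reporting whether the measured
mean falls inside each interval.

## The synthetic-data generator

`generateExperiment()` emulates the statistical structure the analysis
relies on: ground-truth trajectories from a chosen variant; per-cell
intensities drawn log-normally around the well signal (median equal to
the signal; default log-scale SD 0.35); cell counts per well negative
binomial around 300 (dispersion 20); hourly sampling at 23 time points;
multiplicative per-plate drift, log-linear in time (intercept SD 0.05,
slope SD 0.02/h), shared exactly by treated and control wells of a
plate — the assumption the normalization needs; two technical
replicate wells; and a per-plate, per-compound log-normal scale jitter
(SD 10%) applied to treated wells only, reproducing the
compound-specific baseline scatter (roughly 0.8–1.2 after
normalization) seen at non-responsive low concentrations.
`makeStudyPanels()` bundles three designs matching the classes
studied: an ETC panel (basic variant, 10 concentrations, 4 plates), an
uncoupler panel with decay ($\gamma = 0.2$/h, 4 plates) and an
ATP-synthase panel with concentration-dependent decay
($\gamma_L = 0.6 > \gamma_H = 0.04$, 8 concentrations, 3 plates —
the replicate count used for the oligomycin-style design).

What the generator does *not* emulate: image segmentation errors,
cell death and its selection effects, spatial well-position gradients
within a plate, autofluorescence background, or temporal correlation
of a cell's intensity across frames (cells are redrawn independently
per time point). Passing tests on synthetic data therefore validate
the inference machinery under the model's own assumptions — they do
not certify robustness to those unmodelled features of real imaging
data.

## Numerical choices and problem sizes

Defaults: solver `lsoda`, `rtol = 1e-8`, `atol = 1e-10` (tightened
1000-fold during polishing and for oracle comparisons); optimizer
tolerances `ftol = ptol = gtol = 1e-10`, exploration iteration cap
100, polish cap 250 per restart; start ranges four decades around
nominal values; profile walk step 1.3, hard range six decades, two
extra points past the threshold crossing. The test and acceptance
suites run scaled-down designs chosen to finish quickly on one CPU —
typically 3–8 concentrations, 2–4 plates, 5–40 cells per well, and 100
multistart initializations where the full design is the claim under
test — while the generator defaults above describe the full study
geometry. The bootstrap coverage study uses 100 bootstrap samples per
repetition; interval widths at that depth are slightly noisier than at
the 200 samples used for reported intervals, which does not affect the
coverage property being checked.

## Known limitations

* ATP, glucose and glycolysis are not modelled; there is no reverse-mode
  complex V, and leakage is linear in $\Psi - \Psi^o$ rather than a
  Nernst-style nonlinearity — adequate for modest perturbations.
* $\alpha$ is structurally non-identifiable from relative-scale data;
  resolving it requires absolute MMP calibration or fixing parameters
  (any parameter can be frozen via the config/bounds machinery).
* Fitted rate constants are in arbitrary units (the time rescaling
  $r$ and intensity units absorb physical scales); only ratios and
  the decay rates $\gamma$ (1/h) are directly interpretable.
* The bootstrap treats plates as exchangeable; systematic plate-order
  effects (e.g. dye lot changes) would violate that.
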