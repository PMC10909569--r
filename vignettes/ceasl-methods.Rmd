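---
title: "Modelling blood-brain barrier water exchange with contrast-enhanced ASL"
author: "ceasl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling blood-brain barrier water exchange with contrast-enhanced ASL}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ceasl)
```

## The measurement problem

Water exchange across the blood-brain barrier (BBB) is a candidate biomarker
for subtle BBB damage: unlike gadolinium leakage, water crosses the intact
barrier at a measurable rate, so a *rate* estimate can detect degradation
before any contrast agent escapes the vasculature. Arterial spin labelling
(ASL) magnetically labels arterial blood water and follows it into the
tissue, which in principle allows the blood-to-tissue exchange rate
`k_b = PS / v_bw` (units s⁻¹) to be estimated. In practice the intravascular
and extravascular contributions to the ASL difference signal must be
disentangled, and with pre-contrast relaxation times (blood T1 ≈ 1.65 s,
grey-matter tissue T1 ≈ 1.5 s at 3 T) the two compartments are nearly
indistinguishable.

Contrast-enhanced ASL (CE-ASL) solves this by injecting a gadolinium-based
contrast agent (GBCA) that stays intravascular and shortens the blood T1,
pulling the two compartments' relaxation apart. This package implements the
full quantitative machinery for that experiment: the two-compartment kinetic
model and its analytic sensitivity to `k_b`, protocol-optimization sweeps,
T1-error propagation, Monte Carlo precision analysis, GBCA dose/timing
planning, supporting variable-flip-angle T1 mapping, voxel/ROI model
fitting, and a synthetic phantom generator so every step is testable
without scanner data.

## Signal model

For continuous labelling of duration $t_L$, label arriving at arterial
transit time $t_A$ with flow $f$, the difference magnetization (control -
label) of blood and extravascular water follows

$$
\frac{d\,(v_{bw}\Delta m_b)}{dt} = -\frac{v_{bw}\Delta m_b}{T_{1,b}}
  + f\,\Delta m_a(t) - PS\,\Delta m_b,
\qquad
\frac{d\,(v_{ew}\Delta m_e)}{dt} = -\frac{v_{ew}\Delta m_e}{T_{1,e}}
  + PS\,\Delta m_b,
$$

with no venous outflow and no backflow (the label decays before reaching
the veins, and the labelled extravascular fraction stays small). The
arterial inflow is a rectangular bolus
$\Delta m_a = 2\,(M_0/\lambda)\,\alpha\,e^{-t_A/T_{1,b}}$ active for
$t \in [t_A,\,t_A + t_L]$ — the unique inflow consistent with the closed
form below. The measured signal is the volume-weighted sum
$\Delta M = v_{bw}\Delta m_b + v_{ew}\Delta m_e$.

Writing $R_{1,b} = 1/T_{1,b}$, $R_{1,e} = 1/T_{1,e}$, $J = k_b + R_{1,b}$,
$t' = t - t_A$, $s = t' - t_L$ and
$A = 2 f \alpha (M_0/\lambda) e^{-R_{1,b} t_A}$ (with $f$ converted from
mL/min/100 mL to s⁻¹ by division by 6000), the solution collapses to a
single divided-difference form implemented in `asl_signal()`:

$$
\Delta M(t) = A\left[F(J) - k_b\,\frac{F(J) - F(R_{1,e})}{J - R_{1,e}}\right],
\qquad
F(x) = \begin{cases}
(1 - e^{-x t'})/x & t_A \le t \le t_A + t_L\\[2pt]
(e^{-x s} - e^{-x t'})/x & t > t_A + t_L
\end{cases}
$$

and $\Delta M = 0$ before arrival. This form makes the structure of the
model transparent: the signal is exactly linear in $f$, $\alpha$ and $M_0$;
it depends on the exchange rate only through $J$ and the explicit $k_b$
prefactor; and when $T_{1,e} = T_{1,b}$ the divided difference telescopes so
that $\Delta M = A\,F(R_{1,b})$ — independent of $k_b$, which is precisely
why standard (non-contrast) ASL struggles to measure exchange.

**Degenerate denominator.** The divided difference has a removable
singularity at $J = R_{1,e}$. When $|J - R_{1,e}| < 10^{-9}$ s⁻¹ the code
evaluates its analytic limit $F'(J)$ instead, so the model never returns
`NaN`. The sensitivity $\partial\Delta M/\partial k_b$
(`asl_sensitivity_kb()`) is the hand-derived derivative of this expression;
because its divided differences lose one more order to cancellation, it
switches to a second-order Taylor branch already at $|J - R_{1,e}| <
10^{-6}$ s⁻¹. Both code paths are pinned by tests against an independent
ODE integration of the compartment equations (`asl_signal_ode()`, solved
segment-wise across the bolus discontinuities with `deSolve::lsoda` at
`rtol = 1e-10`) and against central finite differences.

## Protocol optimization

`sensitivity_surface()` evaluates $\partial\Delta M/\partial k_b$ at the
single measurement time $t = t_L + \mathrm{PLD}$ over a grid of
post-contrast blood T1 (0.15-1.65 s) and post-labelling delay (0.5-3.0 s),
at the grey-matter operating point ($k_b = 2.65$ s⁻¹, $T_{1,e} = 1.5$ s,
$f = 60$, $t_A = 1.2$ s, $t_L = 2$ s, $\alpha = 0.85$, $\lambda = 0.9$).
The surface is normalized by its maximum *signed* value, so the reported
optimum is exactly 1 and the sign flip at long blood T1 (where extra
exchange now *removes* signal) is visible as negative values; with signed
normalization the equilibrium-T1 point reads about -0.3. The default grid
uses 151 x 151 points (0.01 s steps in T1; the quoted optima are only given
to 0.1 s precision, so this over-resolves them safely).

Two companion sweeps mirror the other panels of the analysis:
`sensitivity_t1e_sweep()` lowers the tissue T1 towards the blood value to
mimic contrast leakage (sensitivity falls approximately linearly and
vanishes at equality), and `sensitivity_kb_sweep()` shows that slower
exchange is intrinsically easier to measure and how the optimal blood T1
drifts from 0.86 s at $k_b = 0.5$ s⁻¹ to 0.77 s at $k_b = 4$ s⁻¹.

## Fitting

`fit_asl()` estimates $(f, t_A, k_b)$ from multi-PLD difference data —
pre- and post-contrast phases jointly, unweighted SSE, relaxation times
fixed — in two configurations:

* **bounded multistart** (default, used by every simulation study): 100
  starting points drawn uniformly between the bounds ($f \in [0, 200]$,
  $t_A \in [0, 2.5]$ s, $k_b \in [0, 5]$ or $[0, 10]$ s⁻¹), each refined by
  box-constrained Levenberg-Marquardt, keeping the lowest SSE. The LM loop
  is compiled (Rcpp) and uses the analytic Jacobian ($\partial/\partial f$
  is the signal over $f$; $\partial/\partial t_A$ and
  $\partial/\partial k_b$ are hand-derived like the sensitivity); a
  `minpack.lm::nls.lm` engine with numerical differentiation is retained
  behind `fit_config(engine = "minpack")` and the test suite checks the two
  land in the same optimum.
* **unconstrained simplex**: a single Nelder-Mead search from
  $(f, t_A, k_b) = (60, 1.0, 1.0)$, matching how in-vivo data are usually
  processed.

Convergence tolerances (relative function tolerance $10^{-10}$, parameter
tolerance $10^{-8}$, at most 2000 evaluations per start) are deliberately
tight so the optimizer never limits accuracy in the recovery tests: 200
random noise-free ground truths are recovered to better than 0.5%.
`fit_asl_volume()` maps the same fit over a masked 4D volume with
voxel-wise $M_0$ and $T_{1,e}$, masks exchange estimates outside
$[0, 10]$ s⁻¹ in the output maps, and `roi_medians()` summarizes regions.

## Error propagation and the extreme-fit screen

`propagate_t1_errors()` generates noise-free signals at truth and refits
with one relaxation time perturbed in the model over a 61-point $\pm 15\%$
grid (0.5% steps — the quoted thresholds carry 0.1% precision, and linear
interpolation between grid points via `threshold_inversion()` recovers
them). The binding (tighter) side of the two asymmetric band crossings is
reported, since accuracy requirements are quoted as single $\pm$ values.
The headline numbers this reproduces: keeping the $k_b$ bias under 10%
requires the pre-contrast blood T1 known to about $\pm 1.5\%$, the
post-contrast blood T1 to $\pm 0.7\%$, and the tissue T1 to $\pm 11\%$.

Monte Carlo replicates (`simulate_noisy_difference()`) add zero-mean
Gaussian noise independently to control and label images at
$\sigma \in \{0.0033, 0.0017, 0.0011\}$ in units of $M_0$; with the
background-suppressed control level at $0.05\,M_0$ these correspond to
control-image SNR 15/30/45. Averaging over an $N$-voxel ROI is modelled by
dividing $\sigma$ by $\sqrt N$ — statistically identical to simulating and
averaging i.i.d. voxels, at a fraction of the cost. Noise is independent
across PLDs (separate acquisitions).

Summaries (`summarize_fits()`) report accuracy as the percent relative
error of the median estimate and precision as CoV = 100 x IQR / truth.
Before summarizing, extreme exchange fits are discarded: a fit is extreme
when $k_b$ lies within 5% *of a screening constraint's own value* (range
$[0, 10]$ s⁻¹ by default, i.e. fits at or above 9.5 s⁻¹). Two readings of
"within 5% of the fit constraints" were possible; the value-relative one is
adopted because a range-based margin (discard $k_b < 0.5$) would throw away
nearly half the sampling distribution when the true rate is 0.5 s⁻¹ and
bias its median upward by ~20%, while the reported behaviour of this study
design is an unbiased median with extreme fractions under 6% everywhere —
and because the voxel-level CoV of ~190% is only attainable when the piles
at the $[0, 5]$ fitting bounds are retained (the IQR then spans the full
constraint width: $100 \times 5 / 2.65 = 189\%$). The per-fit `extreme`
flag on `ceasl_fit` objects keeps the conservative range-based reading as a
diagnostic; study-level screening is the value-relative rule.

The ROI-size feasibility sweep fits with $k_b \in [0, 5]$ s⁻¹ (the
published protocol for that run) and reproduces CoV of roughly 30% for a
500-voxel cortical ROI at SNR 30, 7% for a 10 000-voxel lobe, and ~190% at
the single-voxel level — the quantitative case for regional rather than
voxel-wise exchange mapping.

## GBCA dose planning

Concentration maps to blood relaxation through the fast-exchange relaxivity
relation $R_{1,b}^{post}(t) = R_{1,b}^{pre} + r_1 c_b(t)$
(`gbca_t1b_post()`, defaults $r_1 = 3.4$ s⁻¹mM⁻¹, $R_{1,b}^{pre} = 0.61$
s⁻¹), inverted exactly by `gbca_cb_for_t1()`. Reaching the optimal 0.8 s
requires only ~0.19 mM in blood. Dose fractions scale the concentration
curve pointwise (linear kinetics), and `time_to_target()` reports the
latest washout crossing of a target T1, using monotone cubic interpolation
on the washout limb and, where measured samples end early, extrapolating
with the population parametric input function (two Gaussian bolus passes
plus a sigmoid-gated exponential washout; published population coefficients,
all exposed). The measured input function behind the original dose-timing
figures is not distributed with its study, so those absolute timings (3-48
min depending on dose) are not reproduced here; the package's planner is
validated against a closed-form mono-exponential washout oracle instead and
reproduces the qualitative pattern (a quarter dose reaches 0.8 s within a
few minutes; larger doses take several times longer).

## T1 mapping support

`fit_vfa_t1()` fits the SPGR steady-state signal
$S(\theta) = M_0 \sin\theta\,(1 - E)/(1 - E\cos\theta)$,
$E = e^{-TR/T_1}$, at the four standard flip angles (2°, 5°, 15°, 20°,
TR = 4.75 ms) by Levenberg-Marquardt in log-parameters (positivity without
constraints), initialized from — and cross-checked against — the DESPOT1
linearization. B1 is assumed nominal; no inhomogeneity correction is
applied. `estimate_blood_t1()` implements the sinus-ROI procedure: keep
seed voxels whose T1 dropped at least 20% after contrast, take the 75th
percentile of the pre-contrast T1 as $T_{1,b}^{pre}$, and subtract the 75th
percentile of the pre-post difference (not the percentile of the post map —
the two differ for heterogeneous ROIs). Percentiles interpolate linearly
between order statistics (R type 7) so results are bit-reproducible.
`roi_snr()` is the mean/SD estimator used when no separate noise
measurement exists.

## Synthetic data

`make_phantom()` builds a rectangular multi-region phantom with known
per-region physiology and returns 4D control/label/difference volumes, an
$M_0$ volume, a $T_{1,e}$ map, the region label map and the truth table.
The control/label decomposition is `0.05 M0 ± dM/2` plus independent
Gaussian noise on each image — any static split would do, since only the
difference is modelled; this one keeps both images near the
background-suppressed level. The generator emulates the simulation studies'
conditions (rectangular bolus, instantaneous readout at each PLD,
spatially uncorrelated Gaussian noise, uniform $M_0$) and deliberately does
not model motion, Rician/complex noise, spatial correlation, transit-time
dispersion, vascular artefacts or anatomy. Passing tests on these phantoms
therefore demonstrate correctness of the estimation pipeline under the
stated model, not robustness to real-data artefacts.

## Numerical and design choices

* Flow is stored in mL/min/100 mL at all API boundaries and converted to
  s⁻¹ only inside equations (the published unit convention never states the
  conversion; 1/6000 makes the kinetics dimensionally consistent).
* Start-point sampling is uniform i.i.d. between bounds with a user seed;
  every stochastic routine takes an explicit seed and is bit-reproducible.
* The ODE oracle's compartment volumes ($v_{bw} = 0.05$, $v_{ew} = 0.85$)
  are bookkeeping scalars that cancel exactly in $\Delta M$; the closed
  form never needs them because outflow and backflow are neglected.
* Problem sizes in the shipped studies — 151-251 point sensitivity grids,
  61-point perturbation grids, 2500 Monte Carlo replicates, phantoms of a
  few hundred voxels — were chosen so the full suite runs on a laptop in
  minutes while keeping Monte Carlo sampling error well inside the ±15%
  relative tolerance used for stochastic comparisons.
* Ties in surface normalization are broken by first grid index and flagged
  via the `ties` attribute (none occur on the default grids).

## Known limitations

The model assumes plug flow (no bolus dispersion), no venous outflow, no
backflow of labelled water, an intravascular contrast agent, and
instantaneous acquisition at each PLD. Exchange estimates inherit a strong
dependence on measured blood T1 — the central practical caveat: a 1%
error in post-contrast blood T1 propagates to roughly 10% in $k_b$. Voxels
with transit times longer than the post-contrast PLD lose sensitivity, and
$T_{1,e}$ is treated as independent of $k_b$ although contrast leakage
couples them in vivo.
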