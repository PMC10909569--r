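# ceasl

Kinetic modelling of **contrast-enhanced arterial spin labelling (CE-ASL)**
for quantifying blood-brain barrier (BBB) water exchange.

## The problem

ASL labels arterial blood water magnetically and measures its delivery into
brain tissue. In principle the blood-to-tissue water exchange rate
`k_b = PS / v_bw` (s⁻¹) — a sensitive marker of BBB integrity — can be read
off multi-delay ASL data with a two-compartment model. In practice the
intravascular and extravascular signals are nearly inseparable because blood
and tissue T1 are so similar at 3 T (≈1.65 s vs ≈1.5 s). CE-ASL injects a
gadolinium contrast agent that stays in the blood and shortens blood T1,
pulling the compartments apart and making `k_b` estimable at clinical SNR.

This package is for researchers designing or analysing such experiments. It
provides:

- the closed-form two-compartment CASL difference-signal model `ΔM(t)`
  (`asl_signal()`), an independent ODE-integration oracle
  (`asl_signal_ode()`), and the analytic sensitivity `∂ΔM/∂k_b`
  (`asl_sensitivity_kb()`);
- protocol optimization: the sensitivity surface over post-contrast blood T1
  × post-labelling delay and sweeps over tissue T1 and underlying `k_b`
  (`sensitivity_surface()`, `sensitivity_t1e_sweep()`,
  `sensitivity_kb_sweep()`);
- T1-error propagation into fitted parameters with threshold inversion
  (`propagate_t1_errors()`, `threshold_inversion()`);
- Monte Carlo accuracy/precision studies under the control/label Gaussian
  noise model with √N ROI scaling (`noise_model()`,
  `simulate_noisy_difference()`, `run_mc_study()`, `summarize_fits()`);
- gadolinium dose/timing planning via the relaxivity relation
  `R1_post = R1_pre + r1·cb` and a parametric population input function
  (`gbca_t1b_post()`, `vif_curve()`, `scale_dose()`, `time_to_target()`);
- variable-flip-angle SPGR T1 mapping, blood-ROI T1 extraction and ROI SNR
  (`fit_vfa_t1()`, `estimate_blood_t1()`, `roi_snr()`);
- voxel- and ROI-level model fitting with bounded multistart
  Levenberg-Marquardt (compiled, analytic Jacobian) or the unconstrained
  simplex configuration (`fit_asl()`, `fit_asl_volume()`, `roi_medians()`);
- a synthetic phantom generator with known ground truth so everything is
  testable without scanner data (`make_phantom()`, `make_signal_table()`).

The model: with `J = k_b + 1/T1_b`, `R1e = 1/T1_e`, `t' = t − t_A`,
`s = t' − t_L` and `A = 2 f α (M0/λ) exp(−t_A/T1_b)`,

    ΔM(t) = A · [ F(J) − k_b · (F(J) − F(R1e)) / (J − R1e) ]

with `F(x) = (1 − e^{−x t'})/x` during the bolus and
`F(x) = (e^{−x s} − e^{−x t'})/x` after it (zero before arrival). The
removable singularity at `J = R1e` is evaluated by its analytic limit.

## Worked example

Simulate the standard acquisition (label duration 2 s; pre-contrast PLDs
0.9-2.1 s at blood T1 1.65 s; one post-contrast PLD 1.5 s at the optimized
blood T1 0.8 s), add realistic noise for a 500-voxel cortical ROI at
control-image SNR 30, and estimate flow, transit time and exchange rate:

```r
library(ceasl)

truth  <- physio_params(f = 60, t_a = 1.2, k_b = 2.65,
                        t1_b = 1.65, t1_e = 1.5)
acq    <- acq_params(t_l = 2, alpha = 0.85, m0 = 1)
design <- asl_design()   # 5 pre-contrast PLDs + 1 post-contrast PLD

dat <- make_signal_table(truth, design, acq,
                         noise = noise_model(sigma = 0.0017, n_reps = 1,
                                             roi_size = 500, seed = 1))
fit <- fit_asl(dat, t1_e = 1.5, acq = acq,
               config = fit_config(seed = 2))
fit
#> <ceasl_fit> bounded_multistart on 6 points
#>   f    =   60.530 mL/min/100 mL
#>   t_a  =   1.2213 s
#>   k_b  =   3.3431 1/s
#>   SSE  = 1.408e-08, 100 converged starts
```

Flow and transit time come back within ~2% of the ground truth (f = 60,
t_a = 1.2 s). The exchange-rate estimate of this single noise realization
lands 26% above its truth of 2.65 s⁻¹ — exactly the scatter the Monte Carlo
study predicts for a 500-voxel ROI (CoV ≈ 30%): k_b is the hard parameter,
and a single ROI estimate carries that uncertainty. Where is the protocol
most informative, and how precise is k_b on average?

```r
surf <- sensitivity_surface()
attr(surf, "argmax")
#>  t1b  pld
#> 0.79 1.50

run_mc_study(kb_values = 2.65,
             noise = noise_model(sigma = 0.0017, n_reps = 2500,
                                 roi_size = 500, seed = 100),
             config = fit_config(bounds = list(f = c(0, 200),
                                               t_a = c(0, 2.5),
                                               k_b = c(0, 5)),
                                 seed = 101))[, c("rel_error_kb", "cov_kb")]
#> # A tibble: 1 × 2
#>   rel_error_kb cov_kb
#>          <dbl>  <dbl>
#> 1       -0.830   32.1
```

Sensitivity to `k_b` peaks at post-contrast blood T1 ≈ 0.8 s and PLD 1.5 s,
and at that operating point a 500-voxel ROI yields an essentially unbiased
median `k_b` (relative error −0.8%) with a coefficient of variation of
about 30%.

A thin command-line front end (`inst/cli/ceasl`) exposes the studies as
subcommands (`sensitivity`, `t1-error-study`, `mc-study`, `dose-plan`,
`fit`, `synth`) writing CSV/JSON/NIfTI outputs.

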