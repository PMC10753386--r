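# apqr — closed-loop optogenetic control of cardiac action potentials

Abnormal action-potential (AP) shapes underlie many cardiac disorders, yet
tools to *control* the AP waveform of beating cardiomyocytes — rather than
merely pace them — are scarce. Closed-loop opto-electronic control offers a
way: membrane potential is measured in real time, compared against a
reference AP at 1 kHz, and the error drives light sources that activate a
depolarizing channel (CheRiff-like, blue) and a hyperpolarizing pump
(Jaws-like, red) expressed in the cells. `apqr` is a complete simulation of
such a system for R: a synthetic optogenetic cardiomyocyte monolayer (the
"plant"), the three controllers, the 1-kHz loop engine, waveform generators
and all quantification — so that AP-shape restoration under drug- and
light-induced perturbations, and enforcement of arbitrary AP waveforms, can
be studied end-to-end with no hardware.

It is aimed at cardiac electrophysiologists and control engineers who want
to prototype controller variants, gains or actuator properties before (or
instead of) a wet-lab closed-loop rig.

## The model and the controllers

**Plant.** A phenomenological excitable membrane in physical units,
`V = V_rest + A·u` with `V_rest = −75 mV`, `A = 90 mV`:

- a gated inward excitation current `J_in = h·u²(1−u)/τ_in`, whose gate `h`
  inactivates during the AP (`τ_inact` = 15 ms) and recovers at rest
  (`τ_open` = 100 ms);
- an inward-rectifier-like leak `−u·g(u)`: strong (`1/τ_out`, τ_out = 2 ms)
  below and near rest, weak (`1/τ_close`, τ_close = 180 ms) during the
  plateau, giving a paced APD₉₀ of ≈300 ms at 1 Hz;
- a blue-light-gated conductance `g_blue·a_blue·(V − E_blue)` with apparent
  reversal `E_blue = −11.2 mV` (the plateau reached under a 1-s maximal blue
  pulse), and a voltage-independent red-driven pump current `I_red·a_red`
  calibrated so a maximal red pulse ends at −82 mV;
- drug-like perturbations that scale `τ_close`: `f_4AP = 1.55` prolongs the
  AP (APD₉₀ ≈ 422 ms), `f_cch = 0.195` shortens it (≈ 95 ms).

**Controllers**, executed once per 1-ms tick against a setpoint AP
`AP_ideal` (the average of `lognum` logged beats, or a model waveform):

- **APqr** (adaptive proportional): `e = V_m − AP_ideal[i]`,
  `I_out = (C_m/R_m)·e`, with `R_m` multiplied by `R_m_corr_up` when the
  error overshoots and divided by `R_m_corr_down` when it grows — the gain
  adapts online. Drives injected current or a single LED.
- **APqrPID**: `PID = K_P·e + K_I·Σe + K_D·ê′`, where `ê′` is the
  least-squares slope of the last `l = 10` errors. A positive PID drives the
  red LED, a negative one the blue LED (absolute value), and blue is only
  permitted while `V_m` is below the blue actuator's plateau potential.
- **APqrLE**: the PID core fed by a file- or generator-defined model AP,
  plus 10-ms blue pacing pulses at 1 Hz; correction starts at the first
  detected upstroke and also enforces the model's resting potential between
  APs.

## Worked example

Restore the AP shape of a monolayer whose repolarization has been slowed by
a 4AP-like perturbation, using both LEDs:

```r
library(apqr)

plant <- plant_params()           # calibrated synthetic monolayer
sc <- scenario_dual_fourap(plant) # log 5 beats, pause 10, correct 10
sc$quality_on
#> V_m error: n = 2691, median -0.02 mV, 100.0% within +/-2.5 mV, max 0.2 mV
sc$quality_off
#> V_m error: n = 3807, median 13.96 mV, 12.3% within +/-2.5 mV, max 35.3 mV
```

With the controller off, the perturbed beats deviate from the reference AP
by up to 35 mV and only 12% of the error samples (measured between the
moment of maximal upstroke velocity and 90% repolarization of each beat)
stay within ±2.5 mV; with the controller on, every sample does, and the
median residual error is −0.02 mV. Enforcing an arbitrary waveform
instead:

```r
t01 <- triangular_model(0.1)      # −68 mV → 12 mV at 20 mV/ms, down at 0.1 mV/ms
log <- run_enforcement(plant, pid_gains(), t01, n_beats = 6)
enforcement_quality(log)
#> V_m error: n = 4000, median 0.02 mV, 75.3% within +/-2.5 mV, max 71.3 mV
```

The slow triangle is the hardest target: while the model sits above the
blue actuator's reversal (−11.2 mV) no depolarizing output is permitted, so
the early plateau cannot be matched — exactly the physical limitation such
systems face. The APD₉₀ of the enforced beats (720.6 ms) still lands
within a few milliseconds of the model's 724 ms; the large early error is
confined to the first ~200 ms of each cycle.

Every experiment can also be driven from a YAML config through the thin
command-line tool:

```sh
inst/cli/apqr restore --config inst/extdata/restore_fourap.yaml --out out/
inst/cli/apqr gen-waveforms --out waveforms/
```

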