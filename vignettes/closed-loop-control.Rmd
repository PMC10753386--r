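---
title: "Closed-loop optogenetic control of action potentials: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-loop optogenetic control of action potentials: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apqr)
```

`apqr` simulates a closed-loop opto-electronic system that measures the
membrane potential (V~m~) of cardiomyocytes at 1 kHz and drives two
antagonistic optogenetic actuators so that V~m~ tracks a reference action
potential (AP). This vignette explains the synthetic cell model and its
calibration, the three controllers, the numerical choices, what the
simulated experiments do and do not demonstrate about real preparations,
and the design decisions that were genuinely open.

## The synthetic plant

The controlled system is a single "compound AP" source standing in for an
electrically coupled atrial-myocyte monolayer. Because the experiments
constrain only a handful of macroscopic properties — resting potential,
AP amplitude, APD at 1-Hz pacing, the two light-driven plateau potentials,
and the direction and size of drug-induced APD shifts — the membrane is
modelled phenomenologically rather than with ionic bookkeeping. In
normalized voltage $u = (V - V_{rest})/A$ (defaults $V_{rest} = -75$ mV,
$A = 90$ mV):

$$\frac{dV}{dt} = A\left[\,h\,\frac{u^2(1-u)}{\tau_{in}} - u\,g(u)\right]
  - g_{blue}\,a_{blue}\,(V - E_{blue}) - I_{red}\,a_{red} + I_{inj}$$

with a two-current structure: a regenerative inward excitation current
gated by $h$, and an ungated repolarizing leak. Two features distinguish it
from the textbook two-current excitable model, and both are essential for
the system to be *controllable* by realistic photocurrents:

* **Fast gate inactivation.** $h$ inactivates with $\tau_{inact} = 15$ ms
  whenever $u > u_{gate}$ and recovers with $\tau_{open} = 100$ ms below
  it. After ~50 ms of an AP the inward current is gone, as L-type calcium
  current largely is in real myocytes. A model whose inward current
  persists at mid-plateau voltages would demand tens of mV/ms of
  hyperpolarizing current to force early repolarization — two orders of
  magnitude more than a chloride-pump actuator can deliver — and would make
  the drug-model and triangular enforcement experiments physically
  impossible, which they demonstrably are not.
* **Inward-rectifier-like leak.** $g(u)$ interpolates sigmoidally (centre
  $u_{leak} = 0.12$, width $0.03$) between a strong conductance
  $1/\tau_{out}$ ($\tau_{out} = 2$ ms) below/near rest and a weak one
  $1/\tau_{close}$ ($\tau_{close} = 180$ ms) during the plateau. The strong
  rest conductance anchors the diastolic potential and means the maximal
  red-pump current shifts rest by only ~7 mV (to −82 mV), while the same
  current moves the high-resistance plateau by several mV/ms — the
  asymmetry that makes light-driven APD shortening work at modest
  photocurrents.

The excitation time constant $\tau_{in} = 0.9$ ms sets the upstroke
velocity (~25 mV/ms). It was deliberately chosen at the gentle end: with a
steeper excitation current the operating point "hold V~m~ a few millivolts
above rest", required whenever a model AP has a more positive resting
potential than the cell, becomes locally unstable once the gate has
recovered (the excitation current's voltage slope exceeds the leak's), and
no controller acting through a 5-ms actuator lag can stabilize it — the
simulated monolayer then fires spurious APs during enforcement. Real
monolayers evidently tolerate such holds; the gentler excitation current
reproduces that.

### Calibration

All plant defaults were fixed once, by simulation, against the study
conditions and then frozen:

* $\tau_{close} = 180$ ms gives a paced APD~90~ of 298.6 ms at 1-Hz
  electrical pacing (target 300 ± 20 ms).
* The drug factors scale $\tau_{close}$ multiplicatively:
  $f_{4AP} = 1.55$ yields a 4AP-model APD~90~ of ≈422 ms and
  $f_{cch} = 0.195$ a carbachol-model APD~90~ of ≈95 ms, with APD monotone
  in each factor.
* $I_{red}$ is computed in closed form from the fixed-point condition at
  the −82 mV red plateau (`calibrate_red_current()`), giving
  ≈3.5 mV/ms.
* $g_{blue} = 0.8\,\mathrm{ms^{-1}}$ is the smallest round conductance
  that parks the blue plateau within 1 mV of $E_{blue} = -11.2$ mV against
  the residual repolarizing leak; keeping it small matters because the
  0.1-mW/mm² disturbance pulse scales linearly with it and must remain
  within the red actuator's authority to cancel.
* Actuator kinetics are first-order with $\tau_{act} = 5$ ms and a linear
  irradiance-to-activation map; 1.0 corresponds to the 1.5 mW/mm²
  calibration intensity.

Measurement noise (`noise_sd`, default 0 mV) is added only to the
controller-visible V~m~, never to the plant state, and is drawn from a
seeded stream so runs remain reproducible.

## Controllers

All controllers run once per 1-ms tick, aligned to the pacing stimulus
(beat $n$ spans $[n\,T, (n+1)T)$, $T = 1000$ ms), against a setpoint that
is the element-wise mean of `lognum = 5` logged beats or a model waveform.

**Adaptive proportional (APqr).** $e = V_m - AP_{ideal}[i]$,
$I_{out} = (C_m/R_m)\,e$. $R_m$ is updated every tick: multiplied by
`R_m_corr_up` when the error changed sign (overshoot — the gain backs
off), divided by `R_m_corr_down` when it grew with unchanged sign (the
gain creeps up). The two predicates are the minimal formalization of
"overshoots" / "moves away" and are mutually exclusive; neither leaves
$R_m$ unchanged. The defaults are asymmetric (1.1 up, 1.01 down): backing
off quickly and creeping up slowly keeps the adaptive gain just below the
ringing threshold instead of hovering on it, which removes the ±20-mV
upstroke ringing a symmetric choice produces.

**PID (APqrPID).** The integral term accumulates the raw error each tick;
the derivative term is the least-squares slope of the last $l = 10$ errors
regressed against time, in chronological order so that a rising error
yields a positive derivative. Until $l$ samples exist the derivative is 0.
Gains default to the mid-range of the experimentally useful intervals
(K~P~ = 80, K~I~ = 3, K~D~ = 50) and are overridable per experiment.

**Output routing.** Positive PID drives the red LED with `scale`;
negative PID drives the blue LED with its absolute value and
`scale_blue`; blue output is only permitted while the *measured* V~m~ is
more negative than the blue actuator's plateau potential `V_plateau`
(measured rather than setpoint V~m~, matching the gating's purpose of
protecting against a channel that would otherwise pull V~m~ down). At most
one channel is nonzero per tick. The two channels carry separate scales
because their small-signal authorities differ ~15-fold near rest (a
conductance with ~60 mV driving force versus a ~3.5 mV/ms pump); a single
shared scale is either unstable on blue or uselessly slow on red. Defaults
(`scale = 2e-3`, `scale_blue = 2e-4`) were tuned once on the synthetic
plant for stable, accurate tracking across all scenarios — mirroring the
heuristic per-experiment tuning such rigs require — and then frozen.

**Anti-windup.** The integral accumulator starts at 0 at correction onset,
is continuous across beats within one run, and is frozen on any tick where
the routed output saturates. "Saturates" covers three cases: the drive
clipped at 1; a blue demand gated to 0 by the plateau rule; and a blue
demand issued while the actuator has essentially no driving force left —
either V~m~ within 1 mV of `V_plateau`, or a setpoint at/above
`V_plateau`, which no blue output can reach. Without the last two cases
the accumulator winds up by thousands of mV·ticks while the slow
triangular model sits above the blue reversal, and the stored demand then
corrupts the following 150 ms of tracking.

**Enforcement (APqrLE).** The controller itself paces: a 10-ms blue pulse
(normalized level 1/3) opens each 1000-ms cycle, superseding corrective
output; the PID state is frozen during the pulse. Corrective output begins
at the first detected upstroke — the first tick whose 1-ms V~m~ increment
exceeds 2 mV/ms — and from then on runs on every non-pacing tick, which
also imposes the model's resting potential between APs. The pulse-level
unit ambiguity in the source protocols (0.5 mW/cm² vs 0.5 mW/mm²) is left
unresolved by working in normalized irradiance.

## Quantification

`ap_metrics()` takes the moment of maximal upstroke velocity (earliest
maximal 1-ms forward difference at/after the stimulus) as the timing
reference; the resting potential is the mean of the 50 ms preceding the
stimulus; the x% repolarization level is
$V_{peak} - x\,(V_{peak} - V_{rest})$ relative to that per-beat amplitude
(this choice reproduces the triangular closed forms exactly); crossing
times are linearly interpolated, and fractions whose level is never
crossed are reported missing. dV/dt-max ties break to the earliest sample,
which is forced for linear upstrokes sampled at 1 kHz.

Error distributions use 5-mV bins centred on zero, so the reported
"fraction within ±2.5 mV" is exactly the centre-bin mass. Two windowing
conventions coexist deliberately:

* **Restoration** errors are pooled over the interval between dV/dt-max
  and the 90%-repolarization moment of each *measured* correcting beat —
  the AP itself is the object being restored. The first correcting beat is
  excluded as controller settling.
* **Enforcement** errors are pooled over *all* ticks of the enforced
  cycles (first two excluded as settling), because during enforcement the
  entire cycle, including the diastolic level, is under control. Under a
  per-AP window the benchmark per-model and combined fractions for the
  triangular sequence are mutually inconsistent (the slow models' windows
  end before their errors first enter the band), so the whole-cycle
  convention is also the one that makes those benchmarks coherent.

For the triangular sequence (t13, t09, t05, t01, t05, t09, t13) the runs
are deterministic, so each distinct model is simulated once and its error
samples weighted by its multiplicity in the sequence.

## Numerical choices

Explicit fixed-step Euler integration at `dt_sub = 0.05` ms, 20 substeps
per control tick, with zero-order hold of the light command and injected
current across the tick — the same hard-real-time structure as the
physical loop, and fully deterministic. The fastest time constant
(τ_out = 2 ms) and the steepest voltage slope (~1.3 ms⁻¹ including a
saturated blue conductance) leave the scheme comfortably stable; halving
`dt_sub` changes the paced APD~90~ by less than 0.1 ms. The dark resting
state is an exact fixed point ($u = 0$ silences both currents), so
unstimulated runs do not drift. Non-finite state is a hard failure naming
the offending variable.

Problem sizes were chosen to keep full runs in seconds: restoration
scenarios use 5 logging + 10 paused + 10 correcting beats (25 s of
simulated time); enforcement uses 2–3 uncontrolled beats plus 6–8 enforced
beats per model. All reported fractions are stable to the third digit if
the correcting phases are doubled.

## What the simulations do and do not show

The plant reproduces the macroscopic operating points of an optogenetic
monolayer preparation — resting/plateau potentials, paced APD, drug-shifted
APD, actuator authorities — and the controllers are the tick-exact
algorithms. Passing scenarios therefore demonstrate the *control logic*:
sign routing, plateau gating, adaptive gain behaviour, windup handling,
and the physical limits (red authority during early repolarization, the
blue reversal ceiling) that shape the residual error distributions.

They do not demonstrate robustness to what the synthetic plant omits:
spatial propagation and pacing-site heterogeneity (the measured compound
AP of a monolayer is not a single point process), opsin desensitization
and spectral crosstalk, nonlinear irradiance–current relations,
patch-clamp access artefacts, or beat-to-beat biological variability.
Measurement noise is available but off by default; with it enabled the
fractions degrade gracefully but the published values are no longer
guaranteed.

## Known limitations

* The upstroke cannot be matched during enforcement: the plant's own
  regenerative upstroke (to ≈ +20 mV) overshoots model peaks of +12 mV for
  ~10–30 ms each beat, exactly as the physical system's least-controlled
  phase is the upstroke.
* Models whose voltage exceeds `V_plateau` are unreachable in that range
  by construction; the slow triangle (t01) is the limiting case.
* The adaptive-gain controller assumes a monotone plant response within a
  tick; with large measurement noise its overshoot predicate chatters and
  the gain sinks conservatively.
* Equation indices for the accumulator are per-run, not per-beat: whether
  the integral should reset at each cycle is unspecified in the source
  algorithms; continuity was chosen (matching "computed in every
  iteration") and matters only when gains are far from default.
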