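# Dual-actuator restoration of a 4AP-like (repolarization-slowing)
# perturbation in the synthetic monolayer. All values shown are the package
# defaults; the file exists so that every constant of the experiment is
# visible and overridable in one place.
mode: restore
seed: 1
plant:
  noise_sd: 0
controller:
  algorithm: apqr_pid
  actuation: dual_optical
  gains:
    K_P: 80
    K_I: 3
    K_D: 50
    l: 10
    V_plateau: -11.2
    lognum: 5
    scale: 0.002
    scale_blue: 0.0002
protocol:
  pacing:
    mode: electrical
    period: 1000
    pulse_ms: 5
    pulse_level: 15
  drug:
    label: fourAP
  phases:
    logging: 5
    paused: 10
    correcting: 10
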