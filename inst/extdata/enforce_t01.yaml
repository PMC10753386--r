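# Enforcement of the slowest triangular model waveform (t01, repolarizing at
# 0.1 mV/ms) onto the unperturbed synthetic monolayer.
mode: enforce
seed: 1
plant:
  noise_sd: 0
enforce:
  model: t01
  n_beats: 6
  gains:
    K_P: 80
    K_I: 3
    K_D: 50
    V_plateau: -11.2
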