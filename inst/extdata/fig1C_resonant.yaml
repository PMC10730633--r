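# Resonant open-loop pacing: global 20 uW/mm^2, 33 ms pulses at 13.33 Hz,
# driving linear drift and boundary termination of the spiral.
model:
  variant: apical
  g_ChR2: 0.3
tissue:
  nx: 100
  ny: 100
  dx: 0.025
  D: 0.0014
  dt: 0.01
  scheme: split
init:
  method: phase_seed
  s2_delay: 45.0
  settle: 200.0
  period: 66.0
protocol:
  mode: open_loop
  fp: 13.33
  width_ms: 33.0
  intensity: 20.0
  electrode_xy_cm: [.na, .na]
  Vc_mV: -40.0
  n_max: .inf
analysis:
  trace_point_cm: [0.625, 1.875]
  V_iso: -40.0
run:
  duration_ms: 1000.0
  snapshot_interval_ms: 2.0
  trace_dt_ms: 0.5
  seed: 1
  stop_on_termination: yes
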