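# Example study configuration for a synthetic-cohort model comparison.
cohort:
  n_patients: 7
  base_seed: 42
solver:
  h: 0.25            # structural mesh size, mm
  load_steps: 4
  pressure_phase: max
preconditioning:
  shrink_tol: 0.001  # relative lumen-area tolerance of the shrink search
flow:
  viscosity: 0.04    # Poise
  flow_rate: 1.0     # mL/s, shared across variants
  mesh_h: 0.08
materials:
  wall: vessel
  lipid: lipid
  calc: calcification
comparison:
  pairs: ['M1:M2', 'FSI:M1', 'FSI:M5', 'FSI:M7']
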