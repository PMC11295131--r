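# Example run configuration: Monte Carlo simulation of the fragmenting
# protonated-ethyl-acetate fixture at 110 Td, with the MS transfer region.
# Units at this boundary are instrument-friendly: mm, mbar, degrees C, Td,
# microseconds.  Omitted keys fall back to the reference-instrument
# defaults.
instrument:
  drift_length_mm: 150.5
  pressure_mbar: 14.3
  temperature_C: 27
  injection_time_us: 3
  atd_resolution_us: 3
field:
  EN_td: 110
engine:
  type: mc
  n_particles: 4000
  seed: 1
  transfer_region: true
  transfer_time_us: 50
network:
  fixture: etoac
output:
  dir: driftims_out
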