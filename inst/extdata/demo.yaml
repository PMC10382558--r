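# Demonstration run: G178D-like channel at pH 7.4, -120 mV.
# Levels and occupancies are the experimentally observed sub-state ladder;
# the titration stage recovers K_H and K_OC from model-generated occupancy
# curves over the buffer pH grid.
seed: 7
figures: true
simulate:
  duration: 20
  levels: [0.0, 0.45, 0.74, 0.92, 1.0]
  occupancies: [0.06, 0.02, 0.07, 0.26, 0.59]
  mean_dwells: 0.010
  acquisition:
    sample_rate: 3000
    filter_corner: 1000
    noise_sd: 0.3
    voltage: -120
    full_conductance: 60
    pH: 7.4
idealize:
  max_levels: 5
  dead_time: 0.0005
  min_separation: 0.3
stats:
  burst_cutoff: 0.1
  same_level_only: true
titration:
  pH_grid: [6.2, 6.5, 6.8, 7.1, 7.4, 7.7, 8.0]
  truth:
    K_H: 2.0e-7
    K_OC: 0.05
    n_sites: 4
  start:
    K_H: 1.0e-6
    K_OC: 0.1
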