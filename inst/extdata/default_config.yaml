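grid:
  dims:
  - 100
  - 100
  cell_size_m: 25.0
  adjacency: von_neumann
land_uses:
  land_use:
  - residential
  - employment
  - public_building
  - mixed_R_E_retail
  - entertainment_retail
  - public_open_space
  cell_quota:
  - 3400
  - 1000
  - 1200
  - 2400
  - 800
  - 1200
  max_cluster:
  - 1000.0
  - 500.0
  - 200.0
  - 300.0
  - 40.0
  - 100.0
  size_distribution:
  - exponential
  - exponential
  - exponential
  - exponential
  - exponential
  - exponential
  size_mean:
  - 333.3333333
  - 166.6666667
  - 66.6666667
  - 100.0
  - 13.3333333
  - 33.3333333
theta:
  mean: 1.0
  sd: 0.05
  floor: 0.05
agents:
  'n': 10000
  proportions:
    teenager: 0.15
    bachelor: 0.25
    married: 0.45
    senior: 0.15
  employment:
    teenager: 0.0
    bachelor: 0.6
    married: 0.85
    senior: 0.3
  n_favored: 40
probability_table: ~
iac:
  d: 0.95
  g: 1.02
  top_k: 10
  mood_sd: 0.05
  favored_boost: 1.5
run:
  days: 28
  n_runs: 20
master_seed: 1
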