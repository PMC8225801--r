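settings:
  start_age: 69
  cohort_size: 6834
  discount_rate: 0.035
  cycle_length: 1
  age_cap: 100
  wtp_threshold: 20000
  ppi_all_alive: true
accuracy:
  sensitivity: 0.799
  specificity: 0.924
  endoscopy_sensitivity: 1.0
  endoscopy_specificity: 1.0
scenario:
  n_invited: 6834
  n_swallowed: 1654
  n_referred: 221
  n_endoscopy_intervention: 198
  n_endoscopy_usual: 16
  n_repeat_tests: 202
  n_repeat_endoscopies: 23
  uptake: 0.2420251683
  include_repeat: false
prevalence:
  NDBE: 0.082908984489
  LGD: 0.000673105063
  HGD: 0.002019315189
  EarlyEAC: 0.002692420252
detected:
  intervention:
    NDBE: 123
    LGD: 1
    HGD: 3
    EarlyEAC: 4
  usual:
    NDBE: 11.6
    LGD: 0
    HGD: 0
    EarlyEAC: 4
tables:
  transitions: transitions.csv
  costs: costs.csv
  utilities: utilities.csv
  disutilities: disutilities.csv
  life_table: life_table.csv
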