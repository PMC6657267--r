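name: case2
description: >
  Breast duct -> circulatory system -> bone metastasis case study.
  Drug treatment case 2: at t_drug every circulating tumour cell carrying
  exactly two driver mutations (of any genes) is removed.
provenance: >
  Driver genes, their compartment order and the drug signature follow the
  published breast-to-bone case tables; kinetic amplitudes, stemness
  supports, waiting-time parameters, capacities, population sizes and
  times are calibrated desk-scale defaults, not paper-derived.
genes: [EPCAM, CD47, CD44, MET]
compartments:
  labels: [breast, circulation, bone]
  n_secondary: 1
  transition:
    - [0.0, 1.0, 0.0]
    - [0.0, 0.0, 1.0]
    - [0.0, 0.0, 1.0]
  required_sets:
    - [EPCAM]
    - [CD47, CD44]
    - [MET]
ordered: true
kinetics:
  alpha: 0.25
  r: 4.0
  amplitudes: {asym: 1.0, sym: 0.45, apop: 0.35, pass: 10.0}
  centers: {asym: 0.25, sym: 0.5, apop: 0.75}
  width: 1.1
  s_bar: 1.0
  beta: 14.0
  bounds: {m_d: 4, m_n: 12, m_m: 20}
energy:
  capacity: [40.0, 1.0, 40.0]
simulation:
  initial_cells: 10
  t_end: 3.5
  record_dt: 0.25
  replicates: 100
  seed: 20190725
drug:
  d: [0, 0, 0, 0]
  m_n: 0
  m_m: 0
  k: 2
  m_d: 2
  time: 2.5
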