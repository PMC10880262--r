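# Demo run: synthetic cohort through every stage.
seed: 1
out_dir: centrosat_demo
library:
  source: synthetic
  seed: 101
motif:
  sequence: NTTCGNNNNANNCGGGN
stages:
  annotate: true
  monomers: true
  boxes: true
  trees: true
  chip: true
reads:
  source: simulate
  specs:
    - {sat_class: MiSat120, n_monomers: 25, divergence: 0.05, intact_box_fraction: 0.6, seed: 11}
    - sat_class: MiSat120
      n_monomers: 24
      divergence: 0.06
      seed: 12
      cassettes:
        - {after_monomer: 12, length: 400, label: IAPEz_like}
    - {sat_class: MaSat, n_monomers: 16, divergence: 0.05, seed: 13, direction_switch_at: 8}
    - {sat_class: MiSat112_64, n_monomers: 14, divergence: 0.04, intact_box_fraction: 0.67, seed: 14}
thresholds:
  identity_floor: 70
  gap_min: 100
chip:
  depth: 20
  marks:
    - {mark: CENP-A, folds: {MiSat120: 60, MiSat112_64: 20, MaSat: 1.5}, phased: false, seed: 21}
    - {mark: H3K9me3, folds: {MiSat120: 1.2, MiSat112_64: 1.2, MaSat: 3.5}, phased: true, period: 234, seed: 22}
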