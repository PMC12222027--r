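# Default analysis configuration for the C. jejuni flagellar motor.
# Provenance of constants:
#   [PAPER]   printed in the source literature
#   [DERIVED] reverse-derived so the model reproduces printed quantities
seed: 1
constants:
  N_cj: 17              # [PAPER] stator complexes, C. jejuni
  N_ec: 11              # [PAPER] stator complexes, E. coli / Salmonella
  F_stator_pN: 7.3      # [PAPER] per-stator tangential force
  r_cj_nm: 26.5         # [DERIVED] contact radius from 3,288 = 17*7.3*r
  r_ec_nm: 20.0         # [DERIVED] contact radius from 1,606 = 11*7.3*r
  disk_n1: 51           # [PAPER] inner basal-disk ring protomers (17 trimers)
  disk_spacing_ratio: 0.216  # [DERIVED] reproduces +11 protomers per ring
  lp_ring_steps: 26     # [PAPER] LP-ring dwell periodicity
  cring_teeth_cj: 38    # [PAPER] C-ring periodicity
stages:
  - stage: torque_predictions
  - stage: disk_rings
    n1: 51
    spacing_ratio: 0.216
    n_rings: 5
  - stage: mesh_registry
    n_small: 17
    m_teeth: 38
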