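reactor_mode: batch
carbon_source: cellobiose
biomass_variant: cellobiose
gam: ~
ngam: 0.0
medium:
  uptake:
    EX_sub_e: 10.0
  secretion:
  - EX_etoh_e
  - EX_ac_e
  - EX_h2_e
  - EX_h2s_e
measured:
  EX_sub_e:
  - -10.0
  - 0.0
  BIOMASS_CELLOBIOSE:
  - 4.8
  - 0.0
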