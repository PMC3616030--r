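# Medes Islands reserve scenario: 100-patch coastline zoned 1% no-take /
# 12% partially protected / 87% open; striped red mullet (fished, entering
# the simulation overfished at 1.5x its MSY harvest rate) and European
# seabass (the species divers come to see, taken as bycatch at u = 0.1).
# Dive demand is calibrated to 63000 dives/year at the EUR 3.5 access fee
# against the unfished biomass of the tourism species in the no-take zone.
name: medes
seed: 1
coast:
  n_patches: 100
  patch_length: 1
  fractions: [0.01, 0.12, 0.87]
years:
  burn_in: 100
  post: 100
partial_reduction: 0.5
include_partial_in_reserve: false
econ:
  cost: 30000.0
tourism:
  fee_policy: fixed
  fixed_fee: 3.5
  calibration:
    target_dives: 63000
    fee: 3.5
    reference_biomass: unfished_reserve
    choke_multiple: 2.0
    biomass_share: 0.5
events: []
species:
  - name: red_mullet
    role: fished
    s_nat: 0.66
    w_k: 53.93
    w_km1: 0.0
    rho: 0.77
    R0: 52000
    sigma_L: 2.0
    sigma_A: 1.0
    h: 0.75
    price: 0.01
    u_pre_msy_multiple: 1.5
  - name: european_seabass
    role: tourism
    s_nat: 0.9
    w_k: 384.9
    w_km1: 0.0
    rho: 0.85
    R0: 6100
    sigma_L: 2.0
    sigma_A: 0.01
    h: 0.75
    price: 0.0
    u_pre: 0.1
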