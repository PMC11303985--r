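provenance: Found by make_cycling_fixture(seed = 1, years = 60) and frozen; the control
  run (behavioral model off) exhibits multiyear fish-biomass cycles and the behavior-on
  run (f_PM = f_FC = 1) damps them.
floor: 0.25
cfg:
  run:
    years: 100.0
    dt: 1.0
    analysis_fraction: 0.5
  forcing:
    temperature:
      mean: 10.0
      amplitude: 9.0
      phase: 112.0
    light:
      mean: 0.55
      amplitude: 0.45
      phase: 81.0
    load:
      base: 0.002
      amplitude: 0.001
      phase: 300.0
    load_scale: 1.0
  physics:
    flushing: 0.004
    burial: 0.0008
    mineralization: 0.01
  chl_conversion: 1.0
  phytoplankton:
    mu_max: 1.2
    K_N: 0.01
    resp: 0.06
    mort: 0.03
    q10: 2.0
  zooplankton:
    c: 2.0
    I_max: 0.8
    f_gut: 1.0
    a: 0.7
    u: 0.04
    m_nat: 0.01
    q10: 2.0
  zoobenthos:
    c: 0.08
    I_max: 0.12
    f_gut: 2.0
    a: 0.6
    u: 0.004
    m_nat: 0.003
    q10: 2.0
  omnivore:
    obm: yes
    tradeoff:
      f_PM: 1.0
      f_FC: 1.0
      f_RF: 0.3
    I_max: 0.06
    u: 0.005
    m_nat: 0.0005
    q10: 2.0
    f_veg: 1.0
    prey:
    - id: zooplankton
      mode: pelagic
      c: 1.2
      f_gut: 1.0
      a: 0.7
    - id: zoobenthos
      mode: benthic
      c: 0.25
      f_gut: 1.5
      a: 0.6
    - id: detritus
      mode: benthic
      c: 0.05
      f_gut: 4.0
      a: 0.2
  predator:
    obm: yes
    tradeoff:
      f_PM: 1.0
      f_FC: 1.0
      f_RF: 0.3
    I_max: 0.025
    u: 0.003
    m_nat: 0.00075
    q10: 2.0
    f_veg: 1.0
    c: 0.1
    f_gut: 1.0
    a: 0.8
  init:
    nutrient: 0.05
    phytoplankton: 0.2
    zooplankton: 0.1
    zoobenthos: 0.5
    detritus: 2.0
    omnivore: 0.3
    predator: 0.1
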