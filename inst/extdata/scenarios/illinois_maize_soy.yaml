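# Four-year maize-soybean rotation with annual autumn basalt applications
# of 5 kg m-2, F_D = 1, 30-cm biogeochemically active layer. Mineralogy:
# Blue-Ridge-basalt characterisation by SEM-EDS (albite, ferroactinolite,
# epidote, chlorite, quartz; 1.7% unresolved, treated as inert). The
# companion file illinois_maize_soy_basaltB.yaml carries the alternative
# XRD characterisation including calcite. Requires user-supplied hourly
# forcing covering four years (synthetic forcing works for testing).
site:
  latitude: 40.1
  z_active: 0.30
  texture: silt_loam
  cec: 60
schedule:
  n_years: 4
  year0: 2017
weathering:
  F_D: 1.0
vegetation:
  pft: maize
  rotation: [maize, maize, soybean, maize]
feedstock:
  events:
    - day: 305            # early November, year 1
      rate: 5.0
      ssa: 300
      fractions: &basaltL
        albite: 0.196
        ferroactinolite: 0.116
        epidote: 0.256
        chlorite: 0.363
        quartz: 0.052
    - day: 670
      rate: 5.0
      ssa: 300
      fractions: *basaltL
    - day: 1035
      rate: 5.0
      ssa: 300
      fractions: *basaltL
    - day: 1400
      rate: 5.0
      ssa: 300
      fractions: *basaltL
external:
  fert_events:
    - day: 130            # spring N for maize years
      element: "N"
      amount: 15
    - day: 860
      element: "N"
      amount: 15
    - day: 1225
      element: "N"
      amount: 15
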