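# Variant of illinois_maize_soy.yaml using the alternative XRD feedstock
# characterisation (epidote standing in for piemontite, plus calcite;
# 1.4% unresolved mass treated as inert).
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
    - day: 305
      rate: 5.0
      ssa: 300
      fractions: &basaltB
        albite: 0.233
        ferroactinolite: 0.119
        epidote: 0.178
        chlorite: 0.340
        quartz: 0.090
        calcite: 0.026
    - day: 670
      rate: 5.0
      ssa: 300
      fractions: *basaltB
    - day: 1035
      rate: 5.0
      ssa: 300
      fractions: *basaltB
    - day: 1400
      rate: 5.0
      ssa: 300
      fractions: *basaltB
external:
  fert_events:
    - day: 130
      element: "N"
      amount: 15
    - day: 860
      element: "N"
      amount: 15
    - day: 1225
      element: "N"
      amount: 15
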