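# Mesocosm-style column experiment: sorghum grown for one season with a
# single basalt application at start, dissolution factor F_D = 0.5.
# The mineral assemblage is an Oregon-basalt-like mix built from the
# packaged kinetics library (plagioclase split into albite/anorthite,
# pyroxene as diopside, olivine as forsterite); the experiment's full modal
# mineralogy is not reproduced here. The 121-day observation window is
# days 1-121 of the run.
site:
  latitude: 52.0
  z_active: 0.20
  texture: sandy_loam
  cec: 20
schedule:
  n_years: 1
  year0: 2001
weathering:
  F_D: 0.5
  k_precip: 1.0e-8
feedstock:
  events:
    - day: 1
      rate: 10.0          # kg rock m-2
      ssa: 230            # m2 kg-1
      fractions:
        anorthite: 0.30
        albite: 0.25
        diopside: 0.25
        forsterite: 0.10
        quartz: 0.10
vegetation:
  pft: sorghum
initial:
  s_eff: 0.6
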