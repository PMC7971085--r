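# Reaction medium of the Hansen PFK equilibrium measurement: 33 mmol/kg
# Tris + HCl, 6.94 mmol/kg MgCl2, 50 mmol/kg KCl, 6 mmol/kg (NH4)2SO4 at
# pH 8, 303.15 K. Dithiothreitol and the enzyme are excluded.
label: hansen_pfk
T: 303.15
pH: 8.0
tris_hcl: 0.033
salts:
  mgcl2: 0.00694
  kcl: 0.050
  ammonium_sulfate: 0.006
counter_ion: k
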