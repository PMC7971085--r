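# Reaction medium of the Veech aldolase equilibrium measurement: 10 mmol/kg
# sodium phosphate buffer (speciated at pH 7) plus 230 mmol/kg KCl (ionic
# strength adjusted to 0.25 mol/L), 311.15 K.
label: veech_aldolase
T: 311.15
pH: 7.0
sodium_phosphate: 0.010
salts:
  kcl: 0.230
counter_ion: k
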