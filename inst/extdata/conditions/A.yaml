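# TFA scenario A: best-case conditions. Only the substrate and product
# metabolites of each reaction are present in water (no salts, no other
# metabolites) when predicting activity coefficients; substrates at their
# maximum, products at their minimum molality.
#
# The metabolite min/max molalities below are editable placeholders: values
# printed in the source text are used where available (T, pH); the remaining
# ranges are literature-informed cytosolic concentration windows chosen to be
# consistent with the reported qualitative feasibility pattern. Correcting
# them requires no code change. Molalities in mol/kg water.
label: A
T: 298.15
pH: 7.0
pressure: 101325.0
mode: activity
salts: {}
counter_ion: k
metabolite_ranges:
  glucose:  {min: 2.0e-4, max: 5.0e-3}
  g6p:      {min: 1.0e-4, max: 7.0e-3}
  f6p:      {min: 2.0e-5, max: 2.0e-3}
  fbp:      {min: 2.0e-5, max: 1.5e-2}
  dhap:     {min: 4.0e-5, max: 3.0e-3}
  gap:      {min: 2.0e-6, max: 1.0e-4}
  bpg:      {min: 5.0e-5, max: 5.0e-4}
  pg3:      {min: 1.0e-4, max: 3.0e-3}
  pg2:      {min: 1.0e-5, max: 5.0e-4}
  pep:      {min: 1.0e-5, max: 1.0e-3}
  pyruvate: {min: 5.0e-5, max: 1.0e-2}
  atp:      {min: 1.0e-3, max: 1.0e-2}
  adp:      {min: 1.0e-4, max: 3.0e-3}
  nad:      {min: 1.0e-4, max: 3.0e-3}
  nadh:     {min: 5.0e-5, max: 3.0e-4}
  pi:       {min: 1.0e-3, max: 1.0e-2}
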