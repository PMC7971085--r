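# The ten glycolytic reactions, numbered as usual (1 hexokinase ... 10 pyruvate
# kinase). Stoichiometry is signed (substrates negative, products positive).
# nu_h is the chemical proton production of the reaction; h_explicit marks
# reactions whose standard data are on the chemical scale so that a_H+ =
# 10^-pH enters the reaction quotient (GAPDH only; all other standard values
# are pH-7 apparent constants with H+ absorbed). Water (enolase) is excluded
# from reaction quotients by the usual dilute-solution convention.
reactions:
  - id: hexokinase
    number: 1
    name: Hexokinase
    stoichiometry: {glucose: -1, atp: -1, g6p: 1, adp: 1}
    nu_h: 1
    h_explicit: false
  - id: pgi
    number: 2
    name: Glucose 6-phosphate isomerase
    stoichiometry: {g6p: -1, f6p: 1}
    nu_h: 0
    h_explicit: false
  - id: pfk
    number: 3
    name: Phosphofructokinase
    stoichiometry: {f6p: -1, atp: -1, fbp: 1, adp: 1}
    nu_h: 1
    h_explicit: false
  - id: aldolase
    number: 4
    name: Fructose-bisphosphate aldolase
    stoichiometry: {fbp: -1, dhap: 1, gap: 1}
    nu_h: 0
    h_explicit: false
  - id: tpi
    number: 5
    name: Triosephosphate isomerase
    stoichiometry: {dhap: -1, gap: 1}
    nu_h: 0
    h_explicit: false
  - id: gapdh
    number: 6
    name: Glyceraldehyde 3-phosphate dehydrogenase
    stoichiometry: {gap: -1, nad: -1, pi: -1, bpg: 1, nadh: 1}
    nu_h: 1
    h_explicit: true
  - id: pgk
    number: 7
    name: Phosphoglycerate kinase
    stoichiometry: {bpg: -1, adp: -1, pg3: 1, atp: 1}
    nu_h: 0
    h_explicit: false
  - id: pgam
    number: 8
    name: Phosphoglycerate mutase
    stoichiometry: {pg3: -1, pg2: 1}
    nu_h: 0
    h_explicit: false
  - id: enolase
    number: 9
    name: Enolase
    stoichiometry: {pg2: -1, pep: 1}
    nu_h: 0
    h_explicit: false
  - id: pk
    number: 10
    name: Pyruvate kinase
    stoichiometry: {pep: -1, adp: -1, pyruvate: 1, atp: 1}
    nu_h: -1
    h_explicit: false
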