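metabolite_id,pka_values,charge_most_protonated,provenance
atp,4.06;6.95,0,apparent stability constants near I=0.1 mol/L
adp,3.93;6.68,0,apparent stability constants near I=0.1 mol/L
g6p,0.94;6.11,0,sugar-phosphate second ionization
f6p,0.97;6.11,0,sugar-phosphate second ionization
fbp,5.90;6.40,-1,bisphosphate third/fourth ionization
dhap,5.90,0,phosphate second ionization
gap,6.45,0,phosphate second ionization
pg3,3.42;6.21,1,carboxyl and phosphate ionizations
pg2,3.55;7.00,1,carboxyl and phosphate ionizations
pep,3.50;6.35,0,enol-phosphate ionizations
bpg,7.50,-2,acyl-phosphate region
pi,2.15;6.75,1,orthophosphate; apparent near I=0.1 mol/L
pyruvate,2.49,0,carboxyl ionization
tris,8.07,1,Tris conjugate acid at 298.15 K
glucose,,0,no ionization in 0-14 window relevant here
nad,,0,none relevant near neutral pH
nadh,,0,none relevant near neutral pH
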