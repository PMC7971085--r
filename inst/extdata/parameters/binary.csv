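species_i,species_j,kij_slope,kij_T0,source
h3o,water,0,0.25,CR35
na,water,-0.007981,2.37999,CR35
k,water,-0.004012,1.3959,CR35
nh4,water,0,0.064,CR35
cl,water,0,-0.25,CR35
h2po4,water,0,0.25,CR35
mg,water,0,-0.25,CR35
hpo4,water,0,0.25,CR35
so4,water,0,0.25,CR35
k,cl,0,0.064,CR35
k,h2po4,0,0.018,CR35
k,hpo4,0,1.000,CR35
k,so4,0,1.000,CR35
na,cl,0,0.317,CR35
na,h2po4,0,-0.071,CR35
na,hpo4,0,-1.000,CR35
na,so4,0,-1.000,CR35
nh4,cl,0,-0.566,CR35
nh4,h2po4,0,-1.000,CR35
nh4,hpo4,0,-0.556,CR35
nh4,so4,0,-1.000,CR35
mg,cl,0,0.817,CR35
mg,so4,0,-1.000,CR35
h3o,cl,0,0.654,CR35
glucose,water,0.00024,-0.1192,CR30
atp,water,0,-0.1719,CR17
adp,water,0,-0.1368,CR17
g6p,water,0,-0.065,CR18
f6p,water,0,-0.065,CR18
fbp,water,0,-0.1011,CR31
dhap,water,0,0,CR22
gap,water,0.0020333,-0.7064,CR24
pg3,water,0.0020333,-0.7064,CR24
pg2,water,0.0020333,-0.7064,CR24
nad,water,0,-0.074,CR32
nadh,water,0,-0.056,CR23
bpg,water,0,0,CR23
pep,water,-0.005083,1.3316,CR12
pyruvate,water,0,0.1601,CR33
tris,water,0,-0.047,CR18
trish,water,0,-0.061,CR12
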