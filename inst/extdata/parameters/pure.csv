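species_id,display_name,m_seg,sigma,u_kB,n_donor,n_acceptor,eps_AB_kB,kappa_AB,z,sigma_T,source
glucose,Glucose,6.6260,2.9860,244.53,5,5,5000.0,0.1,0,FALSE,CR30
atp,ATP,50.1628,2.1398,164.92,7,7,862.4,0.0001,0,FALSE,CR17
adp,ADP,18.8255,2.3283,169.55,6,6,1285.5,0.0001,0,FALSE,CR17
g6p,Glucose 6-phosphate,22.3290,2.2266,243.31,5,5,5000.0,0.1,0,FALSE,CR18
f6p,Fructose 6-phosphate,35.5936,1.8100,198.49,5,5,5000.0,0.1,0,FALSE,CR18
fbp,"Fructose 1,6-bisphosphate",19.8735,2.2922,215.77,5,5,5000.0,0.1,-3,FALSE,CR31
dhap,Dihydroxyacetone phosphate,1.3472,4.1611,289.43,2,2,3614.4,0.1,-1,FALSE,CR22
gap,Glyceraldehyde 3-phosphate,3.1100,4.6600,322.02,5,5,501.2,0.0001,-2,FALSE,CR24
pg3,3-phosphoglycerate,3.1100,4.6600,322.02,5,5,501.2,0.0001,-2,FALSE,CR24
pg2,2-phosphoglycerate,3.1100,4.6600,322.02,5,5,501.2,0.0001,-2,FALSE,CR24
nad,NAD+,25.0875,2.2714,299.04,8,8,3557.3,0.001,0,FALSE,CR32
nadh,NADH,27.3947,2.7559,380.52,8,8,3711.9,0.001,-2,FALSE,CR23
bpg,"1,3-bisphosphoglycerate",2.9053,2.3452,216.84,5,5,501.2,0.0001,-4,FALSE,CR23
pep,Phosphoenolpyruvate,12.0070,2.2000,407.27,2,2,5000.0,0.1,-2,FALSE,CR12
pyruvate,Pyruvate,18.7471,2.0812,141.02,2,2,0.0,0.04509,-1,FALSE,CR33
water,Water,1.2047,NA,353.94,1,1,2425.7,0.04509,0,TRUE,CR34
tris,Tris,6.3730,2.7484,302.16,1,1,4786.9,0.02027,0,FALSE,CR18
trish,Tris-H+,10.2047,2.4081,348.10,4,4,10970.9,1e-6,1,FALSE,CR18
k,K+,1,3.3417,200.00,0,0,0,0,1,FALSE,CR35
na,Na+,1,2.8232,230.00,0,0,0,0,1,FALSE,CR35
h3o,H3O+,1,3.4654,500.00,0,0,0,0,1,FALSE,CR35
nh4,NH4+,1,3.5740,230.00,0,0,0,0,1,FALSE,CR35
mg,Mg2+,1,3.1327,1500.00,0,0,0,0,2,FALSE,CR35
cl,Cl-,1,2.7560,170.00,0,0,0,0,-1,FALSE,CR35
h2po4,H2PO4-,1,3.6505,95.00,0,0,0,0,-1,FALSE,CR35
hpo4,HPO4(2-),1,2.1621,146.02,0,0,0,0,-2,FALSE,CR35
so4,SO4(2-),1,2.6491,80.00,0,0,0,0,-2,FALSE,CR35
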