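reaction_id,dRg0,dRg0_uncertainty,dRh0,dRh0_uncertainty,provenance
hexokinase,-17.8,0.5,-23.8,0.7,equilibrium study
pgi,2.94,0.05,12.1,0.2,equilibrium study
pfk,-9.3,0.3,-9.5,NA,derived from Hansen Kc with ePC-SAFT
aldolase,22,2,48.97,NA,derived from Veech Km with ePC-SAFT
tpi,7.1,0.3,18,7,equilibrium study
gapdh,51.5,0.4,4.6,0.1,chemical scale; H+ explicit participant
pgk,-17.8,0.2,-49,9,equilibrium study
pgam,-5.8,NA,2,5,derived from Clarke Km; isomer Kgamma = 1
enolase,-2.8,0.2,27,10,equilibrium study
pk,-28,1,-9.3,NA,equilibrium study
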