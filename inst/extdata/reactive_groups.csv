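name,smarts
aldehyde,[CX3H1]=O
acyl_halide,[CX3](=O)[F,Cl,Br,I]
alkyl_halide,[CX4][Cl,Br,I]
epoxide,C1OC1
aziridine,C1NC1
michael_acceptor,C=CC(=O)[#6]
isocyanate,N=C=O
isothiocyanate,N=C=S
anhydride,C(=O)OC(=O)
sulfonyl_halide,S(=O)(=O)[F,Cl,Br,I]
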