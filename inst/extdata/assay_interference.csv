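name,smarts
quinone,O=C1C=CC(=O)C=C1
catechol,c1ccc(O)c(O)c1
nitro_aromatic,[c][N+](=O)[O-]
nitro_aromatic_neutral,[c][N](=O)=O
azo,[#6]N=N[#6]
hydrazine,[NX3][NX3]
thiourea,NC(=S)N
curcumin_dienone,C=CC(=O)C=C
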