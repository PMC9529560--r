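pattern,endpoint,likelihood
[CX3H1]=O,mutagenicity,probable
C1OC1,mutagenicity,certain
[c][N+](=O)[O-],mutagenicity,plausible
[#6]N=N[#6],carcinogenicity,plausible
NC(=S)N,thyroid toxicity,equivocal
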