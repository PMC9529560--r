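code,name,smiles,group_label,kind,pka
A,alanine,NC(C)C(=O)O,alpha_carboxyl,acid,2.34
A,alanine,NC(C)C(=O)O,alpha_amine,base,9.69
R,arginine,NC(CCCNC(=N)N)C(=O)O,alpha_carboxyl,acid,2.17
R,arginine,NC(CCCNC(=N)N)C(=O)O,alpha_amine,base,9.04
R,arginine,NC(CCCNC(=N)N)C(=O)O,guanidine,base,12.48
N,asparagine,NC(CC(N)=O)C(=O)O,alpha_carboxyl,acid,2.02
N,asparagine,NC(CC(N)=O)C(=O)O,alpha_amine,base,8.80
D,aspartic acid,NC(CC(O)=O)C(=O)O,alpha_carboxyl,acid,1.88
D,aspartic acid,NC(CC(O)=O)C(=O)O,alpha_amine,base,9.60
D,aspartic acid,NC(CC(O)=O)C(=O)O,side_carboxyl,acid,3.65
C,cysteine,NC(CS)C(=O)O,alpha_carboxyl,acid,1.96
C,cysteine,NC(CS)C(=O)O,alpha_amine,base,10.28
C,cysteine,NC(CS)C(=O)O,thiol,acid,8.18
E,glutamic acid,NC(CCC(O)=O)C(=O)O,alpha_carboxyl,acid,2.19
E,glutamic acid,NC(CCC(O)=O)C(=O)O,alpha_amine,base,9.67
E,glutamic acid,NC(CCC(O)=O)C(=O)O,side_carboxyl,acid,4.25
Q,glutamine,NC(CCC(N)=O)C(=O)O,alpha_carboxyl,acid,2.17
Q,glutamine,NC(CCC(N)=O)C(=O)O,alpha_amine,base,9.13
G,glycine,NCC(=O)O,alpha_carboxyl,acid,2.34
G,glycine,NCC(=O)O,alpha_amine,base,9.60
H,histidine,NC(Cc1c[nH]cn1)C(=O)O,alpha_carboxyl,acid,1.82
H,histidine,NC(Cc1c[nH]cn1)C(=O)O,alpha_amine,base,9.17
H,histidine,NC(Cc1c[nH]cn1)C(=O)O,imidazole,base,6.00
I,isoleucine,NC(C(C)CC)C(=O)O,alpha_carboxyl,acid,2.36
I,isoleucine,NC(C(C)CC)C(=O)O,alpha_amine,base,9.68
L,leucine,NC(CC(C)C)C(=O)O,alpha_carboxyl,acid,2.36
L,leucine,NC(CC(C)C)C(=O)O,alpha_amine,base,9.60
K,lysine,NC(CCCCN)C(=O)O,alpha_carboxyl,acid,2.18
K,lysine,NC(CCCCN)C(=O)O,alpha_amine,base,8.95
K,lysine,NC(CCCCN)C(=O)O,side_amine,base,10.53
M,methionine,NC(CCSC)C(=O)O,alpha_carboxyl,acid,2.28
M,methionine,NC(CCSC)C(=O)O,alpha_amine,base,9.21
F,phenylalanine,NC(Cc1ccccc1)C(=O)O,alpha_carboxyl,acid,1.83
F,phenylalanine,NC(Cc1ccccc1)C(=O)O,alpha_amine,base,9.13
P,proline,N1CCCC1C(=O)O,alpha_carboxyl,acid,1.99
P,proline,N1CCCC1C(=O)O,alpha_amine,base,10.96
S,serine,NC(CO)C(=O)O,alpha_carboxyl,acid,2.21
S,serine,NC(CO)C(=O)O,alpha_amine,base,9.15
T,threonine,NC(C(O)C)C(=O)O,alpha_carboxyl,acid,2.11
T,threonine,NC(C(O)C)C(=O)O,alpha_amine,base,9.62
W,tryptophan,NC(Cc1c[nH]c2ccccc12)C(=O)O,alpha_carboxyl,acid,2.38
W,tryptophan,NC(Cc1c[nH]c2ccccc12)C(=O)O,alpha_amine,base,9.39
Y,tyrosine,NC(Cc1ccc(O)cc1)C(=O)O,alpha_carboxyl,acid,2.20
Y,tyrosine,NC(Cc1ccc(O)cc1)C(=O)O,alpha_amine,base,9.11
Y,tyrosine,NC(Cc1ccc(O)cc1)C(=O)O,phenol,acid,10.07
V,valine,NC(C(C)C)C(=O)O,alpha_carboxyl,acid,2.32
V,valine,NC(C(C)C)C(=O)O,alpha_amine,base,9.62
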