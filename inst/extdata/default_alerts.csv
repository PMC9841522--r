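"label","smarts"
"quinone","O=C1C=CC(=O)C=C1"
"catechol","c1cc([OX2H1])c([OX2H1])cc1"
"rhodanine_like","C1(=O)SC(=S)N1"
"michael_acceptor","[CX3]=[CX3]-[CX3]=[OX1]"
"acyl_halide","[CX3](=O)[F,Cl,Br,I]"
"sulfonyl_halide","[SX4](=O)(=O)[F,Cl,Br,I]"
"aldehyde","[CX3H1](=O)[#6]"
"epoxide_aziridine","[OX2r3,NX3r3]1[#6r3][#6r3]1"
"isocyanate","[NX2]=[CX2]=[OX1]"
"azo","[#6]-[NX2]=[NX2]-[#6]"
"nitroso","[#6]-[NX2]=[OX1]"
"anhydride","[CX3](=O)[OX2][CX3](=O)"
"alpha_halo_ketone","[CX3](=O)[CX4][F,Cl,Br,I]"
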