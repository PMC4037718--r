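# Classic fragrance molecules and named non-fragrance-like exclusions.
# One record per line: SMILES id
CC1OC(C)=C(O)C1=O furaneol
CC(=O)OCCC(C)C isoamyl_acetate
CCCCCCCC(=O)O caprylic_acid
COc1cc(C=O)ccc1O vanillin
O=C/C=C/c1ccccc1 cinnamaldehyde
CC1=CC[C@@H](CC1)C(=C)C limonene
CC1=CCC2CC1C2(C)C alpha_pinene
CC1(C)C2CCC1(C)C(=O)C2 camphor
CC1CCC(C(C)C)C(=O)C1 menthone
CC1CCO[C@@H](C=C(C)C)C1 rose_oxide
CC(C)[C@@H]1CC[C@H](C)C[C@H]1O menthol
OCCC(C)CCC=C(C)C citronellol
CCCCCCCCCCCC=O lauraldehyde
CC(=C)[C@@H]1CC(C)=CC(=O)C1 carvone_minus
CC(=C)[C@H]1CC(C)=CC(=O)C1 carvone_plus
c1cnccn1 pyrazine
CCOC(=O)c1ccccc1N ethyl_anthranilate
CCc1cccnc1 ethylpyridine_3
SC1CCCC1 cyclopentanethiol
CSSC dimethyl_disulfide
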