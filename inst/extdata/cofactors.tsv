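# Packaged cofactor / supporting-molecule exclusion list.
# Editable: one molecule per line, name<TAB>smiles. Lines starting with '#'
# are ignored. Molecules are matched by canonical SMILES key after the same
# canonicalization applied to substrate records (largest covalent fragment,
# implicit hydrogens), so counter-ions listed here also catch salt forms.
water	O
ammonia	N
oxygen	O=O
carbon_dioxide	O=C=O
hydrogen_peroxide	OO
phosphate	OP(=O)(O)O
pyrophosphate	OP(=O)(O)OP(=O)(O)O
sodium_ion	[Na+]
potassium_ion	[K+]
chloride_ion	[Cl-]
magnesium_ion	[Mg+2]
calcium_ion	[Ca+2]
iron_ii_ion	[Fe+2]
iron_iii_ion	[Fe+3]
zinc_ion	[Zn+2]
manganese_ion	[Mn+2]
copper_ii_ion	[Cu+2]
atp	Nc1ncnc2c1ncn2C1OC(COP(=O)(O)OP(=O)(O)OP(=O)(O)O)C(O)C1O
adp	Nc1ncnc2c1ncn2C1OC(COP(=O)(O)OP(=O)(O)O)C(O)C1O
amp	Nc1ncnc2c1ncn2C1OC(COP(=O)(O)O)C(O)C1O
nad_plus	NC(=O)c1ccc[n+](c1)C1OC(COP(=O)(O)OP(=O)(O)OCC2OC(n3cnc4c(N)ncnc43)C(O)C2O)C(O)C1O
nadh	NC(=O)C1=CN(C2OC(COP(=O)(O)OP(=O)(O)OCC3OC(n4cnc5c(N)ncnc54)C(O)C3O)C(O)C2O)C=CC1
nadp_plus	NC(=O)c1ccc[n+](c1)C1OC(COP(=O)(O)OP(=O)(O)OCC2OC(n3cnc4c(N)ncnc43)C(OP(=O)(O)O)C2O)C(O)C1O
nadph	NC(=O)C1=CN(C2OC(COP(=O)(O)OP(=O)(O)OCC3OC(n4cnc5c(N)ncnc54)C(OP(=O)(O)O)C3O)C(O)C2O)C=CC1
fad	CC1=CC2=C(C=C1C)N(CC(O)C(O)C(O)COP(=O)(O)OP(=O)(O)OCC3OC(n4cnc5c(N)ncnc54)C(O)C3O)C3=NC(=O)NC(=O)C3=N2
fmn	CC1=CC2=C(C=C1C)N(CC(O)C(O)C(O)COP(=O)(O)O)C3=NC(=O)NC(=O)C3=N2
coenzyme_a	CC(C)(COP(=O)(O)OP(=O)(O)OCC1OC(n2cnc3c(N)ncnc32)C(O)C1OP(=O)(O)O)C(O)C(=O)NCCC(=O)NCCS
glutathione	NC(CCC(=O)NC(CS)C(=O)NCC(=O)O)C(=O)O
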