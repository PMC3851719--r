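# Nearest-neighbor RNA duplex free-energy parameters, set "turner2004"
# source: Xia et al. 1998 Watson-Crick stacks (two decimals) + ViennaRNA 2.7.2 rna_turner2004.par wobble stacks; Turner 2004 rules
# units: kcal/mol at 37 C (convert to kJ/mol at 4.184)
# key XY/ZW: top strand 5'-XY-3' stacked on bottom strand 5'-ZW-3' (pairs X.W and Y.Z)
type	key	value
stack	CG/CG	-2.36
stack	CC/GG	-3.26
stack	CU/GG	-2.10
stack	CG/UG	-1.40
stack	CU/AG	-2.08
stack	CA/UG	-2.11
stack	GG/CC	-3.26
stack	GC/GC	-3.42
stack	GU/GC	-2.50
stack	GG/UC	-1.50
stack	GU/AC	-2.24
stack	GA/UC	-2.35
stack	GG/CU	-2.10
stack	GC/GU	-2.50
stack	GU/GU	1.30
stack	GG/UU	-0.50
stack	GU/AU	-1.40
stack	GA/UU	-1.30
stack	UG/CG	-1.40
stack	UC/GG	-1.50
stack	UU/GG	-0.50
stack	UG/UG	0.30
stack	UU/AG	-0.60
stack	UA/UG	-1.00
stack	AG/CU	-2.08
stack	AC/GU	-2.24
stack	AU/GU	-1.40
stack	AG/UU	-0.60
stack	AU/AU	-1.10
stack	AA/UU	-0.93
stack	UG/CA	-2.11
stack	UC/GA	-2.35
stack	UU/GA	-1.30
stack	UG/UA	-1.00
stack	UU/AA	-0.93
stack	UA/UA	-1.33
init	-	4.09
terminal_au	-	0.45
symmetry	-	0.43
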