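# Nearest-neighbor RNA duplex free-energy parameters, set "turner1999"
# source: Turner/Mathews 1999 rules as distributed with ViennaRNA 2.7.2 (rna_turner1999.par stack + Misc tables)
# units: kcal/mol at 37 C (convert to kJ/mol at 4.184)
# key XY/ZW: top strand 5'-XY-3' stacked on bottom strand 5'-ZW-3' (pairs X.W and Y.Z)
type	key	value
stack	CG/CG	-2.40
stack	CC/GG	-3.30
stack	CU/GG	-2.10
stack	CG/UG	-1.40
stack	CU/AG	-2.10
stack	CA/UG	-2.10
stack	GG/CC	-3.30
stack	GC/GC	-3.40
stack	GU/GC	-2.50
stack	GG/UC	-1.50
stack	GU/AC	-2.20
stack	GA/UC	-2.40
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
stack	AG/CU	-2.10
stack	AC/GU	-2.20
stack	AU/GU	-1.40
stack	AG/UU	-0.60
stack	AU/AU	-1.10
stack	AA/UU	-0.90
stack	UG/CA	-2.10
stack	UC/GA	-2.40
stack	UU/GA	-1.30
stack	UG/UA	-1.00
stack	UU/AA	-0.90
stack	UA/UA	-1.30
init	-	4.10
terminal_au	-	0.50
symmetry	-	0.43
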