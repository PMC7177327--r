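# Nearest-neighbor free-energy parameters for intermolecular RNA:RNA
# duplexes, kcal/mol at 37 C.
# Watson-Crick stack values follow the Xia/Turner nearest-neighbor set;
# G:U wobble stacks follow the same style, with the tandem-wobble entries
# kept mildly favorable so that every stack in the table is < 0 and the
# model is internally consistent. Wobble stacks not listed default to
# -0.50 (see default_energy_model()).
# Stack notation XY/ZW: top strand 5'-XY-3' over bottom strand 3'-ZW-5',
# i.e. pairs X:Z and Y:W. The mirror entry WZ/YX is implied.
# kind	key	value
stack	AA/UU	-0.93
stack	AU/UA	-1.10
stack	UA/AU	-1.33
stack	CU/GA	-2.08
stack	CA/GU	-2.11
stack	GU/CA	-2.24
stack	GA/CU	-2.35
stack	CG/GC	-2.36
stack	GG/CC	-3.26
stack	GC/CG	-3.42
stack	AG/UU	-0.55
stack	AU/UG	-1.36
stack	CG/GU	-1.41
stack	CU/GG	-2.11
stack	GG/CU	-1.53
stack	GU/CG	-2.51
stack	GA/UU	-0.27
stack	UG/AU	-1.36
stack	GG/UU	-0.50
stack	GU/UG	-0.30
stack	UG/GU	-0.30
param	duplex_init	4.09
param	bulge_open	3.80
param	bulge_extend	0.40
param	internal_open	2.00
param	internal_extend	0.50
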