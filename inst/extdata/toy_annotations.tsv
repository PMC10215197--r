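protein_id	is_mitochondrial	pathway_bin	flags
MT001	1	TCA cycle	disulfide
MT002	1	ETC	
MT003	1	redox regulation	metal_binding
MT004	1	transport	
MT005	1	mt ribosomal subunits	
MT006	1	urea cycle	s_palmitoylation
MT007	1	fatty acid oxidation	
MT008	1	Fe-S biogenesis	
MT009	1	apoptosis	
MT010	1	other	
CY001	0	other	
CY002	0	other	
CY003	0	other	
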