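cas_rn	kegg_id	compound_name
89-78-1	C00400	Menthol
21634-04-4	C11344	tert-Butyl ethyl ether
107-87-9	C01949	2-Pentanone
67-64-1	C00207	Acetone
64-17-5	C00469	Ethanol
50-00-0	C00067	Formaldehyde
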