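kegg_id	pathway_id	pathway_name
C00400	map00902	Monoterpenoid biosynthesis
C00207	map00072	Synthesis and degradation of ketone bodies
C00207	map00640	Propanoate metabolism
C00469	map00010	Glycolysis / Gluconeogenesis
C00067	map00680	Methane metabolism
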