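term_id	term_name	gene_id
GO:0006954	inflammatory response	probe_00001
GO:0006954	inflammatory response	probe_00010
GO:0006954	inflammatory response	probe_00018
GO:0006954	inflammatory response	probe_00024
GO:0006954	inflammatory response	probe_00025
GO:0006954	inflammatory response	probe_00036
GO:0006954	inflammatory response	probe_00037
GO:0006954	inflammatory response	probe_00049
GO:0032496	response to lipopolysaccharide	probe_00003
GO:0032496	response to lipopolysaccharide	probe_00007
GO:0032496	response to lipopolysaccharide	probe_00020
GO:0032496	response to lipopolysaccharide	probe_00025
GO:0032496	response to lipopolysaccharide	probe_00026
GO:0032496	response to lipopolysaccharide	probe_00036
GO:0032496	response to lipopolysaccharide	probe_00037
GO:0032496	response to lipopolysaccharide	probe_00046
GO:0002376	immune system process	probe_00005
GO:0002376	immune system process	probe_00020
GO:0002376	immune system process	probe_00025
GO:0002376	immune system process	probe_00027
GO:0002376	immune system process	probe_00031
GO:0002376	immune system process	probe_00036
GO:0002376	immune system process	probe_00037
GO:0002376	immune system process	probe_00041
GO:0031663	lipopolysaccharide-mediated signaling pathway	probe_00003
GO:0031663	lipopolysaccharide-mediated signaling pathway	probe_00024
GO:0031663	lipopolysaccharide-mediated signaling pathway	probe_00028
GO:0031663	lipopolysaccharide-mediated signaling pathway	probe_00030
GO:0031663	lipopolysaccharide-mediated signaling pathway	probe_00033
GO:0031663	lipopolysaccharide-mediated signaling pathway	probe_00034
GO:0031663	lipopolysaccharide-mediated signaling pathway	probe_00040
GO:0031663	lipopolysaccharide-mediated signaling pathway	probe_00042
GO:0006955	immune response	probe_00004
GO:0006955	immune response	probe_00008
GO:0006955	immune response	probe_00015
GO:0006955	immune response	probe_00018
GO:0006955	immune response	probe_00022
GO:0006955	immune response	probe_00036
GO:0006955	immune response	probe_00043
GO:0006955	immune response	probe_00048
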