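rs_id,gene,effect_allele,other_allele
rs12913832,HERC2,T,C
rs1800407,OCA2,A,G
rs12896399,SLC24A4,T,G
rs16891982,SLC45A2,C,G
rs1393350,TYR,A,G
rs12203592,IRF4,T,C
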