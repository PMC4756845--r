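probe_id,design_type,channel,chromosome
cg0001,I,red,chr1
cg0002,I,green,chr2
cg0003,II,,chr3
cg0004,II,,chrX
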