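population	normal	sterile	ratio
WT-a x MT-a	112	125	1:1
WT-b x MT-b	46	136	1:3
WT-c x MT-c	65	108	1:3
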