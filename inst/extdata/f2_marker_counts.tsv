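population	marker	homozygous_WT	heterozygous_TL	homozygous_TL
WT-a x MT-a	Chr6 + Chr6^10	51	125	61
WT-a x MT-a	Chr10 + Chr10^6	51	125	61
WT-b x MT-b	Chr1 + Chr1^5	52	89	41
WT-b x MT-b	Chr5 + Chr5^1	49	91	42
WT-b x MT-b	Chr4 + Chr4^8	54	88	40
WT-b x MT-b	Chr8 + Chr8^4	49	89	44
WT-c x MT-c	Chr1 + Chr1^5	44	82	47
WT-c x MT-c	Chr5 + Chr5^1	44	82	47
WT-c x MT-c	Chr5 + Chr5^11	37	93	43
WT-c x MT-c	Chr11 + Chr11^5	37	93	43
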