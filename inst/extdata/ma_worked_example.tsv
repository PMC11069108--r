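category	target_size	mutations
snv_total	9080403	428
nonsynonymous	6053873	249
synonymous	2143616	109
intergenic	828655	65
pseudogenic	47343	2
rna_coding	6917	3
indel_total	9080403	39
indel_non_str	9080403	12
indel_str	25664	27
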