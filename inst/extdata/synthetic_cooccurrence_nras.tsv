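group	nras_mut	nras_wt
fusion_pos	7	6
fusion_neg	13	65
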