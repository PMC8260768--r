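chrom	pos	ref	alt	tumor_ref	tumor_alt	remission_ref	remission_alt
chr1	10177	A	T	80	20	99	1
chr2	55242	G	A	96	4	99	1
chr5	134114	C	T	50	50	52	48
chr9	21970	G	T	60	40	100	0
chr11	47354	T	C	0	0	100	0
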