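gene_i	gene_j	condition	sign
G0010	G0011	NOR	1
G0010	G0012	NOR	1
G0010	G0013	NOR	1
G0011	G0012	NOR	1
G0011	G0013	NOR	1
G0012	G0013	NOR	1
G0010	G0011	TUM	1
G0010	G0012	TUM	1
G0010	G0013	TUM	1
G0011	G0012	TUM	1
G0011	G0013	TUM	1
G0012	G0013	TUM	1
G0020	G0021	NOR	-1
G0020	G0021	TUM	-1
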