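name	notation	family
asnase2_thr_loop	TGGTxAGG	PF00710.11
asnase2_hgtdt	HGTDTM	PF00710.11
ntn_core	NCSGKHxAM	PF06089.11
dgcgapl	DGCGAPL	PF06089.11
shsge_helix	SHSGEx(2)H	PF06089.11
prs_helix	PRSx(2)KPxQ	PF06089.11
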