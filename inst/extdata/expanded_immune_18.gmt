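EXPANDED_IMMUNE_18	Published 18-gene expanded immune signature (checkpoint-blockade response; Ayers et al. 2017, J Clin Invest 127:2930)	CD3D	IDO1	CIITA	CD3E	CCL5	GZMK	CD2	HLA-DRA	CXCL13	IL2RG	NKG7	HLA-E	CXCR6	LAG3	TAGAP	CXCL10	STAT1	GZMB
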