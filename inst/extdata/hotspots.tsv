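gene	aa_change	label
KRAS	p.Gly12Asp	KRAS_G12
KRAS	p.Gly12Val	KRAS_G12
KRAS	p.Gly12Cys	KRAS_G12
KRAS	p.Gly12Ser	KRAS_G12
KRAS	p.Gly12Ala	KRAS_G12
KRAS	p.Gly12Arg	KRAS_G12
KRAS	p.Gly13Asp	KRAS_G13
KRAS	p.Gln61His	KRAS_Q61
KRAS	p.Gln61Arg	KRAS_Q61
KRAS	p.Gln61Leu	KRAS_Q61
KRAS	p.Gln61Lys	KRAS_Q61
NRAS	p.Gln61Arg	NRAS_Q61
NRAS	p.Gln61Lys	NRAS_Q61
NRAS	p.Gln61Leu	NRAS_Q61
NRAS	p.Gln61His	NRAS_Q61
NRAS	p.Gly12Asp	NRAS_G12
NRAS	p.Gly13Asp	NRAS_G13
HRAS	p.Gly12Val	HRAS_G12
HRAS	p.Gln61Arg	HRAS_Q61
BRAF	p.Val600Glu	BRAF_V600
MAP2K1	p.Lys57Thr	MAP2K1_K57
MAP2K1	p.Lys57Asn	MAP2K1_K57
MAP2K1	p.Lys57Glu	MAP2K1_K57
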