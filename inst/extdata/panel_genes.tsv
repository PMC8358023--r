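gene	min_panel
APC	v2
TP53	v2
KRAS	v2
PIK3CA	v2
BRAF	v2
EGFR	v2
ERBB2	v2
ERBB3	v2
FGFR1	v2
NRAS	v2
HRAS	v2
IRS1	v3
MAP2K1	v3
MET	v3
PDGFRB	v3
PTEN	v3
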