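gene	n_mutations	n_patients	pct_patients
APC	111	72	77.4
TP53	71	64	68.8
ERBB2	13	9	9.7
PTEN	6	5	7.2
KRAS	7	6	6.5
PIK3CA	6	6	6.5
MET	4	3	4.3
PDGFRB	3	3	4.3
BRAF	3	3	3.2
NRAS	2	2	2.2
ERBB3	2	2	2.2
MAP2K1	1	1	1.4
EGFR	1	1	1.1
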