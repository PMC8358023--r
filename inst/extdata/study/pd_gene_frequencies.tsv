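gene	n_mutations	n_patients	pct_patients
APC	10	7	14.9
TP53	9	7	14.9
ERBB2	8	6	12.8
KRAS	5	5	10.6
PIK3CA	5	2	4.3
MAP2K1	4	4	13.8
ERBB3	3	3	6.4
MET	3	1	3.4
PDGFRB	2	2	6.9
EGFR	2	2	4.3
PTEN	1	1	3.4
NRAS	1	1	2.1
HRAS	1	1	2.1
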