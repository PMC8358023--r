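gene	base_change	aa_change	chrom	pos	ref	alt	pathogenicity
KRAS	c.35G > T	p.Gly12Val	12	25398284	C	A	pathogenic
KRAS	c.34G > T	p.Gly12Cys	12	25398285	C	A	pathogenic
KRAS	c.35G > A	p.Gly12Asp	12	25398284	C	T	pathogenic
KRAS	c.38G > A	p.Gly13Asp	12	25398281	C	T	pathogenic
KRAS	c.183A > C	p.Gln61His	12	25380275	T	G	pathogenic
NRAS	c.182A > G	p.Gln61Arg	1	115256529	T	C	pathogenic
MAP2K1	c.171G > T	p.Lys57Asn	15	66727455	G	T	pathogenic
MAP2K1	c.170A > C	p.Lys57Thr	15	66727454	A	C	likely_pathogenic
TP53	c.733G > A	p.Gly245Ser	17	7577548	C	T	pathogenic
APC	c.4348C > T	p.Arg1450*	5	112175639	C	T	pathogenic
APC	c.6610C > T	p.Arg2204*	5	112177901	C	T	likely_pathogenic
PTEN	c.518G > A	p.Arg173His	10	89711900	G	A	pathogenic
BRAF	c.1799T > A	p.Val600Glu	7	140453136	A	T	pathogenic
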