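family	site_index	allowed_kinds
H3.2	4	me1,me2,me3
H3.2	9	ac,me1,me2,me3
H3.2	14	ac
H3.2	18	ac
H3.2	23	ac
H3.2	27	ac,me1,me2,me3
H3.2	36	me1,me2,me3
H4	0	ac
H4	5	ac
H4	8	ac
H4	12	ac
H4	16	ac
H4	20	me1,me2,me3
H4	31	ac
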