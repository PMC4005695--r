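kind	key	value
stack	AT:AT	-1.8
stack	AT:TA	-1.8
stack	AT:GC	-2.4
stack	AT:CG	-2.4
stack	AT:GT	-1.45
stack	AT:TG	-1.45
stack	TA:AT	-1.8
stack	TA:TA	-1.8
stack	TA:GC	-2.4
stack	TA:CG	-2.4
stack	TA:GT	-1.45
stack	TA:TG	-1.45
stack	GC:AT	-2.4
stack	GC:TA	-2.4
stack	GC:GC	-3
stack	GC:CG	-3
stack	GC:GT	-2.05
stack	GC:TG	-2.05
stack	CG:AT	-2.4
stack	CG:TA	-2.4
stack	CG:GC	-3
stack	CG:CG	-3
stack	CG:GT	-2.05
stack	CG:TG	-2.05
stack	GT:AT	-1.45
stack	GT:TA	-1.45
stack	GT:GC	-2.05
stack	GT:CG	-2.05
stack	GT:GT	-1.1
stack	GT:TG	-1.1
stack	TG:AT	-1.45
stack	TG:TA	-1.45
stack	TG:GC	-2.05
stack	TG:CG	-2.05
stack	TG:GT	-1.1
stack	TG:TG	-1.1
hairpin	3	5.2
hairpin	4	5.45
hairpin	5	5.7
hairpin	6	5.95
hairpin	7	6.2
hairpin	8	6.45
hairpin	9	6.7
hairpin	10	6.82
hairpin	11	6.92
hairpin	12	7.02
hairpin	13	7.1
hairpin	14	7.19
hairpin	15	7.26
hairpin	16	7.33
hairpin	17	7.4
hairpin	18	7.46
hairpin	19	7.52
hairpin	20	7.58
hairpin	21	7.63
hairpin	22	7.68
hairpin	23	7.73
hairpin	24	7.78
hairpin	25	7.82
hairpin	26	7.87
hairpin	27	7.91
hairpin	28	7.95
hairpin	29	7.99
hairpin	30	8.02
dangle	AT|A|5p	-0.48
dangle	AT|A|3p	-0.58
dangle	AT|G|5p	-0.42
dangle	AT|G|3p	-0.52
dangle	AT|C|5p	-0.37
dangle	AT|C|3p	-0.48
dangle	AT|T|5p	-0.37
dangle	AT|T|3p	-0.48
dangle	TA|A|5p	-0.48
dangle	TA|A|3p	-0.58
dangle	TA|G|5p	-0.42
dangle	TA|G|3p	-0.52
dangle	TA|C|5p	-0.37
dangle	TA|C|3p	-0.48
dangle	TA|T|5p	-0.37
dangle	TA|T|3p	-0.48
dangle	GC|A|5p	-0.62
dangle	GC|A|3p	-0.72
dangle	GC|G|5p	-0.58
dangle	GC|G|3p	-0.67
dangle	GC|C|5p	-0.52
dangle	GC|C|3p	-0.62
dangle	GC|T|5p	-0.52
dangle	GC|T|3p	-0.62
dangle	CG|A|5p	-0.62
dangle	CG|A|3p	-0.72
dangle	CG|G|5p	-0.58
dangle	CG|G|3p	-0.67
dangle	CG|C|5p	-0.52
dangle	CG|C|3p	-0.62
dangle	CG|T|5p	-0.52
dangle	CG|T|3p	-0.62
dangle	GT|A|5p	-0.39
dangle	GT|A|3p	-0.49
dangle	GT|G|5p	-0.34
dangle	GT|G|3p	-0.44
dangle	GT|C|5p	-0.29
dangle	GT|C|3p	-0.39
dangle	GT|T|5p	-0.29
dangle	GT|T|3p	-0.39
dangle	TG|A|5p	-0.39
dangle	TG|A|3p	-0.49
dangle	TG|G|5p	-0.34
dangle	TG|G|3p	-0.44
dangle	TG|C|5p	-0.29
dangle	TG|C|3p	-0.39
dangle	TG|T|5p	-0.29
dangle	TG|T|3p	-0.39
const	duplex_init	4.1
const	min_hairpin	3
const	duplex_loop_open	2
const	duplex_loop_base	0.5
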