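base	p1	p2	p3	p4	p5	p6
A	60	15	10	65	15	15
C	10	5	5	10	5	10
G	15	70	75	10	70	55
T	15	10	10	15	10	20
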