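anticodon	copies
GGC	2
TGC	3
GCC	4
TCC	1
CCC	1
TGG	1
GGG	1
CGG	1
GGT	2
CGT	1
TGT	1
TAC	5
GAC	2
TAA	1
CAA	1
TAG	1
GAG	1
CAG	4
GAT	3
CAT	6
TGA	1
CGA	1
GGA	2
GCT	1
ACG	4
CCG	1
TCT	1
CCT	1
TTG	2
CTG	2
GTT	4
TTT	6
GTC	3
TTC	4
GTG	1
GAA	2
GTA	3
GCA	1
CCA	1
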