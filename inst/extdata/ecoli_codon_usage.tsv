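codon	aa	fraction
GCA	A	0.274859
GCC	A	0.0572233
GCG	A	0.198874
GCT	A	0.469043
TGC	C	0.666667
TGT	C	0.333333
GAC	D	0.69735
GAT	D	0.30265
GAA	E	0.794281
GAG	E	0.205719
TTC	F	0.771605
TTT	F	0.228395
GGA	G	0.00570451
GGC	G	0.413006
GGG	G	0.0108386
GGT	G	0.570451
CAC	H	0.774593
CAT	H	0.225407
ATA	I	0.00252525
ATC	I	0.841751
ATT	I	0.155724
AAA	K	0.798085
AAG	K	0.201915
CTA	L	0.0062167
CTC	L	0.0328597
CTG	L	0.888099
CTT	L	0.0373002
TTA	L	0.017762
TTG	L	0.017762
ATG	M	1
AAC	N	0.951475
AAT	N	0.0485252
CCA	P	0.110929
CCC	P	0.00986031
CCG	P	0.821693
CCT	P	0.0575185
CAA	Q	0.11032
CAG	Q	0.88968
AGA	R	0.00291971
AGG	R	0.00145985
CGA	R	0.00291971
CGC	R	0.259854
CGG	R	0.00291971
CGT	R	0.729927
AGC	S	0.175739
AGT	S	0.0364338
TCA	S	0.0330047
TCC	S	0.318903
TCG	S	0.00728676
TCT	S	0.428633
ACA	T	0.035514
ACC	T	0.46729
ACG	T	0.0462617
ACT	T	0.450935
GTA	V	0.277778
GTC	V	0.037037
GTG	V	0.124018
GTT	V	0.561167
TGG	W	1
TAC	Y	0.807103
TAT	Y	0.192897
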