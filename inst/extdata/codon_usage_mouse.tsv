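# Mus musculus codon usage fractions (per amino acid), standard reference
# table values; renormalised per amino acid on load.
# columns: amino acid (1-letter, * = stop), codon, fraction
aa	codon	fraction
A	GCT	0.29
A	GCC	0.38
A	GCA	0.23
A	GCG	0.10
R	CGT	0.09
R	CGC	0.18
R	CGA	0.12
R	CGG	0.19
R	AGA	0.21
R	AGG	0.22
N	AAT	0.43
N	AAC	0.57
D	GAT	0.45
D	GAC	0.55
C	TGT	0.48
C	TGC	0.52
Q	CAA	0.26
Q	CAG	0.74
E	GAA	0.41
E	GAG	0.59
G	GGT	0.18
G	GGC	0.33
G	GGA	0.26
G	GGG	0.23
H	CAT	0.41
H	CAC	0.59
I	ATT	0.34
I	ATC	0.50
I	ATA	0.16
L	TTA	0.07
L	TTG	0.13
L	CTT	0.13
L	CTC	0.20
L	CTA	0.08
L	CTG	0.39
K	AAA	0.39
K	AAG	0.61
M	ATG	1.00
F	TTT	0.44
F	TTC	0.56
P	CCT	0.31
P	CCC	0.30
P	CCA	0.29
P	CCG	0.10
S	TCT	0.20
S	TCC	0.22
S	TCA	0.14
S	TCG	0.05
S	AGT	0.15
S	AGC	0.24
T	ACT	0.25
T	ACC	0.35
T	ACA	0.29
T	ACG	0.10
W	TGG	1.00
Y	TAT	0.43
Y	TAC	0.57
V	GTT	0.17
V	GTC	0.25
V	GTA	0.12
V	GTG	0.46
*	TAA	0.28
*	TAG	0.24
*	TGA	0.48
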