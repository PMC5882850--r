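# qPCR assay primers for the opto-GPR37 workflow (5'->3').
# The published reverse opto-GPR37 primer and forward GAPDH primer each
# contain an internal space in print (almost certainly a typesetting
# artifact); they are stored here with the space removed. If the space were
# meaningful the oligos would be unusable as written, so this reading is
# flagged rather than silently assumed.
name	forward	reverse
GAPDH	TTGTGATGGGTGTGAACCACGAGA	GAGCCCTTCCACAATGCCAAAGTT
GPR37	ACCGGACACAATCTATGTTTTGG	TCTTCCGAGCAGTCACTAGAG
opto-GPR37	TGACAACGAGTACACCACGG	GCTTCGTCGCAATGAGTTCC
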