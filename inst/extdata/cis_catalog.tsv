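element	pattern	class
G-Box	CACGTG	light
ABRE	ACGTG	hormone-ABA
CGTCA-motif	CGTCA	hormone-MeJA
TGACG-motif	TGACG	hormone-MeJA
P-box	CCTTTTG	hormone-GA
GARE-motif	TCTGTTG	hormone-GA
TGA-element	AACGAC	hormone-auxin
TCA-element	CCATCTTTTT	hormone-SA
HSE	AAAAAATTTC	stress
MBS	CAACTG	stress
TC-rich repeats	ATTTTCTTCA	stress
CAT-box	GCCACT	meristem
CCGTCC-box	CCGTCC	meristem
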