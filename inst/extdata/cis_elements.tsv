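name	iupac
G-box	CACGTG
ABRE	ACGTGKC
CGTCA-motif	CGTCA
TGACG-motif	TGACG
MBS	CAACTG
LTR	CCGAAA
ERE	ATTTCAAA
TGA-element	AACGAC
TATC-box	TATCCCA
GARE-motif	TCTGTTG
Box4	ATTAAT
Sp1	GGGCGG
GATA-motif	AAGGATAAGG
TCT-motif	TCTTAC
TCCC-motif	TCTCCCT
ACE	ACGTGGA
AE-box	AGAAACAA
GA-motif	ATAGATAA
Gap-box	CAAATGAA
TATA-box	TATAWAW
CAAT-box	CCAAT
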