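MEME version 4

ALPHABET= ACGT

strands: + -

Background letter frequencies
A 0.25000 C 0.25000 G 0.25000 T 0.25000

MOTIF MOTIF_bHLH
letter-probability matrix: alength= 4 w= 10 nsites= 20 E= 0
0.015000 0.015000 0.015000 0.955000
0.015000 0.015000 0.015000 0.955000
0.015000 0.955000 0.015000 0.015000
0.015000 0.015000 0.015000 0.955000
0.015000 0.015000 0.015000 0.955000
0.015000 0.015000 0.015000 0.955000
0.015000 0.955000 0.015000 0.015000
0.015000 0.955000 0.015000 0.015000
0.955000 0.015000 0.015000 0.015000
0.015000 0.015000 0.955000 0.015000

MOTIF MOTIF_WRKY
letter-probability matrix: alength= 4 w= 10 nsites= 20 E= 0
0.955000 0.015000 0.015000 0.015000
0.015000 0.015000 0.955000 0.015000
0.955000 0.015000 0.015000 0.015000
0.955000 0.015000 0.015000 0.015000
0.955000 0.015000 0.015000 0.015000
0.015000 0.015000 0.955000 0.015000
0.015000 0.015000 0.015000 0.955000
0.015000 0.955000 0.015000 0.015000
0.955000 0.015000 0.015000 0.015000
0.015000 0.955000 0.015000 0.015000

MOTIF MOTIF_ERF
letter-probability matrix: alength= 4 w= 10 nsites= 20 E= 0
0.015000 0.015000 0.955000 0.015000
0.015000 0.955000 0.015000 0.015000
0.015000 0.015000 0.015000 0.955000
0.955000 0.015000 0.015000 0.015000
0.015000 0.015000 0.955000 0.015000
0.015000 0.015000 0.015000 0.955000
0.015000 0.955000 0.015000 0.015000
0.015000 0.955000 0.015000 0.015000
0.015000 0.955000 0.015000 0.015000
0.015000 0.955000 0.015000 0.015000

MOTIF MOTIF_B3
letter-probability matrix: alength= 4 w= 10 nsites= 20 E= 0
0.955000 0.015000 0.015000 0.015000
0.015000 0.015000 0.015000 0.955000
0.955000 0.015000 0.015000 0.015000
0.015000 0.015000 0.015000 0.955000
0.015000 0.015000 0.015000 0.955000
0.015000 0.015000 0.015000 0.955000
0.015000 0.015000 0.955000 0.015000
0.015000 0.015000 0.955000 0.015000
0.015000 0.015000 0.955000 0.015000
0.015000 0.015000 0.955000 0.015000

MOTIF MOTIF_MYB_related
letter-probability matrix: alength= 4 w= 10 nsites= 20 E= 0
0.015000 0.015000 0.955000 0.015000
0.955000 0.015000 0.015000 0.015000
0.955000 0.015000 0.015000 0.015000
0.015000 0.955000 0.015000 0.015000
0.015000 0.015000 0.015000 0.955000
0.015000 0.015000 0.015000 0.955000
0.015000 0.015000 0.955000 0.015000
0.015000 0.955000 0.015000 0.015000
0.015000 0.955000 0.015000 0.015000
0.015000 0.015000 0.955000 0.015000

MOTIF MOTIF_C2H2
letter-probability matrix: alength= 4 w= 10 nsites= 20 E= 0
0.015000 0.015000 0.955000 0.015000
0.015000 0.955000 0.015000 0.015000
0.015000 0.015000 0.955000 0.015000
0.015000 0.955000 0.015000 0.015000
0.015000 0.015000 0.015000 0.955000
0.015000 0.955000 0.015000 0.015000
0.015000 0.955000 0.015000 0.015000
0.015000 0.955000 0.015000 0.015000
0.955000 0.015000 0.015000 0.015000
0.955000 0.015000 0.015000 0.015000

MOTIF MOTIF_NAC
letter-probability matrix: alength= 4 w= 10 nsites= 20 E= 0
0.015000 0.015000 0.015000 0.955000
0.955000 0.015000 0.015000 0.015000
0.955000 0.015000 0.015000 0.015000
0.955000 0.015000 0.015000 0.015000
0.955000 0.015000 0.015000 0.015000
0.015000 0.015000 0.015000 0.955000
0.015000 0.015000 0.015000 0.955000
0.015000 0.015000 0.015000 0.955000
0.015000 0.015000 0.015000 0.955000
0.015000 0.015000 0.955000 0.015000

MOTIF MOTIF_WD40
letter-probability matrix: alength= 4 w= 10 nsites= 20 E= 0
0.015000 0.015000 0.015000 0.955000
0.015000 0.015000 0.955000 0.015000
0.955000 0.015000 0.015000 0.015000
0.015000 0.955000 0.015000 0.015000
0.015000 0.955000 0.015000 0.015000
0.015000 0.955000 0.015000 0.015000
0.015000 0.015000 0.955000 0.015000
0.015000 0.015000 0.015000 0.955000
0.955000 0.015000 0.015000 0.015000
0.015000 0.015000 0.955000 0.015000

MOTIF MOTIF_GRAS
letter-probability matrix: alength= 4 w= 10 nsites= 20 E= 0
0.955000 0.015000 0.015000 0.015000
0.015000 0.015000 0.955000 0.015000
0.015000 0.015000 0.955000 0.015000
0.955000 0.015000 0.015000 0.015000
0.955000 0.015000 0.015000 0.015000
0.015000 0.015000 0.015000 0.955000
0.955000 0.015000 0.015000 0.015000
0.955000 0.015000 0.015000 0.015000
0.015000 0.955000 0.015000 0.015000
0.015000 0.955000 0.015000 0.015000

MOTIF MOTIF_MYB
letter-probability matrix: alength= 4 w= 10 nsites= 20 E= 0
0.015000 0.015000 0.015000 0.955000
0.015000 0.015000 0.955000 0.015000
0.015000 0.015000 0.955000 0.015000
0.955000 0.015000 0.015000 0.015000
0.955000 0.015000 0.015000 0.015000
0.015000 0.955000 0.015000 0.015000
0.015000 0.955000 0.015000 0.015000
0.015000 0.015000 0.955000 0.015000
0.015000 0.955000 0.015000 0.015000
0.015000 0.015000 0.955000 0.015000

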