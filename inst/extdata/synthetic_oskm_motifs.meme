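MEME version 4

ALPHABET= ACGT

Background letter frequencies
A 0.25 C 0.25 G 0.25 T 0.25

MOTIF Oct4
letter-probability matrix: alength= 4 w= 10 nsites= 100 E= 0
 0.010 0.010 0.010 0.970
 0.970 0.010 0.010 0.010
 0.010 0.010 0.010 0.970
 0.010 0.010 0.970 0.010
 0.010 0.970 0.010 0.010
 0.970 0.010 0.010 0.010
 0.970 0.010 0.010 0.010
 0.970 0.010 0.010 0.010
 0.010 0.010 0.010 0.970
 0.010 0.010 0.010 0.970

MOTIF Sox2
letter-probability matrix: alength= 4 w= 10 nsites= 100 E= 0
 0.010 0.970 0.010 0.010
 0.010 0.970 0.010 0.010
 0.970 0.010 0.010 0.010
 0.010 0.010 0.010 0.970
 0.010 0.010 0.010 0.970
 0.010 0.010 0.970 0.010
 0.010 0.010 0.010 0.970
 0.010 0.010 0.010 0.970
 0.010 0.970 0.010 0.010
 0.010 0.010 0.010 0.970

MOTIF Klf4
letter-probability matrix: alength= 4 w= 10 nsites= 100 E= 0
 0.970 0.010 0.010 0.010
 0.010 0.010 0.970 0.010
 0.010 0.010 0.970 0.010
 0.010 0.010 0.970 0.010
 0.010 0.010 0.970 0.010
 0.010 0.010 0.010 0.970
 0.010 0.010 0.970 0.010
 0.010 0.010 0.970 0.010
 0.010 0.010 0.970 0.010
 0.010 0.010 0.970 0.010

MOTIF cMyc
letter-probability matrix: alength= 4 w= 10 nsites= 100 E= 0
 0.010 0.010 0.970 0.010
 0.970 0.010 0.010 0.010
 0.010 0.970 0.010 0.010
 0.010 0.970 0.010 0.010
 0.970 0.010 0.010 0.010
 0.010 0.970 0.010 0.010
 0.010 0.010 0.970 0.010
 0.010 0.010 0.010 0.970
 0.010 0.010 0.970 0.010
 0.010 0.010 0.970 0.010

MOTIF Oct4-Sox2
letter-probability matrix: alength= 4 w= 15 nsites= 100 E= 0
 0.010 0.970 0.010 0.010
 0.970 0.010 0.010 0.010
 0.010 0.010 0.010 0.970
 0.010 0.010 0.010 0.970
 0.010 0.010 0.970 0.010
 0.010 0.010 0.010 0.970
 0.010 0.010 0.010 0.970
 0.970 0.010 0.010 0.010
 0.010 0.010 0.010 0.970
 0.010 0.010 0.970 0.010
 0.010 0.970 0.010 0.010
 0.970 0.010 0.010 0.010
 0.970 0.010 0.010 0.010
 0.970 0.010 0.010 0.010
 0.010 0.010 0.010 0.970
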