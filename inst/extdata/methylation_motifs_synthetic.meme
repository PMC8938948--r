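MEME version 4

ALPHABET= ACGT

strands: + -

Background letter frequencies
A 0.25 C 0.25 G 0.25 T 0.25

MOTIF synthMeth-CGCG-1
letter-probability matrix: alength= 4 w= 8 nsites= 40 E= 1.2e-08
0.050 0.800 0.100 0.050
0.050 0.100 0.800 0.050
0.020 0.900 0.050 0.030
0.020 0.050 0.900 0.030
0.100 0.600 0.200 0.100
0.100 0.200 0.600 0.100
0.250 0.250 0.250 0.250
0.050 0.050 0.100 0.800

MOTIF synthMeth-GATC-2
letter-probability matrix: alength= 4 w= 6 nsites= 25 E= 3.4e-05
0.050 0.050 0.850 0.050
0.850 0.050 0.050 0.050
0.050 0.050 0.050 0.850
0.050 0.850 0.050 0.050
0.150 0.550 0.150 0.150
0.600 0.150 0.100 0.150

MOTIF synthMeth-CCWGG-3
letter-probability matrix: alength= 4 w= 7 nsites= 32 E= 7.7e-06
0.050 0.850 0.050 0.050
0.050 0.850 0.050 0.050
0.450 0.050 0.050 0.450
0.050 0.050 0.850 0.050
0.050 0.050 0.850 0.050
0.200 0.300 0.300 0.200
0.100 0.400 0.400 0.100

MOTIF synthMeth-TCGA-4
letter-probability matrix: alength= 4 w= 8 nsites= 18 E= 2.1e-04
0.050 0.100 0.050 0.800
0.050 0.800 0.100 0.050
0.050 0.050 0.850 0.050
0.800 0.050 0.100 0.050
0.100 0.700 0.100 0.100
0.050 0.100 0.800 0.050
0.700 0.100 0.100 0.100
0.100 0.100 0.100 0.700
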