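# Four-population human model B1: continent-island structure.
# Sampled demes: 1 = ASW (10 lineages), 2 = CEU (18), 3 = YRI (18),
# 4 = LWK (8). Unsampled demes: 5 = European continent, 6 = Niger-Congo
# continent, 7 = ancestral African population.
# The CEU island receives migrants from the European continent, the YRI and
# LWK islands from the Niger-Congo continent; all islands were formed 100
# generations ago (backward: island lineages transfer to their continent).
# The ASW population dissolves 16 generations ago into the European (AE)
# and Niger-Congo continents. The Niger-Congo continent diverges from the
# African population at TNC after a 100-generation bottleneck of size NBNC;
# the European continent diverges 2000 generations ago (fixed calibration)
# after a bottleneck of size NBEUR. The African population size changes to
# the human ancestral size NANC at TBOT. Placeholder search ranges.

[populations]
NASW 0 10
NCEU 0 18
NYRI 0 18
NLWK 0 8
NEUR 0 0
NNC 0 0
NAFR 0 0

[migration]
matrix
0 0 0 0 0 0 0
0 0 0 0 MC 0 0
0 0 0 0 0 MY 0
0 0 0 0 0 ML 0
0 0 0 0 0 0 0
0 0 0 0 0 0 0
0 0 0 0 0 0 0
matrix
0 0 0 0 0 0 0
0 0 0 0 0 0 0
0 0 0 0 0 0 0
0 0 0 0 0 0 0
0 0 0 0 0 0 0
0 0 0 0 0 0 0
0 0 0 0 0 0 0

[events]
16 1 5 AE . . .
16 1 6 1 . . .
100 2 5 1 . . 2
100 3 6 1 . . 2
100 4 6 1 . . 2
TNC 6 7 1 . . .
TBNCEND . 6 . NBNC . .
1900 . 5 . NBEUR . .
2000 5 7 1 . . .
TBOT . 7 . NANC . .

[parameters]
NASW size 100 1000000 log10 free
NCEU size 100 1000000 log10 free
NYRI size 100 1000000 log10 free
NLWK size 100 1000000 log10 free
NEUR size 100 1000000 log10 free
NNC size 1000 1000000 log10 free
NAFR size 100 1000000 log10 free
NBNC size 100 1000000 log10 free
NBEUR size 100 1000000 log10 free
NANC size 100 1000000 log10 free
TNC time 100 10000 log10 free
TBOT time 2000 100000 log10 free
MC rate 0.000001 0.01 log10 free
MY rate 0.000001 0.01 log10 free
ML rate 0.000001 0.01 log10 free
AE proportion 0 1 linear free

[derived]
TBNCEND = TNC - 100
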