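# African continent-island model B for the ascertained SNP panels.
# Demes: 1 = San island (24 lineages), 2 = Yoruba island (88),
# 3 = Denisova (2), 4 = San continent (unsampled), 5 = Yoruba continent
# (unsampled). The sampled islands receive migrants from their continents
# (backward rates MS, MY); the continents exchanged a bidirectional
# admixture pulse at TA and, between TEY and TDS, continuous migration at
# rates MSY and MYS; the Yoruba continent's exponential growth is
# approximated by a size change to NDY at TEY, the San continent's by a
# change to NDS at TDS, when the two merge into an African population of
# size NAFR. Denisova merges 16000 generations ago into the human ancestral
# population of size NANC. Placeholder search ranges; the islands were
# formed 100 generations ago (scattering phase).

[populations]
20000 0 24
20000 0 88
10000 0 2
NCS 0 0
NCY 0 0

[migration]
matrix
0 0 0 MS 0
0 0 0 0 MY
0 0 0 0 0
0 0 0 0 0
0 0 0 0 0
matrix
0 0 0 0 0
0 0 0 0 0
0 0 0 0 0
0 0 0 0 MSY
0 0 0 MYS 0
matrix
0 0 0 0 0
0 0 0 0 0
0 0 0 0 0
0 0 0 0 0
0 0 0 0 0

[events]
100 1 4 1 . . .
100 2 5 1 . . .
TA 4 5 AYS . . .
TA 5 4 ASY . . .
TEY . 5 . NDY . 2
TDS 5 4 1 NAFR . 3
TDSB . 4 . NDS . .
16000 3 4 1 NANC . .

[parameters]
NCS size 1000 1000000 log10 free
NCY size 1000 1000000 log10 free
NDS size 100 100000 log10 free
NDY size 50 100000 log10 free
NAFR size 1000 1000000 log10 free
NANC size 1000 100000 log10 free
MS rate 0.0000001 0.01 log10 free
MY rate 0.0000001 0.01 log10 free
MSY rate 0.0000001 0.01 log10 free
MYS rate 0.0000001 0.01 log10 free
TA time 10 2000 log10 free
TEY time 100 5000 log10 free
TDS time 1000 15000 log10 free
AYS proportion 0 0.5 linear free
ASY proportion 0 0.5 linear free

[derived]
TDSB = TDS - 1
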