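# Two continent-island systems, ten sampled islands (demes 1-10, 4 lineages
# each, 500 diploids each) and two unsampled continents (demes 11 and 12).
# Islands 1-5 receive migrants from continent 11, islands 6-10 from
# continent 12, which itself stems from island 5 at TCI2; the older system
# coalesces into a single ancestral population of size NANC at TCI1.
# Backward in time, island lineages are transferred to their continent when
# the system is created. Immigration-rate truths are placeholders spanning
# two orders of magnitude.

[populations]
500 0 4
500 0 4
500 0 4
500 0 4
500 0 4
500 0 4
500 0 4
500 0 4
500 0 4
500 0 4
10000 0 0
10000 0 0

[migration]
matrix
0 0 0 0 0 0 0 0 0 0 M1 0
0 0 0 0 0 0 0 0 0 0 M2 0
0 0 0 0 0 0 0 0 0 0 M3 0
0 0 0 0 0 0 0 0 0 0 M4 0
0 0 0 0 0 0 0 0 0 0 M5 0
0 0 0 0 0 0 0 0 0 0 0 M6
0 0 0 0 0 0 0 0 0 0 0 M7
0 0 0 0 0 0 0 0 0 0 0 M8
0 0 0 0 0 0 0 0 0 0 0 M9
0 0 0 0 0 0 0 0 0 0 0 M10
0 0 0 0 0 0 0 0 0 0 0 0
0 0 0 0 0 0 0 0 0 0 0 0

[events]
TCI2 6 12 1 . . .
TCI2 7 12 1 . . .
TCI2 8 12 1 . . .
TCI2 9 12 1 . . .
TCI2 10 12 1 . . .
TCI2 12 5 1 . . .
TCI1 1 11 1 . . .
TCI1 2 11 1 . . .
TCI1 3 11 1 . . .
TCI1 4 11 1 . . .
TCI1 5 11 1 . . .
TCI1 11 1 1 NANC . .

[parameters]
M1 rate 0.000001 0.01 log10 free
M2 rate 0.000001 0.01 log10 free
M3 rate 0.000001 0.01 log10 free
M4 rate 0.000001 0.01 log10 free
M5 rate 0.000001 0.01 log10 free
M6 rate 0.000001 0.01 log10 free
M7 rate 0.000001 0.01 log10 free
M8 rate 0.000001 0.01 log10 free
M9 rate 0.000001 0.01 log10 free
M10 rate 0.000001 0.01 log10 free
TCI1 time 100 100000 log10 free
TCI2 time 10 10000 log10 free
NANC size 100 1000000 log10 free
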