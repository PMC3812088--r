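# Isolation-with-migration: two populations diverging at TDIV while
# exchanging migrants at (backward) rates M12 and M21. Default truths for
# this package's benchmarks (placeholders, user-editable): N1 = 10000,
# N2 = 5000, NANC = 10000, TDIV = 2000, M12 = 1e-4, M21 = 5e-5.

[populations]
N1 0 20
N2 0 30

[migration]
matrix
0 M12
M21 0

[events]
TDIV 2 1 1 NANC . .

[parameters]
N1 size 100 1000000 log10 free
N2 size 100 1000000 log10 free
NANC size 100 1000000 log10 free
TDIV time 10 100000 log10 free
M12 rate 0.000001 0.01 log10 free
M21 rate 0.000001 0.01 log10 free
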