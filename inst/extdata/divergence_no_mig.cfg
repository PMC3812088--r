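# Two-population divergence without migration (benchmark model).
# Deme 1 (n1 = 20, diploid size N1 = 5000) and deme 2 (n2 = 30, N2 = 500)
# split from an ancestral population of size NANC = 5000 diploids at TDIV
# generations (benchmark values 10 / 1000 / 100000, i.e. 0.001, 0.1 and 10
# in units of twice the ancestral size).

[populations]
N1 0 20
N2 0 30

[events]
TDIV 2 1 1 NANC . .

[parameters]
N1 size 50 500000 log10 free
N2 size 5 50000 log10 free
NANC size 50 500000 log10 free
TDIV time 10 100000 log10 free
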