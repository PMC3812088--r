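# African divergence model A, fitted to SNP panels ascertained in one
# individual (use --asc-pop 1 or 2 and -0; the Denisova divergence at
# 16000 generations calibrates the time scale).
# Demes: 1 = San (24 lineages), 2 = Yoruba (88), 3 = Denisova (2).
# Backward: the San and Yoruba populations shrink to their ancestral sizes
# NAS and NAY at their recent expansion times TES and TEY; a single pulse of
# bidirectional admixture connects them at TA (AYS = Yoruba-into-San
# fraction, ASY = San-into-Yoruba); they merge at TDIV into an African
# population of size NAFR; Denisova merges 16000 generations ago, after
# which the size is the human ancestral NANC. Search ranges placeholders.

[populations]
NSAN 0 24
NYRI 0 88
10000 0 2

[events]
TES . 1 . NAS . .
TEY . 2 . NAY . .
TA 1 2 AYS . . .
TA 2 1 ASY . . .
TDIV 2 1 1 NAFR . .
16000 3 1 1 NANC . .

[parameters]
NSAN size 1000 1000000 log10 free
NYRI size 1000 1000000 log10 free
NAS size 100 100000 log10 free
NAY size 100 100000 log10 free
NAFR size 1000 1000000 log10 free
NANC size 1000 100000 log10 free
TES time 10 2000 log10 free
TEY time 10 2000 log10 free
TA time 10 5000 log10 free
TDIV time 500 15000 log10 free
AYS proportion 0 0.5 linear free
ASY proportion 0 0.5 linear free
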