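# Four-population human model A: simple admixture scenario.
# Demes: 1 = ASW (African American, 10 lineages), 2 = CEU (18),
# 3 = YRI (18), 4 = LWK (8).
# Backward in time: the ASW population dissolves 16 generations ago into its
# three sources (a European fraction AE, a small Luhya fraction AL, the
# remainder Yoruba); the two Niger-Congo populations merge at TNC into an
# African population of size NAFR; the European branch merges into it 2000
# generations ago (a fixed calibration); an ancestral bottleneck of size
# NBOT lasts 100 generations from TBOT, after which the size is NANC.
# Search ranges are placeholders spanning four orders of magnitude.

[populations]
NASW 0 10
NCEU 0 18
NYRI 0 18
NLWK 0 8

[events]
# ASW sources applied sequentially: AE to CEU, then ALR of the remainder to
# LWK, then everything left to YRI
16 1 2 AE . . .
16 1 4 ALR . . .
16 1 3 1 . . .
TNC 4 3 1 NAFR . .
2000 2 3 1 . . .
TBOT . 3 . NBOT . .
TENDBOT . 3 . NANC . .

[parameters]
NASW size 100 1000000 log10 free
NCEU size 100 1000000 log10 free
NYRI size 100 1000000 log10 free
NLWK size 100 1000000 log10 free
NAFR size 100 1000000 log10 free
NBOT size 100 1000000 log10 free
NANC size 100 1000000 log10 free
TNC time 16 2000 log10 free
TBOT time 2000 100000 log10 free
AE proportion 0 1 linear free
ALR proportion 0 1 linear free

[derived]
TENDBOT = TBOT + 100
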