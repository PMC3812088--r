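# Two-population divergence observed through an ascertained SNP panel:
# SNPs are sites heterozygous in one individual of deme 1, so fits of this
# model use the ascertainment scheme (--asc-pop 1) and drop the
# monomorphic-site terms (-0). Placeholder truths: N1 = 20000, N2 = 8000,
# TDIV = 3000; the ancestral size is fixed to calibrate the scale.

[populations]
N1 0 20
N2 0 20

[events]
TDIV 2 1 1 10000 . .

[parameters]
N1 size 100 1000000 log10 free
N2 size 100 1000000 log10 free
TDIV time 10 100000 log10 free
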