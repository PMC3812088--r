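# Single-population bottleneck benchmark model.
# One deme of 20 sampled lineages; current size N_CUR, reduced to N_BOT
# between T_BOT and T_BOT + 100 generations, ancestral size fixed at 10000
# diploids. True benchmark values: N_CUR = 10000, N_BOT = 100, T_BOT = 1000.

[populations]
# size growth sample_size
NCUR 0 20

[events]
# time source sink proportion new_size new_growth matrix_id
TBOT . 1 . NBOT . .
TEND . 1 . 10000 . .

[parameters]
NCUR size 100 1000000 log10 free
NBOT size 1 10000 log10 free
TBOT time 10 100000 log10 free

[derived]
TEND = TBOT + 100
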