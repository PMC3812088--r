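# Three-population divergence with exponential growth and migration,
# patterned after a simple model of human differentiation: deme 1 is a
# constant-size African-like population; demes 2 and 3 split from it at T1,
# then from each other at T2, each growing exponentially from a founding
# size to a current size of one million diploids while exchanging migrants.
# Growth rates are derived from the founding sizes and times.
# Placeholder truths: N1 = 10000, N2BOT = 2000, N3BOT = 1000, T1 = 3000,
# T2 = 1000, M = 1e-4.
#
# The growth rate needed (log(N_CUR/N_BOT)/T2) is not expressible with the
# derived-parameter operators, so this config fixes representative rates;
# the scenario_preset() version derives them exactly.

[populations]
N1 0 20
1000000 0.0062 20
1000000 0.0069 20

[migration]
matrix
0 0 0
0 0 M
0 M 0
matrix
0 0 0
0 0 0
0 0 0

[events]
T2 3 2 1 N2BOT 0 2
T1 2 1 1 . . .

[parameters]
N1 size 100 1000000 log10 free
N2BOT size 10 100000 log10 free
T1 time 100 100000 log10 free
T2 time 10 10000 log10 free
M rate 0.000001 0.01 log10 free
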