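# sfscoal

Simulation-based composite-likelihood inference of demographic history from
the site frequency spectrum (SFS).

Given the observed spectrum of derived-allele counts in one or more
populations — 1-D, joint 2-D, or multidimensional — `sfscoal` estimates the
parameters of an arbitrary user-defined demographic model: effective
population sizes, divergence and event times, migration rates, exponential
growth rates and admixture proportions. It is aimed at population
geneticists working with genome-wide SNP data, including SNP panels with a
known single-heterozygote ascertainment scheme, for which the ascertainment
bias is modelled rather than corrected away.

## Method

The probability that a polymorphic site falls in SFS entry *i* equals the
expected fraction of coalescent tree length carried by branches subtending
*i* sampled lineages. `sfscoal` estimates it from *Z* simulated
genealogies,

    p_i = ( sum_k sum_{j in Omega_i} t_ij^(k) ) / ( sum_k T^(k) ),

where `T^(k)` is the total length of the *k*-th simulated tree and
`Omega_i` its branches compatible with entry *i* — a ratio of sums that
implicitly weights each simulation by its mutational opportunity. The
composite log-likelihood of an observed spectrum `X` with `S` SNPs in `L`
surveyed sites is

    log CL = (L - S) log p0 + S log(1 - p0) + sum_i X_i log p_i,

with `p0 = mean_k exp(-mu T^(k))` the Poisson zero class (monomorphic
probability); dropping the `p0` terms (`use_monomorphic = FALSE`, flag
`-0`) gives the pure multinomial form used for ascertained SNP panels. The
likelihood is maximized by multi-start ECM cycles — each parameter
maximized in turn by Brent's method on its search scale — and uncertainty
comes from a parametric bootstrap. AIC/Akaike weights compare models; a
bootstrapped likelihood-ratio G statistic tests absolute fit. For panels
ascertained as "heterozygous in one individual", expectation and
pseudo-data are restricted to the subtree joining two random lineages of
the ascertained population to their MRCA.

## Worked example

Fit a single-population bottleneck model (current size `N_CUR`, bottleneck
size `N_BOT` from `T_BOT` for 100 generations, ancestral size fixed) to
simulated data of 40,000 unlinked 50-bp loci:

```r
library(sfscoal)
set.seed(1)

pre <- scenario_preset("bottleneck")   # truths: N_CUR 10000, N_BOT 100, T_BOT 1000
obs <- simulate_sfs(pre, num_loci = 40000)
obs
#> Observed SFS: dims (20), S = 4,019 SNPs, L = 2e+06 bp

fit <- sfs_fit(obs, pre$space, mu = pre$mu,
               config = ecm_config(cycles = 10, runs = 5,
                                   z_start = 5000, z_end = 20000),
               seed = 1)
coef(fit)
#>      N_CUR      N_BOT      T_BOT
#> 8457.54500   92.57592 1186.88156
```

The estimates land within about 15% of the simulated truth for the two
sizes and about 19% for the bottleneck age on this dataset; the spread
across independent replicates reflects both data randomness and the
Monte-Carlo noise of the simulated likelihood (the fit's `$runs` field
keeps every start's trajectory), and it tightens as the data size, `z_end`
and the number of starts grow toward the full-scale settings. Confidence intervals, model comparison and fit testing follow
as `confint(fit, B = 100)`, `compare_models(fit_a = ..., fit_b = ...)` and
`gof_test(fit, B = 100)`.

A command-line interface wraps the same machinery:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts","sfscoal.R",package="sfscoal"))')" \
  estimate --config model.cfg --obs data.obs -n 50000 -N 250000 -L 30 --runs 20 \
  --seed 7 --out run1
```

Model configuration files (populations, migration matrices, events, free
parameters with search ranges, derived parameters) are documented in
`?read_model_config`; eleven example configs, from the simple bottleneck to
multi-continent human and African models, ship in `inst/extdata/`.

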