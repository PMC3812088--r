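---
title: "Composite-likelihood demographic inference from the site frequency spectrum"
author: "sfscoal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Composite-likelihood demographic inference from the site frequency spectrum}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sfscoal)
```

## The model and the estimator

`sfscoal` estimates the parameters of multi-population demographic models —
effective sizes, divergence and event times, migration rates, growth rates,
admixture proportions — from the observed (joint) site frequency spectrum
(SFS). For unlinked, neutrally evolving sites, the probability that a
polymorphic site shows the derived allele in $i$ copies is a ratio of
coalescent branch lengths: writing $T$ for the total length of the sample's
genealogy and $\Omega_i$ for the set of branches subtending exactly $i$
sampled lineages (per deme, for a joint spectrum), the entry probability is
$E[\sum_{b \in \Omega_i} t_b] / E[T]$. No closed form exists for arbitrary
demographies, so the package estimates it by Monte Carlo: $Z$ genealogies
are simulated under the structured coalescent and

$$\hat p_i \;=\; \frac{\sum_{k=1}^{Z} \sum_{j \in \Omega_i} t_{ij}^{(k)}}
                      {\sum_{k=1}^{Z} T^{(k)}},$$

with numerator and denominator accumulated over the *same* genealogies.
Dividing sums rather than averaging per-tree ratios implicitly weights each
simulation by the probability that a mutation occurs on its tree; an
unweighted average would over-weight shallow genealogies, which matters for
recently bottlenecked populations.

The composite log-likelihood of an observed spectrum $X$ with $S$
polymorphic sites in $L$ surveyed base pairs combines a binomial term for
the monomorphic/polymorphic split with a multinomial term over polymorphic
classes,

$$\log CL \;=\; (L - S)\log \hat p_0 + S \log(1 - \hat p_0)
             + \sum_i X_i \log \hat p_i ,$$

where $\hat p_0 = \frac1Z \sum_k e^{-\mu T^{(k)}}$ is the Monte-Carlo mean
of the Poisson zero class — the probability that a site carries no mutation
— evaluated per site ($\mu$ is the per-site per-generation mutation rate).
Averaging $e^{-\mu T}$ over trees rather than plugging in the mean tree
length keeps the zero class unbiased under tree-length variation. The
monomorphic terms tie the parameters to an absolute (mutation-clock) scale;
without them the likelihood is exactly a multinomial over SFS classes, and
parameters are identified only relative to a fixed reference (a known size
or divergence time). Treating sites as independent makes this a composite
likelihood; for data such as SNPs sampled far apart the approximation is
close to a true likelihood.

For models with many populations the dense joint spectrum becomes
unmanageable, and the package instead maximizes the sum of the composite
log-likelihoods of all pairwise 2-D marginal spectra (`pairwise = TRUE`),
always without monomorphic terms (each pair would count them repeatedly).
Rarely observed entries can be pooled below a count threshold `epsilon`
(`collapse_entries()`), stabilizing entries whose expectations are hard to
estimate; classes observed but estimated at probability zero are floored at
`floor` (default $10^{-12}$, applied after normalization and only inside
the likelihood).

## The coalescent engine

Genealogies are simulated backward in time under demographies built from
per-deme diploid sizes (pairwise coalescence rate $1/2N$), forward
exponential growth rates (backward size $N(t) = N(0)e^{-rt}$), a
backward-convention migration matrix (`m[from, to]` per lineage per
generation), and a time-ordered list of events that move lineages
(divergences and admixture pulses), reset sizes or growth, or switch
migration matrices. Waiting times under growth are drawn by the exact
inversion of the integrated hazard ($s = \log(1 + bE/a)/b$ for hazard
$ae^{bs}$), so there is no discretization error and no step-size knob.
Simultaneous events are processed in declaration order — the documented
tie-break, which matters for scattering-phase constructions where islands
must empty into a continent before the continent itself merges. Validation
(`validate_demography()`) checks bounds and a reachability condition for
"closability" (all sampled demes can reach a common deme); the simulator
additionally guards at run time with a hard time cap.

## Ascertainment

SNP panels discovered as "sites heterozygous in one individual of
population $k$" are handled by modelling the bias rather than correcting
the data: two lineages of the ascertained deme are drawn at random in every
simulated genealogy, and only the subtree joining them to their most recent
common ancestor can carry observable mutations. The expected ascertained
spectrum therefore restricts both the compatible branch sets and the
denominator of $\hat p_i$ to that subtree while descent vectors still count
the full sample. Internally a branch lies on the subtree exactly when one
of the two chosen lineages descends through it, which is how both the
estimator and the independent pseudo-data check implement it (the
pseudo-data generator filters true mutation placements, not subtrees, so
the two paths cross-validate each other). For a stationary population the
ascertained class probabilities are proportional to $n - i$ — depleted in
singletons relative to the neutral $1/i$ spectrum — a closed form the test
suite checks. Fits to ascertained panels drop the monomorphic terms (only
polymorphic sites are reported), so one parameter must be fixed to
calibrate the scale.

## Optimization

The likelihood surface is estimated with Monte-Carlo noise, so
derivative-based optimizers are unsuitable. The package uses
expectation/conditional-maximization (ECM) cycles: each free parameter is
maximized in turn by Brent's method (golden section plus parabolic
interpolation, via `stats::optimize()`) over its full search range, holding
the others fixed; every objective evaluation re-estimates the expected
spectrum from a fresh batch of simulations (no common random numbers — two
evaluations at identical parameters differ by noise, and estimates from
identical starts can differ, which is inherent to the approach). Sizes,
times and rates are searched on a log10 scale because realistic search
ranges span several orders of magnitude; proportions are searched linearly.
The simulation count ramps linearly from `z_start` to `z_end` across
cycles, spending little on early cycles that only need the coarse shape of
the surface. A run stops when no parameter moved by more than `stop_tol`
(default 0.5%) over a full cycle or at the cycle cap; with a noisy
objective the cap usually binds. When a run completes, every visited
cycle's parameter vector is re-scored once at `z_end` and the best
re-scored vector becomes the run's estimate. This selection step exists
because a bounded one-dimensional search on a noisy objective can,
rarely but catastrophically, discard the half-interval containing the
optimum on the strength of a single unlucky comparison (the monomorphic
term amplifies the Monte-Carlo error of the zero-class probability far
from the optimum, so the noise is largest exactly where such mistakes are
made); a derailed late cycle then scores hundreds of log-units below the
good cycles and is reliably screened out. Because the surface can be
multi-modal and the noise can strand single runs, `sfs_fit()` launches
`runs` independent starts drawn log-uniformly (or uniformly, for
proportions) over the search ranges, each on its own deterministic
sub-stream of the master seed, and retains the highest re-scored solution,
ties to the earliest run.

Tunables that matter, with defaults: `cycles` (20), `runs` (20), `z_start`
(50,000) and `z_end` (250,000) — the per-evaluation simulation counts
trade likelihood noise against time linearly; `brent_tol` (0.01 on the
search scale, i.e. about 2% for log10 parameters) and `brent_maxiter` (20,
enforced by flooring the effective tolerance at the golden-section bound);
`stop_tol` (0.005). Benchmarks in this package's tests scale these down —
typically 40,000 loci of 50 bp, $Z$ = 20,000, 10–15 cycles, 5–10 starts —
sizes chosen to keep a complete run in minutes on one core while retaining
the recovery signal; the corresponding full-scale settings (400,000 loci,
$Z$ = 100,000 or a 50,000→250,000 ramp, 20–40 cycles, 20–50 starts) are
plain arguments.

## Uncertainty, model choice, goodness of fit

Confidence intervals come from a parametric bootstrap: replicate spectra
are simulated at the estimates, each is re-fitted with a reduced number of
starts (default 10), and percentile intervals are taken over the replicate
estimates. Replicates are drawn multinomially from the fitted expected
spectrum (the fast path; an exact per-locus path exists and the test suite
checks their agreement). With the monomorphic terms in the likelihood the
replicate SNP count is drawn $\mathrm{Binomial}(L, 1-\hat p_0)$ so the
binomial part of the likelihood is resampled too; in SNP-panel mode the
count is fixed at the observed $S$, matching how such panels are produced.

Models are compared by AIC, $2d - 2\log CL$, and Akaike weights. Because a
single likelihood evaluation is noisy, the value entering the comparison is
the maximum over `rescore` (default 100) re-evaluations at the fitted
parameters — a noise-robust summary whose residual error is small against
the AIC differences that matter. Composite-likelihood AIC can overstate
support for the winning model when sites are linked; for spectra built from
well-spaced SNPs the approximation is reasonable. No effective-parameter
correction is applied.

Absolute fit is assessed by a likelihood-ratio G statistic,
$G = 2(\log CL_{\mathrm{sat}} - \log CL_{\mathrm{model}})$, where the
saturated likelihood replaces expected probabilities by relative observed
frequencies (and $p_0$ by $(L-S)/L$). Its null distribution is unknown for
composite likelihoods, so it is obtained by the same parametric bootstrap:
simulate at the estimates, re-fit, recompute $G$; the p-value is the
fraction of null values at least as large as the observed one. The factor 2
is the conventional G-statistic scaling; since the null distribution is
bootstrapped, any fixed constant would give identical p-values. One
implementation point matters for calibration: the model likelihood inside
$G$ is computed with the *same* protocol (the maximum over `rescore`
re-evaluations at a common simulation count) for the observed data and for
every bootstrap replicate, so that the Monte-Carlo noise of the likelihood
enters the observed statistic and its null distribution identically.

## The pseudo-data generator

`simulate_sfs()` emulates a study design of many short, unlinked,
non-recombining loci (default 400,000 regions of 50 bp at
$\mu = 2.5\times10^{-8}$, i.e. 20 Mb): each locus gets an independent
genealogy and $\mathrm{Poisson}(\mu L T)$ infinite-sites mutations placed
uniformly along branches. It captures genealogical and mutational
randomness exactly under the model; it does *not* emulate recombination
within loci, linkage between nearby sites, sequencing or polarization
error, or missing data — so passing recovery tests demonstrates
correctness of the inference machinery under the model's own assumptions,
not robustness to the artefacts of real data. Benchmark truths for the
bottleneck (current size 10,000 diploids, bottleneck size 100 at 1,000
generations for 100 generations, ancestral size 10,000) and the
two-population divergence (diploid sizes 5,000/500 from an ancestor of
5,000; split at 0.001, 0.1 or 10 times twice the ancestral size) are the
package's reference benchmark settings; the isolation-with-migration,
three-population-growth, hierarchical-island and ascertained-divergence
presets ship plausible defaults, marked user-editable.

## Numerical choices and degenerate inputs

- The two absorbing spectrum entries (all-ancestral, all-derived) are
  masked everywhere; all-derived-within-one-deme entries are retained
  (observable with an outgroup). Expected probabilities are renormalized
  over the retained classes (relevant for pairwise marginals); a flag
  disables renormalization.
- Sizes and times are rounded to whole numbers (at least 1) when a
  parameter vector is bound to a demography, and the likelihood is
  evaluated on the rounded values.
- Derived parameters support `+ - * / min max` only — enough to express
  constructions like "bottleneck end = start + 100" without a full
  expression language; the dependency graph must be acyclic.
- A search interval of zero width is legal and returns its single point. A
  space with no free parameters reduces the fit to one likelihood
  evaluation.
- The zero-probability floor default of $10^{-12}$ is configurable; with
  the floor disabled, an observed class with zero expected probability is
  an error rather than silently $-\infty$.
- Master seeds key deterministic sub-streams per optimization run and per
  bootstrap replicate, so increasing `runs` or `B` never perturbs the
  streams of earlier ones, and any run is reproducible from its logged
  seed.

## Known limitations

Composite-likelihood confidence intervals can be anticonservative when
sites are linked, and are expected to be so when the pairwise-product
objective is used for many-population models. Monte-Carlo noise in the
objective limits how finely parameters along flat likelihood ridges can be
resolved at moderate $Z$ — visibly so for the bottleneck benchmark, where
current size, bottleneck size and age partly compensate; raising `z_end`
tightens this at linear cost. Folded spectra, genotype-likelihood-based
spectra, recombination within loci and serial sampling are out of scope.
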