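---
title: "Estimating riboviral mutation rates from burst and spectrum data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating riboviral mutation rates from burst and spectrum data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qmutate)
```

# The experimental system and what the package computes

qmutate analyses spontaneous mutation in riboviruses from two kinds of
experiment, both built around a codon-framed mutation reporter — for
phage Q-beta, the 591-nt read-through (RT) region spanning genomic
positions 1743–2333, which begins with the leaky UGA stop codon of the
coat gene and is dispensable when complemented in trans:

1. **Forward screens**: isolates from a single infection cycle are
   screened for loss of reporter function, and mutants are sequenced.
   These yield the mutation spectrum and, through the subset of
   mutations whose detectability is unconditional (nonsense mutations
   and frameshifting indels), an absolute mutation rate.
2. **Single-burst reversion tests**: many parallel cultures, each with
   N infected cells, are plated so that revertant counts per culture
   can be read off. The distribution of counts identifies the mode of
   intracellular genome replication and yields reversion rates.

## Replication modes and why they matter

A (+)-strand phage can replicate its genome two ways. Under the
**stamping-machine (linear)** mode the infecting (+) strand is copied
repeatedly into a modest number of (−) templates, each of which is
copied repeatedly into progeny (+) strands; every progeny genome then
experiences exactly `n = 2` replications per infection cycle, and most
replication errors arise in the second round, producing singleton
mutants. Under **exponential** replication progeny serve as templates
and mutants form clones with the heavy-tailed Luria–Delbrück size
distribution. The distinction fixes the denominator (`c*n`) that
converts mutant frequencies into rates per replication, which is why
the package couples the rate estimators to replication-mode
diagnostics.

Three diagnostics are implemented:

- the fit of per-culture revertant counts to a Poisson distribution
  (`burst_fit()`, `poisson_gof()`): linear replication with errors
  confined to the second round makes culture totals Binomial(NB, mu),
  i.e. Poisson to excellent approximation;
- the index of dispersion of per-burst counts (near 1 for linear,
  well above 1 for exponential);
- the log–log slope of the cumulative clone-size distribution
  (`loglog_cumulative_slope()`): near −1 under exponential
  replication, much steeper under linear replication. Classes at or
  above a cap (we use 16, the convention used for the classical T2
  data this diagnostic derives from) are dropped before fitting since
  classes approaching the burst size saturate.

# Rate estimators

All three estimators reduce to closed-form arithmetic on counts; the
value of packaging them is the shared bookkeeping (components stored
with every `rate_estimate`, so each value can be recomputed exactly)
and the shared conversion `mu = f / (c*n)`.

**Nonsense-path method** (`rate_nonsense()`). Most base substitutions
are phenotypically silent or leaky, so the raw substitution count
under-counts. Nonsense mutations are essentially always detectable,
and their target size is computable from the sequence:
`nonsense_paths()` enumerates every (site, mutant base) pair whose
substitution creates a stop codon. Dividing the per-path frequency by
one path per base-and-direction triple gives the per-base rate:
`f_path = k/(isolates * T_paths)`, `f_SUB = 3 f_path`,
`mu_SUB = f_SUB/(c n)`. Indels are essentially always detectable, so
`mu_I` uses the full 591-nt target. The genomic rate is
`mu_g = (mu_SUB + mu_I) G`. The count of nonsense mutations includes
the conversion of the leaky read-through UGA to a tighter stop
(`stop_to_stop` in `mutation_effects()`), which is detectable by the
same criterion; correspondingly `nonsense_paths()` counts the paths
out of that codon by default.

**Hitchhiker method** (`rate_hitchhiker()`). Secondary mutations
sequenced in sub-isolates of driver mutants are recovered without
regard to phenotype, so the whole reporter is the target:
`f_SUB = k/(subisolates * T_nt)`. Its assumptions are weaker but its
exposure differs: hitchhikers can arise during any of the roughly
three infection cycles of plaque growth, and missense hitchhikers are
exposed to selection; both biases are examined with
`missense_deficit_test()` and the plaque-loss model below.

**Reversion (fluctuation) methods** (`burst_fit()`). The null-class
estimator uses only the fraction of zero-revertant cultures:
`m = ln(C/C0)`, `mu = m/(N B)`. The frequency estimator uses all
revertants: `f = total/(N B C)`; under second-round attribution (the
linear-mode default) `mu = f`, under equal attribution to both rounds
`mu = f/2`. Per-target rates are scaled to the genome with
`scale_to_genome()` by the size of the reversion target (3 mutable
bases for a stop-codon substitution target; 4 for a four-base
duplication, though 1 is arguable — both choices are exposed, neither
hard-coded). Standard deviations propagate the burst-size SD alone by
the first-order delta method, matching how the source experiments
report uncertainty (B is the dominant and only replicated uncertainty;
count noise is not folded in).

## Numerical and convention choices

- **Poisson expectations** follow the p0 construction
  `E_k = C e^{-m} m^k / k!` with `m = ln(C/C0)`, so the zero class
  matches the observed zero class exactly. In `poisson_gof()` the tail
  beyond the largest observed class is folded into the top class so
  the expected column sums exactly to C.
- **Goodness of fit** uses the G statistic `2 sum O ln(O/E)` with
  zero-observed classes contributing 0; trailing classes are pooled
  until the tail expectation reaches 1 (configurable); df = classes −
  1 − 1 for the estimated mean. Because the p0 mean is a moment
  estimator rather than ML, the p0-based test is mildly
  anticonservative (its P-values run small under the null); the
  `m_method = "ml"` variant is calibrated, and the package's
  uniformity checks use it. Published P-values computed under
  unstated pooling conventions (e.g. 0.825 for the insertion-mutant
  table) are therefore reproduced only approximately (we obtain 0.76);
  the qualitative verdicts (fit vs strong misfit) are stable across
  conventions.
- **Replicated G-tests** for upstream-context composition partition
  `G_T = G_P + G_H` across the window offsets, after the classical
  Sokal–Rohlf scheme; no Williams correction is applied by default
  since the source analysis states none.
- **Mispair inference** attributes errors to the second replication
  round by default — template = complement of the wild-type (+) base,
  primer = observed mutant base — because the burst analyses place
  most errors there; first-round attribution is available for
  sensitivity analysis.
- **Normalised mutabilities** are class count divided by the target
  count of the wild-type base. Two of the published normalised values
  (0.058 and 0.038) disagree with their own defining ratios (8/130 =
  0.062 and 5/139 = 0.036); the package computes the ratios.
- The **expected missense fraction** for the hitchhiker deficit test
  is a parameter (default 0.75) because the published "approximately
  3.3:1" is imprecise; `expected_missense_fraction()` derives the
  codon-table value from any supplied target.

# The burst simulator

`replication_model()` + `simulate_bursts()` generate synthetic
single-burst experiments with the statistical structure the analysis
assumes, and are the package's test bed: every estimator is validated
by parameter recovery on simulator output.

Default study conditions mirror the two reversion experiments: the
insertion-mutant arm (N = 4560 infected cells per culture, C = 239
cultures, B = 328 ± 93) and the substitution-mutant arm (N = 35,
C = 498, B = 859 ± 165), with reversion rates of order 1.4e-6 and
2.5e-5 per target per replication respectively. Choices a user can
make, with the defaults and their rationale:

- `c1`, the number of (−) templates, defaults to `B/10`, reflecting
  the roughly 10-fold excess of accumulated (+) over (−) strands
  reported for Q-beta. `template_weights` optionally skews the
  multinomial-uniform allocation of progeny to templates.
- `burst_law` defaults to a discretised gamma truncated at 1 with the
  given mean and SD: burst sizes are reported as mean ± SD without a
  distributional form, and the gamma is the standard non-negative
  choice at that level of information.
- `mu1` and `mu2` are independent per-copy error rates for the two
  rounds; nothing in the source data constrains `mu1`, so it defaults
  to 0 and the recovery tests estimate `mu2`.
- `mixed_fraction` recruits each newly synthesised (+) strand as an
  additional template with probability ε, interpolating continuously
  from linear (ε = 0, exact reduction) toward exponential behaviour.
- `f_pre` seeds whole-burst revertant cultures from preexisting
  mutants, emulating the large bursts that real experiments exclude;
  `burst_dataset(exclude_ge =)` implements the exclusion rule (a
  count of B/3 in one culture is a reasonable default cutoff, since a
  single second-round event cannot approach the burst size).

What the simulator does **not** emulate: plating and sampling losses
beyond a scalar plating-efficiency multiplier, replicase kinetics and
encapsidation, co-infection, and back mutation (mutants breed true).
Passing recovery tests therefore show the estimators are correct for
the sampling structure they assume, not that real data meet that
structure; the GOF and dispersion diagnostics are what carry that
burden on real data.

Problem sizes used in the packaged checks — 100 simulation replicates
per recovery check, 300 datasets for the P-value uniformity check,
1000 cultures for the dispersion and slope checks, 10^4–2×10^4
lineages for the branching-process comparisons — were chosen so each
Monte-Carlo standard error is several times smaller than the tolerance
it guards.

# Mutant loss during plaque growth

`loss_probability()` implements a Galton–Watson extinction
calculation: a mutant arising in the first cycle of plaque growth
starts one lineage with offspring mean `R(1 − s)` per cycle and the
probability it is extinct after g cycles is the g-fold iterate of the
offspring PGF at 0. Poisson and geometric offspring laws are provided;
the law and effective R behind the published loss figures (≥42% at
s ≥ 0.5, ≥40% at s ≥ 0.65) are not specified there, so those numbers
are treated as exploratory, not asserted — the package's claims are
the structural ones (agreement with direct branching simulation,
monotonicity in s and g, convergence to the classical fixed point).

# The synthetic reporter sequence

The actual RT reporter sequence is published only as a figure, which
this package cannot transcribe. The packaged sequence
(`rt_target()`, generated deterministically by
`synthetic_rt_target()`) is therefore a clearly-labelled **synthetic
stand-in** constructed to satisfy every published constraint on the
real sequence: length and codon framing, terminal codons (leaky UGA
start, UAG stop, no internal stops), the exact base composition
(U 175 > G 147 > C 139 > A 130), exactly 66 single-base paths to stop
codons, the wild-type base and amino-acid impact at all 45 catalogued
mutation sites, homopolymeric U runs at both insertion sites, and the
UUAA duplication motif with its published flanks. Free codons are
arbitrary. Consequently every sequence-level computation is exercised
against realistic structure, and catalogue-level results (spectrum
class counts, transition:transversion ratio 9.75, coding effects) are
exact; but analyses sensitive to the uncatalogued sequence between
mutation sites — notably the upstream G/C context test — run
structurally without reproducing the published G values. The
construction (constraint solving per codon, composition-exact fill,
greedy in-codon permutation search for the stop-path count) is run and
verified in the test suite on every build.

# Known limitations

- The null-class and frequency estimators assume errors accrue in the
  second replication round; first-round (clonal) contributions bias
  both upward, by different amounts — their divergence is itself the
  diagnostic.
- `m = ln(C/C0)` is undefined when no culture is null; the package
  directs the user to the frequency method rather than extrapolating.
- The p0-based G-test is anticonservative (see above); use
  `m_method = "ml"` when calibrated P-values matter.
- The log–log slope diagnostic needs at least two populated clone-size
  classes and is sensitive to the class cap near the burst size.
- The hitchhiker rate inherits any transient hypermutation of driver
  lineages; the 7-fold excess of the hitchhiker over the nonsense-path
  rate in the packaged data is reported, not resolved, by the package.
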