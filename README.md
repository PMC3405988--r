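# qmutate

Spontaneous mutation analysis for riboviruses (RNA viruses with no DNA
replication intermediate), built around the phage Q-beta read-through
(RT) reporter system: a 591-nt codon-framed mutation target screened
for loss-of-function mutants, plus single-burst reversion tests read
out as revertants per plated culture.

Riboviral mutation rates are hard to measure because most base
substitutions are phenotypically silent, selection distorts mutant
frequencies, and the rate per infection cycle depends on *how* the
genome is replicated inside the cell. qmutate packages the three
standard routes around these problems, for anyone analysing
plaque-screen or fluctuation-test data from a phage or other virus
with a codon-framed reporter:

- **Nonsense-path method** — sizes the detectable substitution target
  by the number of single-base paths to a stop codon, `T`, computed
  from the sequence by `nonsense_paths()`. With `k` nonsense mutants
  among `n` screened isolates, `f_path = k/(nT)`, `f_SUB = 3 f_path`,
  `mu_SUB = f_SUB/(c n_rep)` with `c` infection cycles of `n_rep`
  replications; indels use the full target; the genomic rate is
  `mu_g = (mu_SUB + mu_I) G`.
- **Hitchhiker method** — phenotype-blind secondary mutations in
  sequenced sub-isolates, with the whole reporter as target.
- **Fluctuation (reversion) methods** — the Luria–Delbrück null-class
  estimator `m = ln(C/C0)`, `mu = m/(NB)`, and the frequency estimator
  `mu = total/(NBC)`, with Poisson class expectations, G-tests of
  goodness of fit, and a log–log clone-size slope that discriminates
  stamping-machine (linear) from exponential genome replication.

Around these sit a mutation-spectrum layer (transition/transversion
classification, template–primer mispair inference, replicated G-tests
of upstream G/C context), a stochastic burst simulator (linear,
exponential, and mixed replication; the test bed for every estimator),
and a Galton–Watson model of mutant lineage loss during plaque growth.

## Worked example

The packaged fixtures are the RT mutation catalogue (45 mutations from
7517 screened isolates), the two single-burst reversion tables, and a
synthetic stand-in for the RT sequence (the real sequence is published
only as a figure; the stand-in reproduces its published length,
composition, stop-path count, and all 45 mutation sites — see
`?synthetic_rt_target`).

```r
library(qmutate)

nonsense_paths(rt_target())
#> [1] 66

# forward-mutation rate from 3 nonsense + 2 indel mutations
est <- rate_nonsense(3, 2, 7517, paths = 66, target_nt = 591,
                     genome_nt = 4217)
est$mu_genomic
#> <rate_estimate: nonsense_path:mu_genomic> 0.0392
#>   components: n_nonsense = 3, n_indel = 2, isolates_screened = 7517,
#>   paths = 66, target_nt = 591, c = 1, n = 2, G = 4217
```

About 0.04 mutations per genome per replication: each progeny genome
carries a new mutation with probability ~4% per replication round.

```r
fit <- burst_fit(read_burst_table(
  system.file("extdata", "rt_in_bursts.tsv", package = "qmutate"),
  N = 4560, B_mean = 328, B_sd = 93))
fit
#> Single-burst fluctuation fit (null-class / p0 method)
#>   cultures C = 239, null class C0 = 31, m = 2.042 events/culture
#>   mu (null-class)  = 1.366e-06 +/- 3.9e-07 per target per replication
#>   mu (frequency)   = 1.427e-06 +/- 4e-07
#>   Poisson GOF: G = 3.16, df = 6, P = 0.789
```

The revertant counts fit a Poisson closely (P = 0.79) and the two
estimators agree within 5% — both signatures of stamping-machine
replication with errors confined to the second replication round.

```r
spectrum_summary(rt_mutation_catalog(), rt_target())
#> <spectrum_summary> 45 mutations: 43 substitutions (39 ts / 4 tv, ratio 9.75), 2 indels
#>   observed classes (template.primer mispair, second round):
#>     G>A   10  C.A  (0.068 per wt base)
#>     U>C   16  A.C  (0.091 per wt base)
#>     A>G    8  U.G  (0.062 per wt base)
#>     U>G    1  A.G  (0.006 per wt base)
#>     A>U    1  U.U  (0.008 per wt base)
#>     C>U    5  G.U  (0.036 per wt base)
#>     G>U    2  C.U  (0.014 per wt base)
#>   effects: missense:31 synonymous:9 nonsense:2 stop_to_stop:1 frameshift:2
```

A 9.75:1 transition:transversion ratio against a random expectation of
0.5, led by U→C — under second-round attribution, an A•C
template–primer mispair.

Simulators close the loop: `simulate_bursts(replication_model(...))`
generates synthetic experiments on which the estimators are verified
to recover their inputs (see the test suite), and
`loss_probability(plaque_growth_model(s, R, cycles))` quantifies how
much selection during plaque growth hides mutants from a screen.

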