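# dcjmoments

Moment estimators of the number of genome rearrangements separating two
genomes under the Double Cut-and-Join (DCJ) model.

Comparative genomics routinely needs evolutionary *distances* between gene
orders — for dating, for building phylogenies, for calibrating rearrangement
rates. The combinatorial (parsimony) DCJ distance is easy to compute but
counts only the *minimum* number of events, and real histories stop being
parsimonious early: once events reuse breakpoint regions, parsimony falls
below the truth. This package is for people who want the *estimated actual*
number of events `k`, obtained by the method of moments: compute the exact
expectation of an observable statistic under `k` random DCJs, then invert it
at the observed value.

## The model and the estimators

A genome with `g` genes is a matching on the `2g` gene extremities; `a`
adjacencies join consecutive genes, the rest of the extremities are
telomeres. Augmented with one telomeric vertex per telomere and `f`
fictional vertices matched pairwise, the genome becomes a perfect matching
with `n = 2g − a + f/2` adjacencies, on which exactly `n(n−1)` DCJ moves
(cut two adjacencies, rejoin the four ends the other way) are equiprobable.

The workhorse is the exact closed-form breakpoint expectation

```
E(B_k) = a (2n−2)/(2n−1) (1 − (1 − 1/(n−1) − 1/n)^k)
```

which inverts analytically (`dcj_tilde()`). Alongside it the package
implements the classical companion estimators, each importing a
better-studied process:

| estimator | statistic | inverted expectation |
|---|---|---|
| `dcj_tilde()` | breakpoints | closed form above (analytic inverse) |
| `seq_coding_estimate()` | breakpoints | binary-sequence substitution model, sites changing four at a time, matched length `N = 4a(2n−2)/(2n−1) ≈ 4a` |
| `estimate_eh()` | breakpoint-graph cycles | expected cycles of the random transposition walk (exact alternating series, arbitrary-precision evaluation) |
| `estimate_bd()` | breakpoint-graph cycles | expected components of a random multigraph (tree-count series) |
| `parsimony_distance()` | graph cycles | none — the minimum distance `n − cycles`, as a baseline |

Supporting machinery: genome construction and UniMoG/GRIMM-style file I/O,
observed and real breakpoint graphs with cycle statistics, a seedable DCJ
Markov-chain simulator with coupled transposition-walk and random-graph
processes, exact brute-force oracles (partition chains and full matching
chains in big-integer arithmetic) that every formula is tested against, and
scripted simulation experiments. See the methods vignette
(`vignettes/dcj-distance-estimation.Rmd`) for the science and the numerical
choices.

## Worked example

The classic three-gene pair — one linear chromosome read `g1 g2 g3` in the
red genome and `g3 g2 g1` in the blue one:

```r
library(dcjmoments)
red  <- build_genome(c(1, 2, 3), name = "red")
blue <- build_genome(c(3, 2, 1), name = "blue")

count_breakpoints(red, blue)
#> [1] 2
observed_breakpoint_graph(red, blue)
#> <dcj_bp_graph: observed> n = 4, cycles = 2, DCJ distance = 2
#>   cycle lengths: 2 x2
real_breakpoint_graph(augment_genome(red), augment_genome(blue))
#> <dcj_bp_graph: real> n = 4, cycles = 1, DCJ distance = 3
```

Red has two adjacencies absent from blue (two breakpoints). The observed
breakpoint graph — which closes the union of observed adjacencies so as to
maximize cycles — has 2 cycles on `n = 4` adjacencies, so two DCJs suffice
(the parsimony distance). Under the identity correspondence of telomeric
vertices the real graph is a single cycle: a history respecting *that*
telomere pairing needs three DCJs. The gap is exactly what observable data
cannot decide.

At realistic scale, estimation inverts the expectation curve:

```r
g0 <- random_genome(g = 1000, telomeres = 40, seed = 1)  # a = 980, n = 1020
tr <- simulate_dcj(g0, k_max = 500, seed = 2, record = "breakpoints")
tail(tr, 1)
#>       k breakpoints
#> 1   500         614
dcj_tilde(tr$breakpoints[501], a = 980, n = 1020)
#> <dcj_estimate: dcj_tilde> observed breakpoints = 614, k_hat = 501.989
```

After 500 random DCJs the genome shows 614 breakpoints (not 1000 — regions
get hit repeatedly), and inverting the expectation recovers an estimate of
502 events. At this depth (`k ≈ n/2`) the parsimony distance on the same
pair still reads 500, but it is bounded by `n` and collapses below the
diagonal as `k` grows past `n`, while the moment estimators keep tracking
the truth much longer (`run_estimator_comparison()` reproduces the full
comparison).

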