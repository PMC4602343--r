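---
title: "Estimating DCJ rearrangement distances by the method of moments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating DCJ rearrangement distances by the method of moments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcjmoments)
library(dplyr)
```

## The problem

Two genomes with the same genes but different gene orders are separated by a
history of rearrangements. The parsimony distance — the *minimum* number of
events explaining the difference — systematically underestimates the true
number once events start reusing the same breakpoint regions, which happens
early: visibly beyond roughly `n/2` events for genomes with `n` adjacencies.
This package estimates the *actual* number `k` of events under the uniform
Double Cut-and-Join (DCJ) model by the method of moments: compute the
expected value of an observable statistic as a function of `k`, then invert
it at the observed value.

## Genomes, augmentation and the uniform DCJ model

A genome on `g` genes is a matching on the `2g` gene extremities (each gene
has a head and a tail): `a` *adjacencies* join consecutive genes; the
`2g - 2a` unmatched extremities are *telomeres*. To make the event model
uniform we *augment* the genome: each telomere is matched to a fresh
telomeric vertex, and `f` fictional vertices (an even model parameter) are
matched pairwise. The augmented genome is a perfect matching with
`n = 2g - a + f/2` adjacencies. A DCJ picks two distinct adjacencies
`{A,B}`, `{C,D}` and rewires them to `{A,C},{B,D}` or `{A,D},{B,C}`; on an
augmented genome there are exactly `n(n-1)` equiprobable moves, including
moves that only touch telomeric/fictional adjacencies and leave the gene
order unchanged. A DCJ never changes the number of non-observed vertices, so
`f` must absorb the telomere-count difference between two genomes
(`choose_f()` returns the lower bound `2|a1 - a2|`; the upper end of the
bracket, tied to the equilibrium telomere scale of uniform-on-genome models,
is not settled and is left configurable).

## The breakpoint expectation and its inversion

A breakpoint of `G` with respect to `G_k` is an observed adjacency of `G`
whose endpoints are not adjacent in `G_k`. Under `k` uniform DCJs,

$$E(B_k) = a\,\frac{2n-2}{2n-1}\left(1 - \Big(1 - \frac1{n-1} -
\frac1n\Big)^k\right),$$

an exact closed form: per adjacency, a step cuts it with probability
`2/n` and re-forms it, once absent, with probability `1/(n(n-1))`, giving a
two-state recurrence whose solution telescopes (`breakpoint_recurrence()`
iterates it literally and matches the closed form to ~1e-14; the package's
exhaustive matching-chain oracle verifies the closed form as an *exact
rational identity* for `n <= 4`). Solving for `k` gives the analytic
estimator `dcj_tilde()`, flagged as *saturated* when the observed count
reaches the asymptote `a(2n-2)/(2n-1)` — expected once `k` is of order
`n log n`, after which no breakpoint-based statistic carries distance
signal.

```{r tilde}
B <- expected_breakpoints(a = 980, n = 1020, k = 500)
dcj_tilde(B, a = 980, n = 1020)
```

## Three companion processes

**Binary sequences.** Code each possible adjacency as a site that is 1 when
present. A DCJ removes two adjacencies and creates two, so sites change
*four at a time*; the single-site substitution expectation matches the
breakpoint expectation only at the matched sequence length
`N = 4a(2n-2)/(2n-1) ≈ 4a` (`proposition_mapping()` gives the exact
correspondence, which `seq_coding_estimate()` inverts). Coding only the
`2n` adjacencies present in either genome overestimates the distance;
coding all `n(2n-1)` possible adjacencies underestimates it — the sweep in
`run_seq_length_sweep()` reproduces both failure modes and the agreement at
`N = 4a`.

**Random transpositions.** Adjacencies play the role of elements of a
permutation and breakpoint-graph cycles the role of permutation cycles. The
expected cycle count of the walk has an exact alternating series
(`eh_expected_cycles()`). Two numerical points deserve note:

* *Orientation.* Exact evaluation at `n = 2` (cycle counts 2, 1, 2, 1, …)
  shows the printed series equals the expected transposition *distance*
  `n - E(cycles)`, although it is usually quoted as the cycle count.
  `eh_formula()` evaluates the printed expression verbatim;
  `eh_expected_cycles()` returns `n` minus it. The partition-chain oracle
  (`exact_transposition_cycle_expectation()`, exact big-integer arithmetic
  over cycle-type states, itself cross-checked against literal enumeration
  of the symmetric group for `n <= 5`) confirms this orientation — and
  rejects the other — for every `n <= 8`, `k <= 20`.
* *Cancellation.* The coefficients grow like `C(n, n/2)` with alternating
  signs while the result is `O(n)`, so double precision fails beyond
  `n ≈ 30`. The series is evaluated in C++ fixed-point arithmetic with
  exact big-integer coefficient numerators and roughly `n log2 n` bits of
  working precision beyond the target; every call is recomputed at doubled
  precision, and disagreement raises an error instead of returning
  cancelled garbage.

**Random multigraphs.** Adjacencies as vertices, breakpoint-graph cycles as
connected components of a graph grown by uniform random edges (parallel
edges allowed). `bd_expected_components()` evaluates the tree-count series
with the prefactor `n^2/(2k)`, the reading fixed by the requirement that the
`k -> 0` limit be `n`; terms are truncated below `1e-12` (the series
argument `c e^{-c}` with `c = 2k/n` never exceeds `1/e`, so truncation is
safe, with a hard cap of `10n` terms). Two caveats are deliberate:

* The series counts *tree* components. True component counts exceed it by
  the expected number of components containing cycles — at `n = 200` about
  0.01 at `k = 20` and 0.75 at `k = 100` against the package's Monte-Carlo
  sampler. That bias is `o(n)`, exactly the error scale the component/cycle
  analogy claims, but it is measurable: tests assert agreement at the
  approximation's own bias scale, not at Monte-Carlo precision.
* The simulator's component process (`random_graph_trajectory()`,
  union-find) and the Monte-Carlo oracle (`montecarlo_components()`,
  igraph) are independent implementations kept apart on purpose.

## Breakpoint graphs, observed and real

The union of two genomes' augmented matchings is a disjoint set of cycles
alternating between the genomes; the DCJ distance is `n` minus the cycle
count. Along a simulated trajectory the vertex identities are known, giving
the *real* graph. From data, only observed adjacencies are available: the
*observed* graph closes each even-length path of the observed union with one
telomeric vertex and each odd-length path with two fictional vertices plus a
fictional adjacency, then turns leftover budget into trivial cycles. This
closure maximizes the cycle count over telomere correspondences (verified
exhaustively for up to four non-observed vertices), so its distance is the
parsimony distance.

Two structural conventions: cycle length is counted in adjacencies of one
genome (trivial cycle = 1), making the lengths sum to the graph's adjacency
total; and traversal order fixes which path end receives which closure
vertex, for determinism. One consequence worth knowing: the closure can
*consume more* telomeric/fictional vertices than the genomes' own
augmentation carries (every odd path needs a fictional pair; with `f = 0`
any odd path does), in which case the observed graph simply has more
adjacencies than the model's `n`. Padding with trivial cycles, where the
budget allows it, changes `n` and the cycle count equally, so distances are
unaffected either way.

## The coupled transposition walk

`simulate_dcj(..., couple = TRUE)` runs the walk that motivates the
transposition analogy: each adjacency carries a label (a bijection onto
`1..n`); a DCJ on the adjacencies labelled `x`, `y` applies the
transposition `(x y)`. When a DCJ splits a real-graph cycle, the labels are
handed to the new adjacencies so as to respect the cycle structure; where
the construction is indifferent, the new adjacency with the smaller minimum
vertex id takes `min(x, y)`. Since labels are always a bijection and edges
are drawn uniformly, the induced walk is an honest uniform transposition
walk regardless of the relabeling rule — its mean cycle count matches the
exact series.

The *pathwise* domination `BCy_k <= Cy_k` that the analogy's proof sketch
suggests does **not** hold: after a DCJ that leaves the breakpoint graph
unchanged while the transposition splits the permutation, the two labels sit
in different permutation cycles but the same breakpoint-graph cycle, and a
later move on those two adjacencies can split the graph while the forced
transposition merges the permutation. At `n = 2` this occurs with
probability at least 1/8 within three steps; at `n = 200` about 9% of steps
violate the inequality. What does hold — and what the tests assert — is the
expectation-level statement: mean `Cy_k - BCy_k` is non-negative and grows
like `O(k/n)`, vanishing relative to `n` up to the saturation horizon.

## Simulation experiments

`experiment_config()` fixes the study conditions. Full scale: a random
genome with `g = 1000` genes, 40 telomeres, `f = 0` — hence `a = 980`
observed adjacencies and `n = 1020` in total — evolved for 4000 DCJs in a
single run. (The generator realizes the adjacency totals directly; telomere
and fictional counts are whatever satisfies `n = 2g - a + f/2`.) Reduced
scale for routine testing: the same proportions at `n = 120` (`g = 118`,
4 telomeres, `f = 0`, `a = 116`), 400 steps, five seeds — chosen once as
the smallest size at which saturation, parsimony collapse and estimator
agreement are all still visible. Each experiment seed derives a genome seed
and an independent chain seed, so runs are reproducible end to end.

```{r fig4, fig.width = 6.5, fig.height = 4}
cfg <- experiment_config("reduced")
comparison <- run_estimator_comparison(cfg)
plot_estimator_comparison(comparison)
```

The comparison shows the qualitative picture the estimators were built for:
all four track the diagonal while `k` is small; parsimony departs downward
first (its median falls below the diagonal beyond `k ≈ n`), while the
moment estimators stay within about 10% of the truth up to `k ≈ n/2` and
degrade gracefully toward saturation.

What these simulations do — and do not — show: the generator draws uniform
random matchings with fixed telomere counts and evolves them under exactly
the model the estimators assume. Real genomes have chromosome-number
constraints, rearrangement-rate heterogeneity along the genome, and unequal
gene content (duplications, losses), none of which the model represents;
passing tests certify the estimators against the model, not against
biology. Unequal gene content is explicitly out of scope.

## Numerical and design choices

* Gene extremities are encoded as `tail(j) = 2j - 1`, `head(j) = 2j`;
  telomeric then fictional vertices follow in a disjoint id range. Fresh
  fictional vertices pair consecutively.
* Genome equality is adjacency-set equality; arc orientation is carried for
  input/output but ignored in comparisons.
* Grid inversion (`grid_invert()`) searches integer `k` in `[0, k_max]` and
  breaks ties toward the smallest `k`; non-integer observed statistics are
  accepted so replicate means can be inverted.
* The simulator draws an unordered adjacency pair uniformly and then a fair
  rewiring bit — exactly the `n(n-1)` equiprobable moves — rather than
  enumerating moves; one seeded RNG stream per trajectory, consumed in a
  documented order (pair, then bit, per step).
* Oracles run in exact arithmetic only: a base-R big-integer layer
  (base-1e7 limbs) carries distribution numerators over the common
  denominator `(moves per step)^k`, with probability conservation checked
  at every step as a big-integer identity.
* Tabular results (trajectories, estimates, expectation tables, experiment
  outputs) are tibbles with `tidy()`/`glance()`/`autoplot()` methods;
  genomes and breakpoint graphs stay plain S3 objects, since a perfect
  matching is not usefully a data frame.

## Limitations

The estimators assume equal gene content and a known (or bracketed) `f`.
The transposition- and graph-based estimators inherit `o(n)` biases from
their analogies, visible at small `n`; the sequence-coding estimator is
exact only at the matched length. All distance signal disappears at
`k = O(n log n)`; saturated estimates are flagged, not guessed. The full
full-scale expected-cycles table (`n = 1020`, `k <= 4000`) is computable
but slow in the required precision (minutes to hours depending on
precision policy); the reduced scale used throughout the tests keeps every
computation in seconds.
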