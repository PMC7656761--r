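---
title: "DCJ genome medians by a discrete particle swarm: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{DCJ genome medians by a discrete particle swarm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcjmedian)
```

## The model

A genome over genes $1..n$ is a set of *adjacencies* (unordered pairs of
gene extremities, head $g.h$ or tail $g.t$) and *telomeres* (singleton
extremities), such that every extremity appears exactly once.  This is
equivalent to a set of signed gene-order chromosomes, linear or
circular.  The package fixes the orientation convention that a
positively written gene faces its tail left and head right, so
consecutive $(+a, +b)$ encodes the adjacency $\{a.h, b.t\}$; any
consistent convention yields identical distances, and this one is
verified in the tests against the five-gene worked example.

A double-cut-and-join (DCJ) operation cuts up to two adjacencies and
rejoins the loose extremities, covering inversion, translocation,
fusion and fission in one operation and transposition in two.  The DCJ
distance is computed from the *adjacency graph*: vertices are the
adjacencies/telomeres of the two genomes, edges are the $2n$
extremities; all components are cycles or paths, and

$$d_{DCJ}(G_1, G_2) = n - \left(C + \frac{I}{2}\right),$$

with $C$ cycles and $I$ odd-edge-count paths.  An operation is *optimal*
when it raises $C + I/2$ by one.

The *median problem*: given three genomes, find $G_m$ minimizing
$S_3 = \sum_i d(G_i, G_m)$.  The triangle inequality gives the
circular-ordering lower bound $\mathrm{medianLB} = (d_{12} + d_{13} +
d_{23})/2$; scores are integers, so $S_3 \ge \lceil \mathrm{medianLB}
\rceil$.

## Optimal-step sampling

`sample_intermediate(source, target, k)` performs $k$ optimal DCJ steps,
each drawn uniformly at random over *all* optimal operations of the
current adjacency graph.  Within a component holding $K$ elements of the
current genome, every unordered pair of elements admits exactly one
splitting recombination; even paths bounded by two target telomeres
additionally allow each of their $K$ terminal-or-internal adjacencies to
be cut.  Components are therefore sampled proportionally to
$\binom{K}{2}$ (plus $K$ for those paths) and the operation is unranked
inside the component, which keeps each step $O(n)$ without materializing
the $O(n^2)$ candidate list.  The correct recombination variant is
resolved by one trial distance evaluation; a defensive check asserts the
step lowered the distance.  An earlier implementation restricted steps
to target-adjacency completions; it biased intermediates toward mosaics
of the two endpoint genomes and was replaced by the uniform sampler.

Shared adjacencies of the two genomes sit in 2-cycles, which admit no
operations, so sorting never destroys what the endpoints agree on — the
property the swarm's recombination moves rely on.

## The swarm solver

Each particle is a candidate median genome.  Per generation:

1. **Personal bests** are replaced only on *strictly* lower median score
   (ties keep the incumbent, preventing drift cycles); the global best
   `gbest` is the lowest personal best, so its score is non-increasing.
2. **Mean best** (`mbest`) is chosen by two fitness averages: `cbest` is
   the particle whose personal-best score is closest to the population
   mean (distance $|f_i - \bar f|$); the second average is taken over
   `cbest` and the strictly better particles, and `mbest` is the member
   of that set closest to it.  Ties go to the lower score, then the
   lower index.
3. **Local attractors** $P_{id}$: when `gbest` strictly beats a
   particle's personal best, the attractor is sampled
   $\mathrm{round}(f \cdot d)$ steps along the sorting path from the
   personal best toward `gbest`, with $f$ drawn from
   $\{1/10, \dots, 6/10\}$ (round half up, clamped to $[1, d]$);
   otherwise it stays at the personal best.
4. **Positions** move in two guarded stages: toward `mbest`, then toward
   $P_{id}$, each by a uniformly random number of optimal steps in
   $1..d$ and only when the target has a strictly better score.
5. **Escape probe**: each particle then takes a short sorting walk
   (length $1 + \mathrm{Geom}(0.75)$, i.e. usually a single optimal
   step) toward a uniformly chosen instance genome.

Initialization builds a pool of $36M$ candidates — for each of $M$
repetitions, each ordered pair of instance genomes (6) and each fraction
(6), one sampled path intermediate — and each particle draws uniformly
from the pool.  The search stops when `gbest` reaches
$\lceil \mathrm{medianLB} \rceil$, or at
$\min(\texttt{max\_generations}, \lceil 1.5 \cdot \mathrm{medianLB}
\rceil)$ generations (the `min` reading shortens easy cases; `cap_rule =
"max"` is available).

### Why the escape probe is on by default

The guarded stages alone freeze the swarm: once several particles tie at
the best score, no strict-improvement guard fires and no position ever
moves again.  On a 1000-gene instance with 200 inversions per edge the
best score then stalls around 805 for the whole run, far from the
lower bound of about 600.  With the per-generation leafward probe the
same run descends steadily and reaches the lower bound (and the true
simulated ancestor) in about 500 generations.  The probe is the
package's reading of the published "avoid being trapped in a local
optimum" move — sampling steps from the current position toward the
three given genomes; its length law (mostly single steps) was chosen
because longer walks land in the strongly non-convex middle of random
sorting paths, where scores are worse than at either endpoint (measured
in the tests' easy-regime setting).  `solver_config(escape =
"stagnation")` or `"none"` restores the conservative variants.

### Parameters

| parameter | default | meaning |
|---|---|---|
| `population` | 20 | particles (candidate medians); 60 trades ~3x time for slightly better ties |
| `max_generations` | 2150 | hard cap; effective cap is `min(cap, 1.5 * medianLB)` |
| `fractions` | 1/10..6/10 | sorting-path fractions for the pool and attractors |
| `mu` | 0.5 | attractor weight, fixed (equal personal/global contribution); documentation-only in the discrete solver |
| `lb_stop` | TRUE | stop at the ceiling of the lower bound |
| `escape`, `escape_geom_p` | "always", 0.75 | leafward probe mode and step-length law |
| `seed` | NULL | `set.seed` at solve start; NULL inherits the caller's RNG state |

## The simulator: what it emulates and what it does not

`simulate_triplet()` applies exactly `r` events per edge (inversions by
default, transpositions per `inversion_fraction`) to a single linear
identity chromosome — the stated experimental protocol, where `r` is an
*average* with no dispersion law; a Poisson option exists
(`count_law = "poisson"`).  `simulate_tree_dataset()` draws a uniform
unrooted binary topology by sequential leaf attachment, roots it at a
random internal (degree-3) node carrying the identity genome, and draws
each edge's event count as `round(uniform(0.1 r, 1.9 r))`.  The
simulator does **not** emulate unequal gene content, duplications,
insertions/deletions, breakpoint hot-spots, or chromosome-number
variation; a green recovery test therefore establishes correctness of
the machinery on the stated stochastic world, not robustness to real
genome features.  Because the root is an internal node of the unrooted
topology, the inferred tree's matching node (by leaf tripartition) can
be compared directly with the true root genome
(`root_ancestor_distance()`).

## Phylogeny layer

Tree scoring follows the iterative scheme: every internal node is seeded
with the median of its three topologically nearest leaves (ties broken
lexicographically), then nodes are revisited in depth-first post-order,
re-solving each node's median against its three current neighbour
genomes and keeping strictly better assignments until a sweep changes
nothing.  Scores are integer sums of edge distances, bounded below by
zero, so termination is guaranteed; a `max_sweeps` safety cap (10)
exists but is not reached in practice.  The search scores the
neighbor-joining tree first (`ape::nj`; cross-checked in the tests
against an independent textbook implementation), then enumerates
unrooted binary topologies (guarded to 9 taxa; 2,027,025 topologies),
pruning every tree whose circular-ordering bound — computed on the leaf
ordering of its own planar embedding — is at least the best score.
Pruning at `>=` rather than `>` is exact for the best score, since a
tree's score can never undercut its bound; the property test confirms
pruned and unpruned searches return the same optimum.  In `"sorted"`
mode topologies are scored in ascending bound order under a time budget,
the practical regime for larger or distant datasets.

## Numerical choices and degenerate inputs

* `C + I/2` is integer arithmetic throughout (`I` is provably even; the
  compiled core asserts it).
* Step-count rounding is round-half-up, clamped to `[1, d]` where a
  guard has already established `d > 0`.
* Degenerate median instances (all genomes equal) terminate at
  generation 1 with score 0; a duplicated leaf makes the remaining
  pairwise distance the optimum, attained by the leaf itself.
* Genomes with no adjacencies at all (all singleton chromosomes) make
  adjacency accuracy's union empty; it is defined as 1 for equal
  genomes and an error otherwise.
* All randomness flows through R's RNG: identical (instance, config,
  seed) triples reproduce results bit-identically, including inside the
  compiled sampler (`unif_rand`).

## Known limitations

* Equal gene content only: no indels, duplicates, or unequal genomes.
* The easy-regime accuracy band is slightly tension-laden: with a mean
  distance-to-ancestor near 1, intersection-over-union adjacency
  accuracy is arithmetically capped near 0.996 for inversion-like
  residuals (each residual operation perturbs about four adjacencies of
  the union), so reported table values of 0.999 at the same distance
  are not reproducible under the stated formula; the acceptance test
  records this honestly.
* The full 12-leaf, 1000-gene, multi-day tree searches are out of desk
  scale; the phylogeny acceptance runs a 6-leaf analogue.
* Exhaustive topology enumeration is memory-bound beyond 9 taxa by
  design; larger searches need the sorted/budgeted mode.
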