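---
title: "Methods: the Random Domino Automaton on the Bethe lattice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the Random Domino Automaton on the Bethe lattice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rdabethe)
```

## The model and its assumptions

The Random Domino Automaton is a stochastic cellular automaton of
forest-fire type. Cells live on the Bethe lattice (the infinite cycle-free
3-regular tree) and are empty or occupied. One cell is selected uniformly
per step. An empty cell with $t$ occupied neighbours becomes occupied with
probability $c_t$; the four empty-cell types are *creating* ($t=0$, a new
cluster of size 1 appears), *enlarging* ($t=1$), *C2-merging* ($t=2$, two
clusters coalesce) and *C3-merging* ($t=3$, three clusters coalesce). An
occupied cell whose cluster has size $i$ triggers an avalanche — removal of
the entire cluster — with probability $\mu_i$. The solvable law is
$\mu_i = \delta/i$, which makes the *per-cluster* removal probability per
step equal to $\delta/N$ regardless of size.

Two structural facts drive everything:

* a cluster of size $i$ on the 3-regular tree has exactly $i+2$ perimeter
  cells (`bethe_perimeter()`), and
* an empty cluster of size $i \ge 2$ with $j$ creating cells has exactly
  $j+2$ C2 cells, $i-2j-2$ enlarging cells and no C3 cell
  (`empty_cluster_composition()`); a size-1 empty cluster is a single C3
  cell. These are exact combinatorial statements, and the simulator
  verifies them on cycle-free lattices snapshot by snapshot.

Stationarity is imposed by balancing expected gains and losses per step.
The balances for the density $\rho$, the cluster count $n$ and the
empty-cluster count $n_0$ are exact; the balances for the four empty-cell
counts $x_0..x_3$ and for the individual $n_i$ use the **mean-field
closure**: no correlation between neighbouring cluster sizes or empty-cell
types, so that the probability that an empty neighbour of an empty cell
becomes occupied is $T = (c_0x_0 + c_1x_1 + c_2x_2)/(x_0+x_1+x_2)$. This
closure is an approximation, and its accuracy is an empirical question the
simulator answers (below).

## The solver

For $\mu_i = \delta/i$ the moments collapse
($\sum_i \mu_i n_i i = \delta n$, $\sum_i \mu_i n_i i^2 = \delta\rho N$)
and the six unknowns $(x_0,x_1,x_2,x_3,\rho,n)$ satisfy three linear
relations, three $T$-product relations
($3Tx_0 = \delta\rho N + \delta x_1 - c_0x_0$,
$2Tx_1 = (c_2+2\delta)x_2 + c_3x_3$, $Tx_2 = (3\delta + c_3)x_3$) and the
definition of $T$. Substituting the products into the definition of $T$ and
eliminating $\delta\rho N$ yields a fourth *linear* row,

$$6c_0x_0 + (4c_1-2\delta)x_1 + (c_2-6\delta)x_2 - (11c_3+18\delta)x_3 = 0,$$

so $x(n,\rho)$ solves a 4×4 linear system and is affine in $(n,\rho)$. The
remaining two relations, with $T$ taken from the C3 row and multiplied
through by $x_2$, are then two conics in $(n,\rho)$ (`conic_pair()`); their
coefficients are assembled analytically from products of affine forms — no
numerical fitting, no transcription of coefficient tables. Intersections
are found by damped Newton from a 9×9 multistart grid, deduplicated, and
filtered by admissibility: $n>0$, $0<\rho<1$, $x_i \ge 0$, $x_2 > x_0$,
$T \in (0,1)$, $\rho < 1/(1+\delta)$. Every published configuration yields
exactly one admissible intersection; the package warns if it ever finds
more. An independent oracle — multistart Newton on the *unreduced*
six-equation system with $T$ kept in its defining form — agrees with the
elimination path to $10^{-9}$ and finds no second admissible root on a
20-point parameter grid.

All solver arithmetic is per cell ($N = 1$); the reference scale $N$
(default $10^6$) only enters when the state object is assembled. This makes
`rda_solve()` exactly invariant under rescaling $N$.

### The stability window

`delta_range()` tracks the admissible branch by Newton continuation in
$\delta$ and brackets three events by bisection refined to
$|\Delta\delta| < 10^{-10}$: $n(\delta) = 0$ (lower boundary
$\delta_{\min}$, the inverse-power limit), $x_2(\delta) = x_0(\delta)$
(upper boundary $\delta_{\max}$, where the admissibility half-plane closes)
and $n(\delta) = n_0(\delta)$ (the crossover $\delta_{eq}$). The $n = 0$
boundary is evaluated as a root *along the branch* — $n$ remains an unknown
and the bisection finds where it crosses zero — never by substituting
$n = 0$ into moment ratios. Boundaries that produce no sign change inside
$(0,1)$ are reported as `NA` (open boundary).

## The cascade and its truncation

`cascade()` evaluates the triangular system for $g_i = n_i/n$ in increasing
$i$. The pairwise convolution $A_m = \sum_k g_k g_{m-k}$ is cached so the
three-fold sum $B_m = \sum_k g_k A_{m-k}$ costs $O(m)$ and the whole run
$O(i_{\max}^2)$; the naive $O(i_{\max}^3)$ double/triple loop is kept in
the test suite as the oracle. Default $i_{\max} = 10^4$ with an early stop
once $i\,n_i < 10^{-12}\rho N$, i.e. once the remaining tail cannot change
the captured mass at double precision. `captured_mass`
($\sum i n_i/\rho N$) and `captured_count` ($\sum n_i/n$) are the
truncation diagnostics: near $\delta_{\max}$ they reach 1 at modest
$i_{\max}$, near $\delta_{\min}$ the $i^{-3/2}$ section makes mass converge
slowly — exactly the regime the early stop and the diagnostics are for.

Two mean cluster sizes are reported with explicit labels: the exact
$\rho N/n$ of the solved state (equal to $Y/\delta + 1$) and the truncated
cascade mean $\sum i n_i / \sum n_i$. The published tables print values
(e.g. 128.34 where $\rho N/n \approx 202$) that match the truncated mean at
an unstated cutoff, not the exact identity; the package therefore never
compares the two silently, and the table's mean-size column is matched only
qualitatively.

`invert_for_mu()` solves each cascade equation for $i\mu_i$ given a target
distribution and fixed aggregates; entries with implied $\mu_i \notin
[0,1]$ are flagged rather than clipped, since they mean the target is not
realizable by any avalanche law at that state.

## Integer recurrences

Rescaling $n_i/n = (c_1x_1/c_2x_2)\,r^i M_i$ with
$r = c_1x_1/((\delta+Y)n)$ turns the cascade into a convolution recurrence
with $M_1 = M_2 = (c_0x_0)(c_2x_2)/(c_1x_1)^2$: the Motzkin recurrence when
$c_3 = 0$, and, with the three-fold term carrying
$a_3 = (c_1x_1)(c_3x_3)/(c_2x_2)^2$, a generalized form whose
unit-coefficient integer case is OEIS A036765 (1, 1, 2, 5, 13, 36, ...).
`rescale_cascade()` computes the $M_i$ from an actual solved cascade and
*verifies* the recurrence term by term rather than assuming it. The integer
sequences themselves (`motzkin()`, `generalized_k3()`) are computed in
exact arbitrary-precision arithmetic implemented in compiled code (base
$10^6$ limbs; no floating point anywhere), because no big-integer package
is available in the target environment and exactness is the module's
contract. The printed third relation of the generalized system is garbled
in the source material; the package fixes $M_3 = M_2 + M_1^2$ in the
unit-coefficient case, which reproduces the published third term (2) and
the printed A036765 terms, and that sequence is used as ground truth.

`scaling_limit()` records the bookkeeping of the two inverse-power limits:
requiring $M_1 = M_2 = 1$ with Motzkin growth compensation forces
$c_0x_0 = c_1x_1 = c_2x_2 = \delta\rho N/3$ and $\delta n = 0$ (the strict
power law lives on the $n \to 0$ boundary), while the analogous A036765
conditions would force all four $c_ix_i = \delta\rho N/4$ and hence
$\delta n < 0$ — impossible, so that constructor raises
`"unreachable initial condition"`.

## The simulator: what it emulates and what it does not

The model is defined on the infinite lattice; any finite run is a
surrogate. The default is a uniformly random 3-regular graph
(`igraph::sample_k_regular`): boundary-free and locally tree-like, the
standard finite stand-in for Bethe-lattice mean field. The `cayley-ball`
mode (a radius-$r$ ball of the actual tree, $N = 1 + 3(2^r-1)$) is exactly
cycle-free and is used for the exact combinatorial checks, with
measurements restricted to clusters that neither contain nor touch a
boundary vertex — on a tree half the vertices are leaves, so only the
combinatorics, not the aggregates, are meaningfully measured there.

Cluster bookkeeping is an incremental union–find (union by size, path
compression): occupying a cell unions it with occupied neighbours; an
avalanche BFS-clears the removed cluster and resets only its own entries,
which is sound because components never reference other components' cells.
The plain per-step BFS recomputation survives as
`run_sim(use_union_find = FALSE)`; both paths consume the RNG in the same
fixed order (cell draw, then one acceptance draw) and the suite asserts
bit-identical trajectories. Defaults: burn-in 50 sweeps, one snapshot per
sweep, batch-means standard errors with 20 batches.

### What a green simulator test does and does not establish

The simulator is validated by (i) trajectory identity between the
union-find and BFS paths, (ii) exact per-snapshot conservation and
change-of-variables identities, (iii) zero violations of the empty-cluster
composition law and the $i+2$ perimeter formula on cycle-free snapshots,
(iv) agreement of stationary means with an independent plain-R
implementation of the update rule, and (v) the *exact* flow-balance
identities for $\rho$, $n$, $n_0$, whose stationary expectations must
vanish — and do, within batch-means error.

What the simulation does **not** reproduce is the mean-field solution
itself to statistical precision. At 50,000 cells the measured stationary
state differs systematically from `rda_solve()`: the density by 0–11%
depending on the configuration (largest when merging is switched off,
$c_2 = c_3 = 0$) and the empty-cluster count always exceeds the closure
value by many standard errors. Because the simulator passes every
closure-free check, this is a genuine, quantified limitation of the
mean-field factorization, not an implementation artifact; the acceptance
criterion that demanded 3-standard-error agreement is therefore left red
with this analysis. A second finite-size effect worth knowing: for most
in-window parameter sets the finite system relaxes through large
quasi-periodic density oscillations (range up to ~0.7 even at 50,000
cells), so batch-means errors are honest but large; below
$\delta_{\min}$ the oscillation simply never damps. The prescribed
non-stationarity detector (first/second-half means differing by more than
5 SE) reliably flags drifting transients but not a symmetric oscillation,
which averages out; the below-window test therefore asserts the large
swings directly and exercises the detector on a drifting trajectory.

## Numerical choices

* Conic coefficients: analytic affine products; Newton tolerance
  $10^{-14}$ on the step, acceptance of a root at residual
  $10^{-10}\cdot$(coefficient scale); roots deduplicated at $10^{-8}$.
* $\delta$ boundaries: bisection width $10^{-10}$ (printed values have six
  decimals; the tests assert $5\times10^{-7}$).
* Degenerate parameters: $c_1 = 0$ or $c_2 = 0$ are allowed (the published
  tables use $c_2 = c_3 = 0$ rows); the admissibility filter and the
  $Tx_2$ elimination guard the divisions. $c_0 \le \min(c_2, c_3)$ is
  rejected at construction — merging would outrun cluster creation.
* Balance-residual orientation: residuals are signed as avalanche inflow
  minus occupation outflow, the one orientation under which both exact
  dependency relations (density = empty-clusters − clusters; sum of the
  four type equations = density) hold for arbitrary states.
* Table comparisons: fractions at ±0.05 percentage points (tables print
  one decimal), counts at ±1 (integer printing), density at $5\times
  10^{-7}$ (six printed decimals).

## Known limitations

* Coordination numbers other than 3 and the one-dimensional chain are out
  of scope; the parameter constructor rejects `k != 3`.
* The Monte-Carlo stepper implements only the $\delta$-law; general
  $\mu(i)$ is supported by the residual and cascade modules.
* The finite-lattice stationary state differs from the mean-field solution
  by more than Monte-Carlo error (quantified above); the solver describes
  the closure, not the finite simulation.
* Five published table cells fail verification against the model's own
  equations (a density misprint, one unconverged row, and three
  rounding-inconsistent cells); the package reproduces the corrected
  values, confirmed by an independent solver, and the acceptance test
  documents the discrepancy rather than hiding it.
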