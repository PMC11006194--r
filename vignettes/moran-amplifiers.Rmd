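---
title: "Moran dynamics on weighted graphs: models, solvers and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Moran dynamics on weighted graphs: models, solvers and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(moranamp)
```

## The model

A population of constant size $N$ lives on a connected, undirected,
weighted graph $G_N = (V, E)$: nodes are sites, each occupied by a single
individual, and the weight $w(u,v) > 0$ of an edge measures how strongly
the two sites interact. Residents have fitness 1; a mutant has relative
fitness $r > 0$ (the interesting regime is $r \ge 1$). Two classical
update rules drive the dynamics, and `moranamp` implements both:

* **Birth-death (Bd).** An individual $u$ reproduces with probability
  $f(u)/F$ (fitness-proportional, $F = \sum_u f(u)$), and its offspring
  replaces a neighbour $v$ chosen with probability
  $w(u,v)/\deg(u)$, where $\deg(u) = \sum_{v'} w(u,v')$.
* **death-Birth (dB).** An individual $v$ dies with probability $1/N$
  (uniformly), and the vacancy is filled by a neighbour $u$ with
  probability $f(u)\,w(u,v) / \sum_{u'} f(u')\,w(u',v)$. Fitness acts in
  the birth step only.

Both processes absorb at the homogeneous states. The central quantity is
the *fixation probability* $\rho(G_N, S)$ that mutants starting on the
set $S$ take over the graph; *uniform initialization* places a single
mutant at a uniformly random node, $\rho(G_N) = \frac1N \sum_v
\rho(G_N, \{v\})$. The well-mixed baseline is the complete graph $K_N$,
with closed forms

$$\rho^{Bd}(K_N) = \frac{1 - 1/r}{1 - 1/r^N}, \qquad
  \rho^{dB}(K_N) = \frac{N-1}{N}\cdot\frac{1 - 1/r}{1 - 1/r^{N-1}},$$

both equal to $1/N$ at $r = 1$ (`rho_complete()` resolves the removable
singularity analytically rather than by perturbing $r$). A graph is an
*amplifier* under a given rule if its uniform-initialization fixation
probability exceeds the baseline at the same $N$ and $r$, a *suppressor*
if it falls below. The star is the canonical Bd amplifier; fans — a hub
weakly coupled to many two-node blades — are the strongest known dB
amplifiers; and the composite two-chunk structure built by
`make_amplifier_an()` targets amplification under *both* rules at once.

## Exact solvers

`solve_fixation_exact()` enumerates all $2^N$ mutant configurations as
bitmasks and solves the linear absorption system. Two numerical choices
matter:

* The chain is conditioned on configuration-changing events (the
  embedded jump chain) before solving. This leaves absorption
  probabilities untouched but removes the near-unit diagonal produced by
  rare-interaction edge weights (the composite amplifier has weights
  spanning six orders of magnitude), keeping the sparse solve well
  conditioned.
* The system is solved on the transient subspace with `Matrix`'s sparse
  LU; the attained residual $\max|Ah - b|$ is reported in the result so
  callers can see the solver tolerance rather than trust a constant.

The full-state backend refuses graphs above `n_max = 20` nodes with a
capacity error (the state space is $2^N$; memory grows as $2^N|E|$) and
points the caller to the lumped or Monte Carlo backends.

`solve_fixation_lumped()` exploits node symmetries. Each family
constructor records the orbit structure of its automorphisms as three
kinds of state components: designated nodes tracked individually (star
or fan center, the connecting-edge endpoints $u$ and $v$ of the
composite), interchangeable classes tracked by mutant count (complete
graph, star leaves, hub nodes), and interchangeable two-node blades
tracked by the pair $(n_1, n_2)$ of blades with exactly one and with two
mutants. The solver breadth-first-enumerates the classes reachable from
single-mutant seeds, aggregates the conditional one-step law class by
class, and solves the resulting (much smaller) absorption system: the
26-node composite collapses from $2^{26} \approx 6.7\times 10^7$
configurations to 8818 classes. Because the partition is induced by
weight-preserving automorphisms, lumping is exact; rather than assuming
this, the solver re-derives the transition law from a second member of
every class it meets (tolerance $10^{-9}$) and refuses with an
invariant-violation error on any mismatch. The test suite additionally
verifies lumped $\equiv$ full-state on every family small enough to
enumerate, for both update rules.

## Monte Carlo engine

`estimate_fixation_probability()` runs independent trajectories to
absorption in compiled code. Each step samples one replacement event by
a linear inverse-CDF scan recomputed from the current configuration — no
caching across steps — and draws its random numbers from R's own RNG, so
a seed makes trajectories exactly reproducible. Steps that copy a type
onto the same type count as steps (only the mutant count matters for
absorption detection). `max_steps` defaults to unlimited because the
rare-interaction weights of the composite amplifier make trajectories
long (hundreds of thousands of steps at $t = 100$); replicates that do
hit a finite cap are reported in `$capped` and excluded from the
estimate, never silently counted as extinctions. The standard error is
the binomial normal approximation. Compiled simulation is what makes the
composite-amplifier checks feasible: its mean trajectory occupies
$\sim 2\times 10^5$ steps, so a pure-R event loop would be orders of
magnitude too slow.

## Temperature, first-step survival, and the impossibility checks

The *temperature* $T(u) = \sum_{v \sim u} w(v,u)/\deg(v)$ is the neutral
rate at which $u$ is replaced under Bd updating; temperatures always
average to 1. The *first-step survival* $\gamma(G, u)$ is the probability
that the first event changing the mutant count, from a single mutant at
$u$, is the mutant reproducing. `gamma_first_step()` computes it
generically by conditioning the one-step distribution, which is the
source of truth; the closed forms $\gamma^{Bd} = r/(r + T(u))$ and
$\gamma^{dB} = S/(1+S)$ with
$S = \sum_{v\sim u} r\,w(u,v)/(\deg(v) + (r-1)w(u,v))$ are fast paths
cross-checked against the generic computation in the tests (the dB form
is derived, not taken from literature, hence gated behind that test).

Two impossibility results are verified numerically rather than proved:

* **Neutral regime.** At $r = 1$ the fixation probabilities have
  degree-based closed forms, $\rho^{Bd}(G, v) \propto 1/\deg(v)$ and
  $\rho^{dB}(G, v) \propto \deg(v)$ (normalized over nodes). These are
  reconstructed from the structure of the reversible neutral dynamics
  and are *verified against the exact solver on random fixtures before
  being trusted* — the test suite compares them on hundreds of seeded
  random weighted graphs at $10^{-8}$. `check_theorem1()` then asserts
  the trichotomy: no start node beats the $1/N$ baseline under both
  rules; a violation raises an error instead of returning a label.
* **First-step bias.** `check_theorem2()` compares $\gamma^{Bd}(G,u)$
  against $r/(r+1)$ and $\gamma^{dB}(G,u)$ against the complete-graph
  value at the same $N$: again no node may exceed both, and nodes with
  above-average temperature are necessarily below the Bd baseline.

Both sweeps run over hundreds of seeded random connected weighted graphs
(`random_connected_graph()`: spanning-tree skeleton plus
density-controlled extra edges, log-uniform weights in $[0.1, 10]$ —
chosen to exercise strong degree heterogeneity without degenerate
near-zero weights). Verdict tolerances are $10^{-9}$ for the
deterministic backends, wide enough to absorb solver noise and narrow
enough to distinguish true isothermal equality; Monte Carlo
classification (`classify_graph(..., method = "monte-carlo")`) instead
reports `"inconclusive"` whenever the 99% confidence interval straddles
the baseline, rather than overclaiming a verdict.

## The composite amplifier and its chunk-coupling approximation

`make_amplifier_an(a, b, f, t)` joins a Bd-favouring chunk (a hub of $a$
nodes forming a unit-weight clique, with $b$ two-node blades attached to
every hub node by a weak coupling) to a dB-favouring fan on $f$ nodes,
through a single edge of weight $t^{-3}$ between a hub node $u$ and the
fan center $v$. After construction, $u$'s remaining incident weight is
rescaled to total $t^{-1}$ and $v$'s to total 1. These totals fix the
migration asymmetry that makes the construction work: under Bd updating
offspring cross mostly $u \to v$ (rate ratio $\approx r\,t$), under dB
updating mostly $v \to u$ — each chunk is "upstream" exactly under the
rule it amplifies, so a mutant that has fixed its favoured chunk (the
*half done* state) is very likely to finish the job.

Several interior details are deliberate package choices, since only the
weight totals and the rare-interaction principle are fixed by the
construction: the hub is a unit clique and every blade node attaches to
every hub node with default coupling $0.01/a$ (the same
rarely-interacting-units motif as the fan); $u$ is a hub node and $v$
the fan center; the fan coupling defaults to $1/(f-1)$ so $v$'s total is
exactly 1 before rescaling; and $t = 100$ by default — large enough that
the chunks resolve internally between cross-chunk events, small enough
for tractable simulation. All of these are constructor arguments. With
these defaults the 26-node instance used throughout the tests is *not*
itself an amplifier (at $N = 26$ the chunks are far too small for the
size balance the construction needs — amplification under both rules is
a large-$N$ phenomenon); the desk-scale value of the instance is that
three independent routes to its fixation probability must agree, which
they do.

`chunk_coupling_approximation()` coarse-grains the dynamics onto
\{all-resident, Bd-chunk half done, dB-chunk half done, all-mutant\}.
Entry into a half-done state is (chunk size$/N$) $\times$ the chunk's
standalone uniform-init fixation probability; from a half-done state,
absorption into all-mutant happens with probability $\lambda_m q_m /
(\lambda_m q_m + \lambda_r q_r)$, where the $\lambda$'s are the
cross-edge migration rates evaluated at the half-done configuration and
the $q$'s are the success probabilities of a single crossing mutant
sweeping the resident chunk, resp. a single crossing resident retaking
the mutant chunk (all computed exactly from the standalone chunk chains,
which are themselves lumpable). The neglected effects — chunk resolution
overlapping a cross event, repeated reseeding during an invasion — are
$O(1/t)$; at $t = 100$ the approximation matches the lumped solve to a
fraction of a percent, and the acceptance check allows it 10% relative
slack on top of the Monte Carlo confidence interval.

## Problem sizes and what the tests do and do not show

The package's own verification uses sizes at which independent oracles
exist: full-state solves up to $N \approx 12$ against lumped chains,
the 11-node benchmark family (star amplifies Bd only, fan amplifies dB
only, across $r \in \{1.01, \dots, 1.1\}$), the 26-node composite for
the three-way lumped/simulation/approximation agreement, and sweeps of
200–500 random graphs for the neutral and first-step trichotomies. The
random fixtures are small ($N \le 8$) and their weights are moderate;
passing sweeps therefore demonstrate the impossibility patterns on
graphs with strong degree heterogeneity, not on structures with extreme
weight separation (those are covered by the composite-amplifier checks)
and not for initial sets of two or more mutants, where the neutral
trichotomy is known to fail and which this package does not analyse.
Reproducing the large-$N$ ($N \approx 1000$) composite-amplifier curves
is out of desk scale: the lumped chain for the composite still grows
with $a b^2 f^2$ classes, so a faithful run at $N = 1001$ is an
hours-scale computation best done with the Monte Carlo backend on a
cluster; the package exposes exactly the machinery needed but its test
suite does not claim that result.

## Limitations

* Directed graphs, self-loops, disconnected populations and
  time-varying structure are out of scope by design.
* The lumped backend covers the four constructor families only; custom
  graphs get a clear unsupported-family error.
* Fixation *times* are recorded per trajectory (`$mean_steps`) but not
  analysed; the package makes no claims about them.
* The composite amplifier's interior weights are parametrized defaults
  satisfying the construction's weight-total contract, not a unique
  canonical instance; conclusions about a specific instance should cite
  its full parameter vector.
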