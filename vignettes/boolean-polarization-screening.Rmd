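---
title: "Boolean control networks and in silico inhibition screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Boolean control networks and in silico inhibition screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bcnscreen)
```

## The model

`bcnscreen` simulates intracellular signaling as a *Boolean control
network*: every molecular species (receptor, kinase, transcription
factor, gene) is a node that is either active (1) or inactive (0), and
directed signed edges carry activation or inhibition between them.
Input nodes stand for extracellular small-molecule transmitters whose
presence is fixed by the cell's microenvironment; output nodes stand
for the transcriptional activation of polarization-relevant genes;
inner nodes are the transducers in between.

All nodes update simultaneously (a synchronous scheme). Writing the
global state at step $t$ as the binary column vector $S_t$, the
dynamics are

$$S_{t+1} = \mathrm{thr}(W \cdot S_t - \Theta)$$

where $W$ is the square signed weight matrix (entry row = target,
column = source; absent edges are 0), $\Theta$ is a per-node threshold
vector, and $\mathrm{thr}(x) = 1$ for $x \ge 0$, else $0$. Edge
weights are logic, not affinity: a single $+1$ edge is sufficient
alone to activate a unit-threshold target (OR), two $+0.5$ edges are
jointly necessary (AND), and a $-1$ edge can veto a single $+1$
activator (NOT). This is why the default threshold is $1$ and the
canonical weights are $\pm 1$ and $\pm 0.5$; constitutively active
nodes instead get $\Theta = 0$, which keeps a source-less node
permanently on because $\mathrm{thr}(0) = 1$.

### Clamping and perturbation by threshold override

Everything external to Equation above — the environment and simulated
drug action — is realised purely by editing the *effective* threshold
vector, so the one update rule is the entire dynamics:

* an active input gets $\Theta = 0$ (inputs have no incoming edges, so
  they are held on);
* an inactive input, or an inhibited target, gets $\Theta = +B$;
* a constitutively activated node gets $\Theta = -B$;

with $B = 1 + \sum |W_{ij}|$, a bound no achievable activation sum can
cross. Inhibition is therefore 100% efficient and immutable, the
idealisation appropriate for screening rather than pharmacokinetics.

### Attractors

Every run starts with *all* nodes inactive at step 0 — including
inputs, which switch on at step 1 through their clamped thresholds.
Because the update is deterministic on a finite state space, every
trajectory ends in an attractor: a steady state (period 1) or a limit
cycle. `find_attractor()` detects it with Brent's cycle-finding
algorithm (power-of-two comparison windows, constant memory), then
recovers the exact transient length and minimal period by the standard
two-pointer replay. `batch_attractors()` evaluates many environments
at once as one state matrix per step — one matrix product per update —
with exact fixed-point detection, falling back to per-environment
Brent for any environment that has not settled within the batch
window; its results are bit-identical to the per-environment path and
the test suite asserts this.

The default `max_steps = 10000` is a guard, not a tuning parameter:
networks of the size treated here empirically converge in tens of
steps, and the cap only matters for pathological inputs.

## Polarization, flips, synergy

The state of the cell at its attractor is summarised by the
polarization index

$$\mathrm{pI} = \frac{A_1}{T_1} - \frac{A_2}{T_2}$$

where $A_x$ is the summed activity of the polarity-$x$ outputs and
$T_x$ their total count; type 1 is the inflammatory (M1-like) pole,
type 2 the tissue-protective (M2-like) pole, and $\mathrm{pI}$ runs
from $-1$ (fully M2-like) to $+1$ (fully M1-like). In a limit cycle
each node contributes the fraction of cycle states in which it is
active, so the index is well defined for oscillating attractors
without special-casing. The canonical macrophage output assignments
ship as `MACROPHAGE_TYPE1_OUTPUTS` (11 genes) and
`MACROPHAGE_TYPE2_OUTPUTS` (7 genes); outputs without an assignment
never influence the index. Input-layer polarity (used to characterise
the environment itself) must come from the node table — it is a data
property, and the package deliberately refuses to guess it.

A perturbation *flips* the polarization when both the baseline and the
perturbed attractor are committed, $|\mathrm{pI}| > 0.2$ with the
inequality strict, and the two signs differ. The direction of a flip
is named after the destination sign. A perturbed index of exactly 0
can never flip.

For a pair of targets $A$, $B$ under environment $i$, the synergy
index is

$$\mathrm{synI}(A,B,i) = \frac{|\Delta \mathrm{pI}(AB,i)|}
 {\max(|\Delta \mathrm{pI}(A,i)| + |\Delta \mathrm{pI}(B,i)|,\ \tau)}$$

with $\tau = 0.1$ by default — an arbitrary but fixed floor that stops
the ratio exploding when both single effects are negligible, capping
synI at $|\Delta \mathrm{pI}|/\tau$. Values above 1 indicate synergy,
1 additive (parallel-pathway) action, below 1 overlapping pathways.
The summary's "synI = 1" bucket uses $|\mathrm{synI} - 1| \le 10^{-9}$:
with binary-fraction weights all pI arithmetic is exact in floating
point, so a tight tolerance is safe and exact additivity is common.

## The screen

`run_screen()` crosses every eligible target with every non-empty
input environment. Eligibility follows the screening convention of the
macrophage model: inner nodes only, excluding receptor-flagged nodes
except TLR2 and TLR4. Environments are enumerated by binary counting
over the node-table input order ($2^k - 1$ of them; the all-inactive
environment is excluded). Baseline attractors are cached once per
environment and shared across targets; order-2 records reuse the
order-1 $\Delta\mathrm{pI}$ of the same environment for synI. The test
suite checks the batched screen against a naive oracle that recomputes
every case independently.

Tunable screen parameters, all strictly positive:

| parameter | default | meaning |
|---|---|---|
| `tau` | 0.1 | synI floor (index units of pI) |
| `flip_threshold` | 0.2 | commitment level for flips (strict) |
| `shift_threshold` | 0.4 | \|ΔpI\| counted as a considerable shift |

Percentages in summaries are rounded to 2 decimals for reporting; all
underlying counts are exact.

## The synthetic-network generator

The package bundles no curated interaction data, so
`generate_random_bcn()` produces networks with the structural features
the analysis assumes: a three-layer feed-forward shape (inputs →
inner, in index order, → outputs), AND/OR gate wiring with weights
drawn from $\{\pm 1, \pm 0.5\}$, optional inhibitory veto edges, an
approximately heavy-tailed degree distribution via preferential
attachment on out-degree, and an optional number of injected feedback
edges among inner nodes. Defaults, chosen once as plausible for a
curated signaling network and not revisited: `and_gate_fraction =
0.25`, `inhibitory_fraction = 0.15`, `cycle_edges = 0` (feed-forward,
so all attractors are steady states — the behaviour expected of an
early-response model with feedback loops excluded). Output and input
polarities alternate type1/type2 deterministically so the polarization
index is always defined.

What generated networks do **not** emulate: polarity-coherent pathway
wiring. Real curated networks route inflammatory stimuli
preferentially to inflammatory genes, which produces a positive
input–output pI correlation; random wiring has no such bias, so on
synthetic networks that correlation is well-defined but of arbitrary
sign, and single inhibitions rarely produce committed flips. Passing
tests on synthetic networks therefore demonstrate the correctness of
the *machinery* (dynamics, indices, screens, statistics), not any
biological claim; quantitative claims about macrophages require
loading a curated node/edge table via `load_network()`.

The generator's RNG (Mersenne-Twister) and seed are recorded in the
exported metadata sidecar; the caller's RNG state is saved and
restored, so generation is reproducible and side-effect free.

## Numerical choices

* Weights and thresholds are binary fractions; every activation sum is
  exact in double precision, so the $\ge$ comparison in
  $\mathrm{thr}$ needs no tolerance. Arbitrary real weights work but
  forfeit this exactness guarantee.
* Transients are reported exactly: the number of steps from the
  all-inactive start to the first attractor state.
* The power-law fit is ordinary least squares of $\log(\mathrm{count})$
  on $\log(\mathrm{degree})$ over degree classes with positive counts
  (at least 3 required), with an explicit exclusion list for outlier
  degrees; the exponent is the negated slope.
* Betweenness centrality treats inhibitory edges as ordinary directed
  edges (it is a topological, not dynamical, statistic) and normalises
  by $(n-1)(n-2)$.
* Ties and degenerate inputs: an empty criteria list, an empty screen,
  a polarity class with no members, and fewer than 3 environments for
  the correlation are all errors, not silent NAs.

## Worked example

```{r example}
net <- make_fixture("two_path_synergy")
net

# single inhibitions cannot silence the redundantly-driven output ...
run_screen(net, screen_config(order = 1))[, c("target1", "delta_pI")]

# ... but the pair does, with the synergy index capped at |dpI|/tau
run_screen(net, screen_config(order = 2))[, c("target1", "target2",
                                              "delta_pI", "synI")]
```

```{r oscillator}
ring <- find_attractor(make_fixture("ring_oscillator"), "IN1")
ring
ring$activity
```

## Problem sizes

The shipped test suite and the reproduction script
(`scripts/acceptance.R`) run on synthetic networks at the study's
layer census (9 inputs, 75 inner, 22 outputs; 511 environments) for
the order-1 screen and structural statistics, and on all pairs of a
12-target subset (66 pairs × 511 environments) for the order-2 screen
— sizes chosen so a complete reproduction stays in the minutes range
on a single core while still exercising every code path at full
environment resolution. A full 75-target pair screen (2,775 pairs ×
511 environments ≈ 1.4 M cases) runs in well under an hour on one core
with the batched evaluator, should you need it.

## Known limitations

* Synchronous updates only; no asynchronous or stochastic schemes, and
  no continuous (ODE) semantics.
* Inhibition is all-or-nothing; partial efficacy is out of scope.
* Screens stop at target pairs; no triple combinations.
* SIF and GraphML exports are lossy (no thresholds or flags); only the
  canonical TSV pair round-trips exactly.
* The verification harness maps literature up/down-regulation onto a
  binary expectation at the attractor (activity $\ge 0.5$ counts as
  active for limit cycles), which is the natural reading for a Boolean
  model but discards effect sizes.
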