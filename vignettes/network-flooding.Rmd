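---
title: "Network flooding: model, algorithm, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network flooding: model, algorithm, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(floodnet)
```

## The problem

Gene regulatory networks are signed, weighted, directed graphs: an edge
$(u, v)$ with weight $c(u,v) > 0$ means $u$ activates $v$, a negative weight
means inhibition, and the magnitude measures regulatory strength. Given such
a network, a set of active environmental signals (heat, nutrients, a sigma
factor — anything sensed by receptor genes), and optionally a set of
reporter ("sink") genes, two questions arise:

1. How much regulatory information flows through each gene and each
   interaction under this specific condition?
2. What is the minimal sub-network that carries the condition's regulatory
   program from the inputs to the outputs?

Classical network flow does not apply, for two reasons. First, regulation
can be negative, and a gene whose inhibitory input outweighs its activatory
input is simply silent — flow is not merely reduced, it is gated at zero.
Second, regulatory "flow" is *replicated*, not conserved: a transcription
factor that accumulates to some activity level drives *each* of its targets
with that level. The sum of outgoing flows of a node has no relation to the
sum of its incoming flows.

`floodnet` implements a calculus for exactly this setting — *network
flooding* — together with the network transformation that maps a GRN onto
it, a threshold/sink minimization pipeline, a synthetic-network generator
for testing and benchmarking, and a reporter-enrichment statistic for
judging minimization quality.

## The flood model

A **flood network** is a directed graph in which every edge carries a
signed, non-zero capacity $c(u,v)$, together with a set of source nodes.
The **flood** $f(u,v)$ is the information actually carried by an edge, and
any admissible flood assignment must satisfy:

* **Capacity**: $|f(u,v)| \le |c(u,v)|$ — an interaction cannot transmit
  more than its strength;
* **Polarity**: $f(u,v)\, c(u,v) \ge 0$ — flood through an inhibitory edge
  is negative or zero, through an activatory edge positive or zero;
* **Walk accumulation**: floods are laid down by a breadth-first traversal
  of *essential walks* from the sources. When a walk ending at $u$ expands
  through $(u, v)$, the edge's flood becomes
  $$f(u,v) \;=\; \operatorname{sign}(c)\,
    \max\!\big(0,\ \min(|c(u,v)|,\ \mathrm{in}(u))\big),$$
  where $\mathrm{in}(u)$ is the algebraic sum of everything the traversal
  has so far delivered into $u$; the walk then carries the signed *change*
  of $f(u,v)$ forward. Outgoing edges of a source always carry their full
  capacity. A negative $\mathrm{in}(u)$ — inhibition dominating — propagates
  nothing, regardless of outgoing capacities.

Because each outgoing edge applies the same rule to the same incoming
total, flood is replicated across fan-outs. The amount by which the inflow
exceeds what an edge can carry is recorded per edge as **excess**; it is
where saturation and capacity clipping become visible to the user.

### Essential walks: how cycles are handled

Feedback loops are ubiquitous in GRNs, so the traversal cannot be a plain
BFS/DFS, and unrestricted walks would never terminate. A walk is
**essential** if, between any two successive visits of the same node, at
least one intermediate node does not appear in the walk's prefix up to the
earlier visit. Intuitively: a walk may go around a cycle, but each revisit
must be "paid for" with a node that is new at that point. Essential walks
have length at most $|V|^2$, traversal terminates, and a feedback loop of
any size is traversed — once. A walk none of whose one-step extensions is
essential is **saturated**; the breadth-first set of saturated walks (the
*essential traversal*) is what `enumerate_essential_traversal()` returns.

### Determinism and processing order

The walk-accumulation rule makes floods depend, in cyclic networks, on the
order in which same-length walks are processed. The package fixes a
canonical order — breadth-first by walk length, ties broken by the byte
order of the node-id sequence — used identically by both implementations.
Together with canonical, sorted internal representations this makes every
result deterministic and independent of the order in which the user's edge
list happens to be written; the test suite asserts byte-identical
minimization output across shuffled inputs.

### Expansions that change nothing are terminal

The defining propagation step is a flood *change* travelling along a walk.
An expansion that leaves its edge's flood unchanged (change magnitude at
most `zero_tol`, default $10^{-12}$) therefore has nothing to propagate and
is not pursued further — in both implementations. This choice is what makes
the traversal practical: once a region of the network is saturated (every
edge at capacity) or suppressed (inhibition-dominated), it stops generating
work, and flooding a 200-gene network takes a fraction of a second where
the unpruned walk set would be astronomical.

It has one documented consequence. In cyclic networks a correction can
occasionally be *blocked*: a later walk lowers $\mathrm{in}(u)$, but every
walk that could re-traverse some edge $(u,v)$ to lower its flood
accordingly is forbidden by the essentialness predicate, and the edge keeps
the flood laid down earlier. Floods are thus a record of the traversal
history, not the solution of a fixed-point system. We considered the
alternative — eagerly re-synchronizing every downstream edge whenever a
node total changes — and rejected it: on negative feedback loops that
recomputation oscillates between two states forever (the underlying
fixed-point equations can lack a walk-reachable solution), whereas the
walk-carried semantics always terminates and is reproduced exactly by the
brute-force reference implementation.

### Two implementations, one semantics

`flood_by_definition()` is the reference: it re-checks the essentialness
predicate in full on every candidate walk, sorts every breadth-first level
explicitly, and keeps its state in plain scanned tables. `flood_network()`
is the scalable worklist: incremental one-step essentialness checks (only
the appended node's previous appearance can violate the predicate, because
the parent walk is already essential), capacity/flood matrices, and
construction-order frontiers. The two share the semantics above and nothing
else; the test suite and the acceptance script verify edge-for-edge
agreement on hundreds of seeded random networks with cycles, fan-outs and
negative fractions up to 0.6.

## From GRN to flood network and back

Phase one (`transform_grn()`) rewrites the GRN:

* each gene $v$ becomes a **saturation gadget** — nodes $v_{in}, v_{out}$
  joined by an edge of positive capacity equal to the gene's saturation —
  capping the total flood the gene can pass on, the network analogue of a
  maximal expression level;
* each regulatory edge $(u, v, w)$ becomes $(u_{out}, v_{in})$ with
  capacity $w$ — the only wiring under which the gadget actually limits a
  gene's downstream influence;
* each active signal becomes a source node linked to its receptors' gate
  *outputs* with the signal regulation weights; inactive signals contribute
  nothing;
* one always-active **basal node** (created even when unused, keeping node
  arithmetic stable) feeds each gene's basal expression level, likewise at
  the gate output.

Attaching external inputs at the gate output means signal and basal input
bypass the receptor's own saturation gadget; the receptor's activity is
then read as its largest direct inflow. The alternative convention —
routing external input through the gadget so that it, too, is
saturation-capped — is a defensible reading, and is available as the
scenario switch `signals_to_gate_in`; the default follows the gadget
construction exactly as stated above. This is the one place where the
transformation is genuinely ambiguous, and the switch exists so users can
test both readings instead of trusting ours.

Phase three reverses the mapping (`reverse_transform()`): gadget pairs
collapse to genes, gene-gene edges inherit the flood of their gate-to-gate
counterpart, the gadget flood becomes the gene's node flood, and direct
signal/basal inflows are reported as per-gene annotations. Between the two
phases sit `apply_threshold()` — strictly retain $|f(u,v)| > t$ — and, when
sinks are given, `prune_to_sinks()` — retain exactly the edges on some
directed source-to-sink path, computed as forward-reachability from the
sources intersected with backward-reachability from the sinks. Threshold
first, then connectivity pruning on the survivors. `minimize_grn()` chains
all stages.

Minimization at $t_2 > t_1$ retains a subset of the edges retained at
$t_1$ (asserted over threshold sweeps on random networks), and the
minimized network is always contained in the *reachable sub-network* — the
genes forward-reachable from the active inputs by directionality alone
(`reachable_subnetwork()`), which also serves as the denominator for
reduction percentages. Re-minimizing an inhibition-free minimized network
returns it unchanged; with inhibition this need not hold, because removing
a suppressed inhibitor can raise floods downstream, so idempotence is
asserted only where it is provable.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `threshold` | 0 | Minimum surviving flood magnitude $t$ (strict). 0 keeps every active edge. |
| `default_saturation` | 10 | Gadget capacity for genes without their own; in units of regulatory weight. Large against unit-scale weights, so saturation binds only when set deliberately. |
| `unit_weights` | `FALSE` | Replace weights by ±1 — the convention when a reconstruction provides topology and sign but no strengths. |
| `noise_sd` | 0 | SD of Gaussian weight noise (applied after unit replacement); a perturbed weight may not cross zero — noise must not turn an activator into a repressor — so it is clamped at `sign(w) * zero_tol`. |
| `zero_tol` | $10^{-12}$ | Magnitude below which a flood change counts as zero. |
| `max_walks` | $10^6$ | Resource guard; traversal aborts with a distinct error class beyond it (worst-case walk growth is exponential). |
| `seed` | 0 | Governs every stochastic step of a scenario. |

## The synthetic generator

`generate_random_grn()` emulates the role of an evolved or reconstructed
benchmark network: a spanning arborescence rooted at the signals' receptor
genes guarantees that every gene is reachable from an input; random extra
edges bring the network to the requested density; `cycle_bias` adds
feedback edges from genes to their arborescence ancestors, guaranteeing
directed cycles; weight magnitudes are uniform on `weight_range`
(default 0.5–3), inhibitory with probability `negative_fraction`. Signal
weights are positive — an active stimulus feeds its receptors.

What it does *not* emulate: degree distributions of real transcriptional
networks (no hubs beyond what density produces), autoregulation (self-loops
never carry flood under the essential-walk rule, so generating them would
only add dead weight), correlated weights, or any evolutionary structure.
Passing tests on these networks therefore demonstrates the correctness and
robustness of the calculus, not biological realism of any particular
network instance.

`example_grn()` is a hand-built six-gene network whose capacities were
chosen (and are locked by tests) so that every qualitative behaviour of the
method appears in miniature: flood replication onto two high-capacity
branches, an inhibitory edge carrying far less than its capacity because
its upstream inflow is small, a near-cancellation leaving a weak positive
flood that survives only a low threshold, and a feedback branch silenced
outright, disconnecting two genes from the sink at every threshold.

`remove_random_links()` and `perturb_weights()` support the missing-data
and weight-noise robustness experiments (`sensitivity_experiment()`):
uniform link removal before minimization, and multiplicative weight
perturbation $w \mapsto w(1+u)$, $u \sim U(-m, m)$, which preserves signs
by construction. Sensitivity is measured against the full-data minimized
network as ground truth — the only truth available when no generative
model of the "correct" sub-network exists.

## Evaluation choices

Reporter enrichment uses the upper-tail hypergeometric probability
$P(X \ge k)$ with population $N$ (reachable genes), $K$ reporters, $n$
retained genes, $k$ reporters retained: the question is whether
minimization retains reporters *more* than chance. Multiple-testing
correction is Bonferroni, $\min(1, p \cdot n_\text{tests})$, with the
family size an explicit argument — the natural family (thresholds?
scenarios?) depends on the user's experiment and is not guessed. The
implementation is `stats::phyper`; the test suite validates it against
exhaustive enumeration of all $\binom{N}{n}$ retained sets for every
$N \le 12$.

"Total flood" of a network is reported as $\sum |f(u,v)|$ over retained
gene-gene edges. This convention (absolute values, gene-gene edges only) is
the package's own and outputs label it as such.

## Numerical and degenerate-input choices

* Thresholding is strict (`|f| > t`), so `t = 0` drops exactly zero-flood
  edges.
* Duplicate (source, target) edges are rejected, not summed: capacity is
  indexed by node pair.
* Zero weights are rejected at parse time — zero capacity is definitionally
  the absence of an edge.
* Gene ids are opaque, case-sensitive strings; ids containing `::` or
  starting with `@` are rejected at transform time because the transformed
  network uses those markers internally.
* An empty network, a network whose sources have no outgoing edges, and a
  threshold above the maximum flood all yield empty-but-well-formed
  results; an unreachable sink set yields an empty network with a warning
  rather than an error.
* All random draws (generator, noise, link removal) happen in canonical
  edge order under `withr::with_seed`, so results are reproducible and
  independent of input ordering.

## Problem sizes used by the automated checks

The test suite and the acceptance script exercise: oracle-vs-worklist
agreement on 200 random networks of up to 8 genes (negative fractions 0,
0.3, 0.6; cycle bias 0.4); threshold monotonicity on 50 such networks with
20-point sweeps; determinism across 10 edge-order permutations;
hypergeometric enumeration up to $N = 12$; and a flooding-time scaling
profile on generated networks of 10–200 genes at edge density 0.1, where
the slope of log-time against network size decreases as networks grow.
These sizes keep the whole suite in well under a minute of compute while
covering every code path; the calculus itself handles networks of a few
thousand genes in seconds to minutes depending on cycle content.

## Known limitations

* Only the linear sum/min/max flood kernel is implemented (behind a single
  dispatch point); sigmoidal or polynomial response kernels would be a
  natural extension.
* Signals are binary active/inactive; graded signal strengths must be
  encoded in the signal weights.
* Self-loops never carry flood — a direct consequence of the essential-walk
  predicate, so autoregulation is invisible to the method.
* Floods in cyclic networks are history-dependent (see above); the
  canonical order makes them reproducible, but they are not the solution of
  an order-free equation system.
* Worst-case traversal cost remains exponential; `max_walks` turns
  pathological cases into a clean error instead of a hang.
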