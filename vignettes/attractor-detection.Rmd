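---
title: "Attractor detection by exhaustive enumeration of pruned state-space subspaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attractor detection by exhaustive enumeration of pruned state-space subspaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boolattract)
```

## The model

A Boolean regulatory network is a directed graph whose nodes (genes,
proteins, complexes) carry a binary activity value and whose edges are
signed: activating (`A -> B`) or inhibiting (`C -| D`). The dynamics are
given per node by a *logical function* in the Thomas parameterization: for
a node with $k$ inputs there are $2^k$ input patterns, and for each pattern
a logical parameter $K$ gives the *image* — the value the node tends to
under that input. A node whose current value equals its image is
**content**; otherwise it is **discontent**, and updating it switches its
value. A state in which every node is content is a **fixed state**.

Updating is *general asynchronous*: one discontent node changes per
transition, so a $k$-discontent state has exactly $k$ successors.
Attractors are the fixed states and the **stable cycles** — sets of two or
more states, closed under the successor relation, out of which the system
cannot escape. Synchronous schemes are deliberately not offered: updating
all discontent nodes at once can create artifacts that have no counterpart
in the underlying biology, where reactions fire one at a time in
unpredictable order.

Instead of committing to one concrete truth table per node, the package
fixes only two *boundary* parameters per node: under optimal conditions
(all activators present, all inhibitors absent) the image is the maximal
value, and under the opposite conditions it is 0. These are the minimal
assumptions under which every node can in principle switch. All other
parameters may be left FREE (`free_table()`), set by the widely used
inhibitor-dominant convention (`default_table()`), drawn at random
(`random_table()`), or supplied as a TSV (`read_table_tsv()`).

## Fixed-state search by incremental build-up

Enumerating all $2^n$ states is hopeless beyond ~30 nodes. The search
instead grows a *partial state matrix*: start from all value combinations
of an initial group of `k0` nodes (default 10, the highest out-degree
nodes), then repeatedly add one node — duplicating the matrix and appending
a column — and evaluate every node whose inputs are now all present.
A row in which an evaluable node is discontent cannot extend to a fixed
state, and removing it removes all $2^{n-(k+1)}$ of its extensions at once.
Node-addition order prefers nodes whose inputs are already included (ties:
highest out-degree, then declaration order), because those can be evaluated
— and prune — immediately. When all nodes are in, the surviving rows are
exactly the fixed states.

```{r fig-example}
net <- parse_network(c("2 -> 1", "1 -> 3", "2 -| 3", "3 -| 2"))
find_fixed_states(net, free_table(net))
```

Under a FREE parameter a row is kept whenever *some* parameter choice makes
the node content, and that choice — `node @ pattern = value` — is recorded
on the row. The result therefore covers all fixed states of *every*
completion of the table, each annotated with the parameter conditions that
realize it (useful for reverse engineering logical functions from observed
stable states). Within one row at most one constraint per node can arise (a
row fixes a single input pattern per node), so no satisfiability machinery
is needed; consistency of constraints *across* different fixed states is
deliberately not enforced — conditions are read per state.

## Cycle detection in the k-discontent subspace

Every member of a cycle is at least 1-discontent, so fixed-state pruning
cannot find cycles. Relaxing it to tolerate up to `kmax` discontent nodes
per row (a node's content status is final once its inputs are included, so
the count only grows — pruning stays exact) enumerates the subspace that
provably contains every $j$-cycle with $j \le k_{max}$. The analysis then:

1. builds the asynchronous transition graph restricted to the subspace,
   flagging as *boundary* any state with a successor escaping the set;
2. computes each fixed state's basin by walking predecessors uphill;
3. searches the remaining unlabeled, non-boundary states for **closed**
   strongly connected components: member sets none of whose successors
   leave the set. Those are the stable cycles; each is classified by
   $k = $ the maximal member discontent count (`simple` iff $k = 1$ — every
   member has exactly one successor; `mixed` otherwise).

```{r toggle}
toggle <- parse_network(c("A -> B", "B -| A"))
run_cycle_analysis(toggle, default_table(toggle), kmax = 1)
```

Two design points were genuinely open and are resolved as follows.
*Boundary semantics*: a state with **any** escaping successor is barred
from attractor membership — closure cannot be certified for it — but is
retained as a basin member; reading "states flowing outside" as requiring
*all* successors to escape would break the closure contract. *Traversal*:
cycle discovery is implemented as strongly-connected-component computation
with a closure filter rather than the seed-cycle enlargement walk; both
compute the maximal closed strongly connected member sets, and equivalence
with a brute-force terminal-SCC oracle over the full state graph is the
tested contract. Basins are reverse-reachability sets ("weak" basins), so
a state may belong to several basins; basin sizes are counted within the
enumerated subspace, which equals the full-space basin only at
$k_{max} = n$.

`kmax` trades completeness for memory: cycles with members outside the
enumerated subspace are not seen. Highly ordered cycles (low $k$) are the
ones most plausibly relevant in biological networks — a stable cycle
containing an even moderately discontent member must absorb all of that
member's successor branches, which makes such cycles rare — so the default
is `kmax = 1`.

## Benchmark generator and the discontent-count distribution

`random_network()` emulates the structural envelope of curated regulatory
networks used for benchmarking: `round(edge_ratio * n)` edges with
`edge_ratio = 2.5` (the 2–3 range typical of signalling maps), in-degree
capped at 6 (regulation by more than a handful of direct inputs is rare),
every node with nonzero in- and out-degree, and no simple mediator nodes
(one edge in, one out), since those can be collapsed without affecting
attractors. Construction places a random permutation round first (one
in/out edge per node), spends extra edges on still-mediator nodes, then
uniformly at random; signs are independent fair draws, and whole attempts
violating any constraint are rejected. Given a seed the generator is fully
deterministic, and it restores the caller's RNG state.

What the generator does *not* emulate: scale-free degree tails, motif
enrichment, autoregulation bias, or empirically fitted sign ratios. Tests
passing on these networks show algorithmic correctness on
degree-constrained uniform topologies, not biological fidelity of any
particular inference.

`estimate_discontent_fraction()` samples states uniformly and reports the
fraction with at most `kmax` discontent nodes, i.e. the relative size of
the subspace a cycle search would enumerate. For a random table each node
is discontent with marginal probability 1/2, so the count is approximately
$\mathrm{Bin}(n, 1/2)$; for $n = 30$, $k_{max} = 10$ the tail is ≈ 4.9%,
and sampled values for single generated networks spread a few points
around it — the quantity is network-specific.

## Numerical and representation choices

* **Pattern indexing.** A node's inputs are ordered by network node order
  (declaration order); a pattern is indexed in mixed radix with the first
  input least significant. Constraint read-outs display the Thomas
  positive-influence notation (`K_3{1}`: inputs listed iff activator
  present or inhibitor absent) alongside the machine form `node@bits=v`.
* **State keys.** Node $i$ contributes $v_i \prod_{j<i} m_j$; keys are
  doubles, exact far beyond the sizes the cycle search can hold.
* **Determinism.** No randomness anywhere in parsing, ordering, pruning or
  traversal; all ties break by node order. Identical inputs give
  byte-identical outputs.
* **Memory guard.** `row_limit` (default 5e7 rows) aborts the build-up
  with a typed error carrying the per-iteration trace; the CLI maps it to
  exit status 3.
* **Degenerate inputs.** Zero-in-degree nodes are rejected unless declared
  frozen external inputs with a fixed value (they are then permanently
  content). The inhibitor-dominant convention for a node with no
  activators maps "no inhibitor present" to the maximal value — the
  optimal-boundary invariant takes precedence over the literal
  "at least one activator present" reading, which would otherwise
  contradict it.
* **Multi-valued nodes.** Tables, boundary constraints (image = max level
  / 0) and matrix expansion (m replicates per added node) support nodes
  with more than two levels for the fixed-state search; a discontent
  multi-valued node steps one level toward its image. Cycle search is
  binary-only.

## Verification strategy and problem sizes

The reference implementation `brute_force_attractors()` enumerates the full
state space and takes terminal strongly connected components — an
independent route kept deliberately separate from the build-up search.
The suite checks, among others: exact reproduction of the two worked
examples above; fixed-state and full-attractor agreement with the oracle on
200 random benchmark networks of 5–12 nodes; monotonicity of the attractor
set in `kmax`; independent closure re-checks of every reported cycle;
soundness of free-table results under sampled completions; peak-row
reduction on 25-node networks (always below $2^{25}$, median ratio under
1%); a 60-node fixed-state search with peak row count under $10^7$; and
generator compliance over 100 seeds at 20–50 nodes. These sizes were chosen
so the whole suite runs in about a minute while still exercising every
contract at meaningful scale.

## Limitations

Memory growth with `kmax` is the binding constraint, as in any exact
subspace enumeration: each added tolerated discontent level multiplies the
enumerated set. Cycles extending beyond the enumerated subspace are
invisible at the chosen `kmax`. No network reduction preprocessing is
applied — pairing the search with a reduction method is the natural route
to larger networks. Basin sizes at `kmax < n` undercount the true basin.
Multi-valued cycle search and arbitrary Boolean formula input (AND/OR/NOT
expressions) are out of scope; only the pattern-table parameterization is
supported.
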