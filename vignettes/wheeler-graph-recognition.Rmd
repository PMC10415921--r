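---
title: "Recognizing, generating and indexing Wheeler graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recognizing, generating and indexing Wheeler graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wgt)
```

## The problem

An edge-labeled directed graph $G = (N, E)$ with labels from an alphabet
$\Sigma$ is a *Wheeler graph* if its nodes admit a total order $<$ such
that

1. every node with indegree 0 comes before every node with positive
   indegree,
2. for every pair of edges $(u, v)$ labeled $a$ and $(u', v')$ labeled
   $a'$ with $a \prec a'$: $v < v'$, and
3. for every pair of same-labeled edges: $u < u' \Rightarrow v \le v'$.

Wheeler graphs generalize the Burrows–Wheeler transform: the order is the
co-lexicographic order of the string sets spelled into each node, and a
graph with the property can be stored and queried through three succinct
arrays (`O`, `I`, `L`). They matter in genomics because several
pangenome-graph indexes are built on exactly this structure. Deciding
whether an arbitrary graph has the property is NP-complete, and hard
already for modest graphs if attacked naively: the permutation space is
$n!$, and the older enumeration alternative explores
$2^{2(n+e)+e\log_2\sigma}$ candidate array triples.

This package implements the Wheelie recognition strategy: an iterative
*renaming heuristic* that assigns every node a rough rank interval, plus
one of two exact solvers for whatever ambiguity remains. It also provides
ground-truth oracles, graph generators, the `O/I/L` index construction and
a two-row diagram in which a valid ordering shows zero same-color edge
crossings.

## The renaming heuristic

The heuristic first checks for an immediate conflict: a node with two
distinct incoming edge labels can never satisfy condition 2 (take
$v = v'$), so such a node proves the graph non-Wheeler outright.

Otherwise every node belongs to exactly one *block*: the roots (indegree
0) occupy ranks $1..r$, and the distinct destinations of each label, taken
in alphabet order, occupy consecutive rank blocks after them. This much is
forced by conditions 1 and 2. Within a block, the heuristic sorts nodes by
their *in-node list* — the sorted distinct temporary orders of their
predecessors — because condition 3 makes destination order follow source
order. Nodes with equal lists share a sub-range (a *tie group*); each pass
re-partitions every block, and iteration stops when the ranges stop
changing, when all ranges are singletons, or after $n$ passes (a hard cap;
the cap cannot change a verdict, only shift work to the solver). Updates
are applied block by block within a pass, so later blocks see the current
pass's refinements of earlier ones.

Two properties make the heuristic safe to combine with an exact solver:
its constraints are all *necessary* (a valid ordering can never place a
node outside its range — the test suite checks this exhaustively on small
graphs), and refinement only ever splits tie groups. A totally resolved
range is therefore the unique candidate ordering, and it is still verified
with `check_wheeler()` before any Wheeler verdict is reported.

In-node lists are compared lexicographically with shorter-prefix-first,
implemented as fixed-width numeric keys so the comparison is
locale-independent; ties between equal lists are broken by node identifier
only for determinism of the output, never for correctness (equal lists
always stay in one tie group).

## Exact solvers

**Wheelie-Pr** enumerates the Cartesian product of permutations within
each tie group, groups in rank order and permutations in lexicographic
order of node identifiers, so the reported witness is reproducible. Root
placement and label-block order are already fixed by the ranges, so only
condition 3 can fail; it is checked incrementally over the edges whose
endpoints are both determined, pruning a partial assignment as soon as a
violation appears. A full `check_wheeler()` at each leaf guards the
bookkeeping. With `exhaustive = TRUE` the search runs to completion (the
configuration used when benchmarking against the enumeration baseline) and
reports the first witness found, if any.

**Wheelie-SMT** encodes the residual problem over integer difference logic
(IDL): one integer variable per node, every atom of the form
$x_i - x_j \le c$, strict inequalities as $c = -1$. In *range mode* the
per-node bounds come from the heuristic; condition 2 clauses and
root-first clauses are implied by the ranges and omitted, and
all-different constraints are restricted to tie groups. In *pure mode*
(no heuristic) the formula carries the whole definition: ranges $1..n$,
root-first unit clauses, condition 2 unit clauses for every
distinct-label edge pair, condition 3 clauses
$(u' - u \le 0) \lor (v - v' \le 0)$ for every ordered same-label edge
pair, and pairwise all-different over all nodes. The root-first clauses
are part of the definition and are required for pure mode to agree with
the brute-force oracle (a graph with an isolated node and a single edge
would otherwise admit a spurious model that fails verification despite
the graph being Wheeler).

Any model is decoded into a rank bijection — ranges pin values across tie
groups and all-different pins them within — and re-verified with
`check_wheeler()` before a Wheeler verdict is reported, so an encoding or
solver defect can produce an error, never a wrong verdict. Unsatisfiable
means non-Wheeler (in range mode this additionally relies on the
necessity of the heuristic ranges). Formulas can be exported as SMT-LIB 2
(`write_smt2()`, logic `QF_IDL`) for cross-checking with any external
solver.

### The built-in IDL solver

The package ships its own complete IDL solver (C++), a DPLL(T) design
around a difference-constraint theory core:

* A feasible *potential function* (one integer per variable plus a fixed
  reference variable) is maintained at all times; asserting a constraint
  triggers incremental Bellman–Ford repair with queue deduplication.
* Negative cycles are detected incrementally: a newly asserted arc lies on
  a negative cycle exactly when the repair cascade it starts reaches the
  arc's tail again.
* Unit clauses are installed in bulk, deduplicated to the tightest bound
  per variable pair, followed by one global repair.
* Propagation probes every clause woken by a potential change: a clause
  with no theory-consistent literal is a conflict; one with exactly one
  forces that literal. Forced literals are implied, so this preserves the
  formula's models exactly.
* Decisions are made only on clauses the current model violates after
  propagation reaches a fixpoint; if none is violated the potentials are
  themselves a model. Within a violated clause, literals are tried
  smallest-slack first (preferring, for the Wheeler clauses, re-alignment
  of the destination pair — the direction in which the co-lexicographic
  order propagates). Backtracking is chronological.
* The starting assignment is any bijection; the encoder supplies one that
  already satisfies the unit families (roots first, destination blocks in
  label order; in range mode, the heuristic order), which leaves only
  genuine ordering decisions to the search.

The solver has no conflict-driven clause learning; on the constraint
systems this package produces, eager propagation makes the search
near-deterministic (satisfiable instances with ~1,500 nodes solve in
seconds even in pure mode), but adversarial IDL formulas could still force
exponential behavior — the `timeout` (default 30 s) converts that into an
explicit `timeout` verdict, distinct from `not_wheeler`.

## Ground truth and search-space arithmetic

`brute_force_recognize()` tries all $n!$ orderings (guarded at $n \le 9$)
with an independent re-implementation of the three conditions; it anchors
every solver-equivalence suite. `gt_enumeration()` reproduces the reduced
enumeration baseline over `O/I/L` candidates: it counts triples passing
cheap consistency screens (well-formed unary codes, a zero-indegree
prefix, per-label indegree block sums, within-source non-decreasing
labels) and deliberately omits the graph-isomorphism inner loop, so it
never decides Wheelerness — its verdict is always `unknown`. It exists to
ground the search-space comparison, not to recognize graphs.

`search_space_C(n)` returns the largest integer $C$ with
$2^{2n+C} \le n!$, computed exactly from the bit length of the exact
factorial (a small base-$2^{26}$ bignum; floating-point log-sums are used
only for display). Logarithms are base 2 throughout, which keeps the
identity $C = \sum_{x=1}^{n} \log_2 x - 2n$ and the comparison
$2^{2(n+e)+e\log_2\sigma}$ vs $n!$ mutually consistent; the floor matches
the convention that $C$ is the largest admissible integer (at $n = 100$
the sum is $\approx 324.77$, so $C = 324$).

## Generators and what they emulate

`random_msa()` draws independent uniform residues (optionally with
independent gaps) and is the synthetic stand-in for sequence collections
throughout the tests. Real multiple alignments differ in ways that matter
here: their rows are highly similar, which concentrates repeated
$(k-1)$-mers and changes how often sequence-derived graphs have the
Wheeler property. Passing tests therefore demonstrate that recognition,
indexing and the generator contracts work on this family — not that any
particular real alignment yields a Wheeler graph.

**Tries** insert gap-stripped rows character by character; node names are
breadth-first search orders. A trie always has a single root and one
in-edge per node, and is always a Wheeler 1-NFA.

**De Bruijn graphs** take one node per distinct $(k-1)$-mer and one
deduplicated edge per adjacent pair within a row. The default edge label
is the last character of the destination $(k-1)$-mer, under which every
node has single-label in-edges; the alternative `"first"` convention is
kept as an option but does not support a validity guarantee. An important
subtlety: the *sampled* De Bruijn graph of raw sequences is **not**
guaranteed to be a Wheeler graph. Conditions 2 and 3 always hold under
co-lexicographic node order for this construction, but condition 1 can
genuinely fail: a 0-indegree $(k-1)$-mer (a row's first window, never seen
as a destination) may be forced away from the front of every otherwise
consistent ordering. The smallest counterexamples are single short
sequences — the package's exhaustive oracle confirms them — and at
$n \sim 10^3$ a noticeable fraction of random-sequence graphs are
non-Wheeler. Setting `pad_start = TRUE` prefixes each row with $k-1$
sentinel characters `$` (which sort before all residues): the root is then
unique and co-lexicographically smallest, and the co-lex order is always a
valid Wheeler ordering. The validity and formula-size suites use the
padded variant for exactly this reason; the unpadded default preserves the
plain sampled construction for studying both outcomes.

**Pseudo-De Bruijn graphs** keep one node per $(k-1)$-mer *occurrence*
(per row and position), so each row is a chain and nothing merges; they
may or may not be Wheeler. **Reverse deterministic graphs** create one
node per distinct character per column and connect consecutive ungapped
characters within each row, labeling with the destination character —
small instances are often Wheeler, larger ones typically not.

**Complete Wheeler graphs** fix the ordering first: ranks $1..r$ are
roots, the rest split into per-label destination blocks of near-equal size
(remainders to alphabetically earlier labels). Per label, every source
emits one edge along a random monotone staircase over the block and each
of the $n_i - 1$ random breakpoint sources emits one extra edge, giving
exactly $n + n_i - 1$ label-$i$ edges and hence
$e_{\max} = n\sigma + n - \sigma - r$ in total. Maximality is relative to
the root count: an edge into an original root keeps the graph Wheeler but
reduces $r$ (and so raises the bound), which is why the completeness test
enumerates additions into non-root destinations; graphs generated with
$r = 0$ are maximal over all additions.

**Random Wheeler graphs** subsample the complete graph's edges, always
keeping each destination's first staircase in-edge — pure uniform
subsampling could orphan a mid-rank node and silently break condition 1.

**d-NFA Wheeler graphs** first solve for a per-label out-multiplicity
profile $x_k$ (number of sources with $k$ same-label out-edges) with all
$x_k$ equal and the residual added to $x_1$, subject to
$\sum_k k\,x_k = e_i$, the destination capacity
$1 + \sum_{k\ge2}(k-1)x_k \le n_i$ (consecutive sources can share at most
one destination), $e_i \ge n_i$ and $\sum_k x_k \le n$. Infeasible
parameter combinations are an error naming the violated inequality — with
$\sigma = 4$ blocks of ~250 nodes, $e = 3000$ admits only $d = 1$; higher
$d$ needs fewer edges (e.g. $e = 1600$ for $d = 4$ at $n = 1000$).
Multiplicities are assigned to shuffled source nodes, and the source slots
(rank order, repeated by multiplicity) are mapped onto the destination
block by a seeded random monotone surjection with strict increase within
one source's slots; the output is Wheeler by construction and attains $d$
exactly.

All generator randomness flows from a single integer seed through one RNG
stream per call, and identical parameters yield byte-identical DOT output.

## Defaults and numerical conventions

| Parameter | Default | Why |
|---|---|---|
| solver | `smt` | heuristic + IDL is the most robust combination |
| timeout | 30 s | converts pathological searches into explicit verdicts |
| De Bruijn label | `last` destination character | single-label in-edges; co-lex validity (with padding) |
| `pad_start` | `FALSE` | preserves the plain sampled construction |
| roots in random generators | $r = 1$ | a single source node, smallest feasible choice |
| block remainders | earlier labels | any deterministic rule works; this is the simplest |
| rank origin | 1-based | matches the range constraints $1 \le v \le n$ |
| label comparison | code point (byte order) | locale-independent; generalizes beyond DNA |

The `O`/`I` arrays use `'0'` per edge then a `'1'` terminator per node, in
rank order, so both have length $n + e$ with exactly $n$ ones; `L` sorts
edges by (source rank, label, destination rank). Duplicate identical edge
triples in DOT input are collapsed with a warning. Violation certificates
report the first offending pair under a deterministic scan (for large
invalid graphs the certificate comes from the structured check rather
than the quadratic pair scan, still deterministically).

## Problem sizes in the test suites

The bundled suites run at desk scale, chosen so the full battery completes
in a few minutes: exhaustive cross-solver agreement on 200 graphs with
$n \le 8$; generator validity on complete/random/d-NFA graphs up to
$n = 1000$, $e = 3000$, $\sigma = 4$, $d \le 4$ plus padded De Bruijn
graphs up to ~3,000 nodes; heuristic-versus-pure formula comparisons on
twenty ~500-node De Bruijn graphs; exact factorial arithmetic up to
$n = 200$; and edge-maximality verified exhaustively for $n \le 5$.

## Limitations

* The solver lacks clause learning; adversarial non-Wheeler graphs with
  large tie groups can exhaust the timeout (reported as `timeout`, never
  as a wrong verdict).
* `gt_enumeration()` reproduces the reduced baseline only; there is no
  full enumeration recognizer with the isomorphism inner loop.
* The visualizer draws the two-row diagram only, and requires an ordering
  (a witness from recognition, or an explicit `--order` file for
  non-Wheeler graphs).
* Succinct rank/select machinery over `O/I/L` and pattern matching on the
  index are out of scope; the arrays are produced as plain strings for
  downstream tools.
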