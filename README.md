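# wgt — Wheeler graph recognition, generation, indexing and visualization

A *Wheeler graph* is an edge-labeled directed graph whose nodes admit a
total order in which (1) 0-indegree nodes come first, (2) for every edge
pair `(u,v)` labeled `a` and `(u',v')` labeled `a'` with `a ≺ a'` the
destinations satisfy `v < v'`, and (3) same-labeled edges preserve the
source order weakly on destinations (`u < u' ⇒ v ≤ v'`). The order is the
co-lexicographic order of the strings spelled into each node, which is
what makes these graphs indexable with a Burrows–Wheeler-style structure
(`O`, `I`, `L` arrays) and relevant as pangenome-graph representations.
Deciding whether a graph has the property is NP-complete in general.

This package is for people who build or study such graphs: it decides
Wheelerness, produces a witness ordering and the succinct index when the
answer is yes and a violation certificate when it is no, generates
Wheeler and non-Wheeler test graphs, and draws the two-row diagram in
which a valid ordering shows zero same-color edge crossings.

The recognizer, *Wheelie*, combines an iterative **renaming heuristic**
(every node gets a rough rank interval from the labels of its in-edges
and the sorted orders of its predecessors; equal intervals form *tie
groups*) with an exact solver for the remaining ambiguity: either
exhaustive permutations within tie groups (`Wheelie-Pr`) or an integer
difference logic (IDL) constraint encoding — all atoms `x_i − x_j ≤ c` —
discharged by a built-in DPLL(T) solver (`Wheelie-SMT`). A pure
constraint mode without the heuristic and a brute-force `n!` oracle are
included for comparison and ground truth. Every Wheeler verdict is
re-verified against the definition before being reported.

## Worked example

Build a De Bruijn graph from four random DNA sequences (start-padded with
`$` sentinels, which guarantees the Wheeler property for this
construction), recognize it, and inspect the index:

```r
library(wgt)
m <- random_msa(4, 60, seed = 11)          # 4 random DNA rows, length 60
g <- gen_debruijn(m, k = 4, pad_start = TRUE)
g
#> Labeled digraph: n=69 nodes, e=161 edges, sigma=4 labels
#>   alphabet: A C G T
#>   $$$ -> $$C [C]
#>   $$C -> $CC [C]
#>   ...

res <- recognize(g)                        # default: Wheelie-SMT, 30 s timeout
res
#> Wheeler graph recognition
#>   verdict: wheeler
#>   solver: smt
#>   ordering: $$$=1 $$A=2 $AA=3 AAA=4 CAA=5 GAA=6 TAA=7 ACA=8 CCA=9 ...
#>   heuristic: 2 iterations, 69 tie groups (largest 1)
```

The witness ordering is the co-lexicographic order of the 3-mers: the
root `$$$` is first, then all nodes with incoming label `A`, and so on.
The attached index encodes outdegrees (`O`) and indegrees (`I`) in unary
and lists the edge labels in `O` order (`L`):

```r
substr(res$index$O, 1, 40)
#> "0010100100100100100100010001001000010001"
substr(res$index$L, 1, 40)
#> "ACACTCTACGTATAGTCGTGTACGTCGTATCGACGTAGTA"
count_same_label_crossings(g, res$ordering)
#> 0    # a valid Wheeler ordering never crosses same-label edges
```

Zero same-label crossings is exactly condition (3); `render_bipartite()`
writes the corresponding two-row SVG diagram. Without `pad_start` the
sampled De Bruijn graph of raw sequences is *not* guaranteed Wheeler —
`recognize()` then returns `not_wheeler` with a certificate such as

```
condition (c): same-label edges TAT->ATA and TCT->CTA [A]:
rank(TAT)=49 < rank(TCT)=55 but rank(ATA)=15 > rank(CTA)=2
```

Two analytic anchors of the search-space comparison between enumeration
and permutation approaches:

```r
e_max(7, 2, 1)        # max edges of a Wheeler graph, n=7, sigma=2, 1 root
#> 18
search_space_C(100)   # largest C with 2^(200+C) <= 100!  (exact bignum)
#> 324
```

## Command line

A thin launcher is installed at `inst/scripts/wgt`:

```sh
wgt recognize -s smt graph.dot            # exit 0 wheeler / 1 not / 2 timeout
wgt generate dnfa -n 1000 -e 1600 -s 4 -d 4 --seed 7 -o g.dot
wgt generate debruijn -f msa.fasta -k 5 -l 200 -a 6 -o g.dot
wgt visualize --order order.tsv -o g.svg g.dot
wgt spacecmp -n 100 -e 100 -s 4
```

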