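---
title: "Finite dimension and Glycan Space: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finite dimension and Glycan Space: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycodim)
```

## The metric

A glycan, stripped of every chemical annotation, is a finite, simple,
undirected, connected graph: vertices are monosaccharide residues, edges are
glycosidic bonds. All edges are taken to have length one — real 1–6
linkages are roughly 1.5 times longer than the other bonds, but ignoring
the difference is what makes the computation tractable, because with the
unit-hop metric the covering quantity in the dimension formula becomes a
classical graph parameter. The **finite dimension** of the graph
$\Gamma$ is

$$\dim_f(\Gamma) \;=\; \frac{\ln N}{\ln D},$$

where $N = \vartheta(\Gamma)$ is the *clique cover number* — the smallest
number of cliques (vertex sets of diameter 1) whose union is $V(\Gamma)$ —
and $D$ is the diameter in hops. It is an adaptation of the Hausdorff
"fractal" dimension to finite metric spaces: $N$ counts the diameter-1
balls needed to cover the space of size $D$. Three states are possible:

* **zero** — the single-vertex graph only ($N = 1$, $D = 0$);
* **infinite** — complete graphs on $\ge 2$ vertices ($D \le 1$);
* **finite** — everything else, with a positive real value.

Isomorphic graphs receive equal dimension, because both $N$ and $D$ are
isomorphism invariants.

## Computing the clique cover number

`clique_cover_number()` dispatches on structure, each route strictly
cheaper than the next one down, and the route taken is recorded in the
result:

1. **single vertex** and **complete graphs**: $N = 1$ by inspection;
2. **trees**: trees are perfect graphs, and on perfect graphs the clique
   cover number equals the independence number $\alpha$ (Lovász), so a
   linear-time two-state dynamic program (include/exclude each vertex,
   children before parents) computes $N = \alpha$; this is implemented in
   C++ because simulated glycogen molecules reach $10^5$ vertices;
3. **triangle-free graphs** (all glycan cycles except triangles): every
   clique is an edge or a singleton, so an optimal cover keeps a maximum
   matching $\nu$ and covers the rest by singletons: $N = n - \nu$.
   Triangle-free graphs need not be bipartite (odd cycles), so $\nu$ is
   computed with Edmonds' blossom algorithm, implemented here in the
   array-based $O(V^3)$ formulation and tested against a brute-force
   matching oracle;
4. **everything else**: exact branch-and-bound minimum clique partition.
   Vertices are ordered with a maximal independent set first (its members
   force distinct cliques, giving an immediate lower bound); each vertex is
   placed into every compatible open clique or a new one, pruning at the
   size of the best complete cover found. The route is exact and refuses
   graphs larger than `exact_cap` (default 64 vertices) with an error
   rather than an approximation — in glycan data the graphs that reach
   this route are tiny, and correctness is preferred over cleverness.

Perfection is deliberately *not* tested: a perfect graph containing a
triangle simply goes through the exact route.

Useful identities covered by the test suite: on trees
$\alpha = n - \nu$ (König/Gallai), and every finite result satisfies
$\lceil (D+1)/2 \rceil \le N \le n - 1$ — the lower bound because a
diametral path of $D + 1$ vertices meets each clique at most twice.

## Equality and grouping of dimension values

Two finite dimensions are equal iff $\ln N_1 \ln D_2 = \ln N_2 \ln D_1$;
`dims_equal()` evaluates this cross-product form to $10^{-9}$, avoiding
the division. For *grouping* (histograms, search buckets, exclusivity) a
tolerance is not transitive, so an exact canonical key is used instead:
write $N = a^p$ and $D = b^q$ with minimal bases; if $a = b$ the value is
the rational $p/q$, keyed by the reduced fraction (so $(4, 8)$ and
$(9, 27)$ share the key $2/3$); otherwise the key is
$(a, b, p/g, q/g)$ with $g = \gcd(p, q)$. For the integer ranges arising
from graphs the two notions agree, and the key is stable.

Reported tables print dimension values to 5 decimals; all comparisons are
made on the exact $(N, D)$ pair, never on the printed value.

## Glycan Space

`encode()` maps a graph to the point $(\dim_f, D)$. Codes with zero or
infinite dimension (the single vertex, single edges, triangles, complete
graphs) are excluded from point exports and histograms, with the excluded
count reported.

Supporting machinery, each an elementary consequence of the cover bounds:

* `triangle_free_LD(D)`: the leftmost attainable dimension on the
  horizontal line at diameter $D$, for triangle-free graphs, is the code
  of the path $P_{D+1}$: $\ln\lceil (D+1)/2 \rceil / \ln D$. With
  triangles allowed (and $D \ge 3$) the left endpoint is the constant
  $\ln 2/\ln 3 \approx 0.6309$.
* `ramified_lower_threshold(b)`: for a *branched* tree, $D + 2 \le n$ and
  $n \le 2N$, so $D + 2 > 2D^b$ forces $\dim_f > b$. The gap function
  $D + 2 - 2D^b$ has a single interior minimum at $D^* = (2b)^{1/(1-b)}$;
  the function checks the sign at $D^*$ and otherwise scans upward from
  $\lceil D^* \rceil$ for the first (hence permanent) sign change. The
  scan is capped at $10^7$: thresholds of practical interest are small
  (20 at $b = 0.8$; 1004 at $b = 0.9$).
* `max_nodes_at(D, a)`: from $N \le n - 1$, any graph of diameter $D$
  with $n - 1 < D^a$ has $\dim_f < a$; the function returns the largest
  such $n$ (32 at $D = 10$, $a = 1.5$).
* `realizable_necessary(N, D)`: the diametral-path bound
  $N \ge \lceil (D+1)/2 \rceil$ is necessary for a lattice point to be the
  code of any graph — it rejects $(2, 10)$, for instance. It is not
  sufficient, and no attempt is made to characterise realizable points
  fully.
* `universal_bounds()`: with $a, b$ the extreme finite dimensions of a
  dataset, every member satisfies $D^a \le N \le D^b$. The check is done
  in log space ($a \ln D \le \ln N \le b \ln D$, slack $10^{-9}$) because
  for glycogen-sized graphs $D^b$ loses precision in the power form.

The right endpoint of a $D$-line deserves a note: over *all* graphs it
does not exist — the friendship graphs (t triangles sharing a hub) have
diameter 2 and dimension $\ln t/\ln 2$, unbounded in $t$ — while over
*chemical* graphs (degree $\le 4$) it is finite for each $D$. The test
suite demonstrates the first on $t \le 8$ through the exact-cover route
and the second by exhaustive enumeration of all connected degree-$\le 4$
diameter-2 graphs on up to 6 vertices (2^15 edge subsets; the sizes are
chosen so the enumeration stays a property test, and 6 vertices already
include the degree-4 star that attains dimension 2).

### Histogram binning

`histogram2d()` defaults to exact-code cells: the data this mirrors is
concentrated on few distinct codes per diameter, so exact grouping loses
nothing. Uniform binning (`mode = "uniform"`) exists for large simulated
cohorts where the codes are all distinct. The choice of exact cells as
default is this package's, made because the equality structure of codes is
exact by construction.

## The glycogen simulator

`simulate_glycogen()` emulates a glycogen molecule as a caterpillar-like
tree: a long spine path from which short pendant paths sprout at roughly
regular intervals. Defaults (all uniform over inclusive integer ranges —
the data only pins the ranges, so the least-informative choice is
uniform):

| parameter | default | unit |
|---|---|---|
| spine length | 1,900–70,900 | nodes |
| branch length | 20–23 | nodes |
| sprout gap | 12–19 | spine nodes |
| node cap | 120,000 | nodes |

Construction: draw the spine length; walk the spine accumulating gap
draws, attaching one branch per attachment point; a branch that would
exceed the node cap is dropped *whole* (never truncated mid-branch), along
with all later ones. The result is always a tree with maximum degree 3,
hence a triangle-free chemical graph whose dimension the tree route
computes in linear time. Diameter grows with the spine:
$D \ge \text{spine} - 1$.

Deliberate simplifications, to keep the generator a structural emulation
rather than a biophysical model: branches do not themselves branch
(real glycogen is multi-tier), there is no $\alpha$-1,4/$\alpha$-1,6
chemistry, and branch placement is memoryless. Consequently cohort
quantile summaries are *not* expected to reproduce any particular
laboratory or database figures beyond their overall envelope; what the
cohort tests do show is the structural signature — dimensions
concentrated near 1 (long path, sparse short ramifications), means in
$(0.95, 1.10)$ — and that signature is stable under the seed.

Reproducibility: `simulate_cohort()` derives one sub-seed per molecule by
drawing `sample.int(2^31 - 1, count)` under the cohort seed, so cohorts
are reproducible and molecules independent; the global RNG state is
restored afterwards.

## Tree canonicalization and database search

`canonical_code()` computes the AHU (Aho–Hopcroft–Ullman) canonical string
of a tree rooted at its center: each vertex's form is the parenthesized
concatenation of its children's forms, children sorted by subtree size
then form string; bicentral trees are rooted at both centers and the
lexicographically smaller form kept. Equal forms $\iff$ isomorphic trees,
which the suite checks against a brute-force permutation oracle on small
trees. With `use_labels = TRUE` the vertex's label token is placed inside
its parentheses, giving label-respecting isomorphism. Edge labels are out
of scope — linkage detail is stripped before any graph enters the
package.

Graphs that are not trees (a fraction of a percent of glycan data) get a
`NONTREE` sentinel and are compared by exact VF2 isomorphism instead; at
glycan sizes this is instantaneous.

`build_search_index()` + `db_lookup()` implement code-then-isomorphism
membership search: bucket by the exact Glycan Space code key, then match
canonical forms (trees) or run VF2 (non-trees), then — when labels are in
play — respect them in the final comparison. The early exit is
conservative and exact: a query whose code key is absent can never be in
the database. The index serializes to plain JSON.

## Taxonomy exclusivity

`partition_table()` cross-tabulates biological domain (Eukaryota,
Bacteria, Archaea) against structure (branched tree / linear / cyclic),
with margins; accessions categorized under more than one domain are
removed up front and counted. `dim_exclusivity()` compares two sets of
codes: a member of A is *exclusive* iff no member of B attains an equal
dimension — equality in the exact canonical-key sense above, a choice this
package makes explicitly since a rounded comparison would merge unequal
codes at coarse precision. Archaea are carried through the partition but
exclusivity is a two-set operation, applied to the branched
Bacteria-vs-Eukaryota comparison in the command-line `taxonomy` report.

## Problem sizes used by the test suite

All fixtures are generated in code. The brute-force oracles bound the
instance sizes: independence number by subset DP up to 14 vertices,
minimum clique cover by subset-sum DP up to 10, permutation isomorphism up
to 8, Prüfer enumeration of all $7^5$ labelled 7-vertex trees (11
unlabelled classes), and the degree-bounded exhaustive enumeration up to 6
vertices noted above. Cohort property tests use 100 molecules at the
default ranges and smaller spines (60–900 nodes) elsewhere; these sizes
are chosen to exercise every route while keeping the suite a few minutes
long.

## Known limitations

* The exact cover route is exponential in the worst case; `exact_cap`
  exists so a pathological input fails loudly instead of silently melting
  the session. No approximation is offered by design.
* Lovász theta / semidefinite programming is not implemented; it is not
  needed on the graph classes handled here.
* `dims_equal()`'s $10^{-9}$ tolerance and the canonical key can in
  principle disagree on adversarial non-graph inputs (astronomically
  close but unequal log-ratios); on integer pairs from real graphs they
  coincide.
* AHU string building is quadratic in depth for path-like trees; for
  database-scale trees (hundreds of vertices) this is irrelevant, but
  canonicalizing a $10^5$-node simulated molecule is not recommended.
* The simulator makes no claim of biophysical realism; see above.
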