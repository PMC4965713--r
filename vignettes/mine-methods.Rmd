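---
title: "Detecting protein complexes from multi-relationship interaction networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting protein complexes from multi-relationship interaction networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mineppi)
```

## The problem

Protein complexes are molecular machines assembled from physically
interacting proteins, and in a protein–protein interaction (PPI) network
they appear as dense subgraphs. Detecting them computationally from
high-throughput interaction data is hampered by the substantial false
positive and false negative rates of those experiments. `mineppi`
addresses this by refusing to treat the PPI network as the only source of
evidence: it combines interaction topology with Gene Ontology (GO)
annotation in a *multi-relationship* network, where one protein pair may
carry up to four typed parallel edges, and then mines each relation
separately for cohesive, well-separated subgraphs.

## The multi-relationship network

Starting from a cleaned PPI graph $G = (V, E)$ (self-interactions and
duplicate records removed by the loader), the package builds a typed,
weighted edge set over the same protein universe:

**Physical interactions** are weighted by the edge clustering coefficient

$$\mathrm{ECC}(v_i, v_j) = \frac{|N_i \cap N_j|^2}{(|N_i| - 1)(|N_j| - 1)},$$

where $N_i$ is the PPI neighborhood of $v_i$ (the interaction partner
included), and ECC is defined as 0 when either endpoint has degree 1. An
interaction supported by no common neighbor has ECC 0 and is removed: an
edge whose endpoints share no third partner is the topological signature
of a spurious interaction.

**Annotation-sharing edges** are generated per GO aspect — biological
process (BP), molecular function (MF), cellular component (CC) — with
weight

$$W(v_i, v_j) = \frac{|T_i \cap T_j|^2}{|T_i| \cdot |T_j|},$$

where $T_i$ is the protein's term set in that aspect (0 if either set is
empty). Because these edges are newly generated rather than observed,
they are filtered more stringently: a pair receives a share-edge only if
it has **at least two** common terms in the aspect *and* at least one
common neighbor in the original PPI graph. Both conditions follow the
construction's intent — a single shared term (often a broad one) is weak
evidence, and the common-neighbor requirement anchors generated edges to
the physical network. Two readings of "only one common function" were
possible (≤ 1 versus = 1); the implementation takes the literal
set-size reading, requiring $|T_i \cap T_j| \ge 2$.

Three choices deserve a note:

* The common-neighbor condition is evaluated on the *original* PPI graph,
  before the ECC filter, because the ECC filter is described for the
  physical relation only.
* Share-edges do not require a physical interaction between the pair;
  candidate pairs are enumerated as pairs with a common PPI neighbor
  (two-hop pairs), which the filter makes exhaustive without scanning all
  $O(|V|^2)$ pairs.
* GO terms are compared exactly as annotated, with no propagation to
  ancestor terms; ontology parsing is deliberately out of scope, and
  propagation would inflate "common function" counts with uninformative
  high-level terms.

The multi-relationship network is then decomposed into four
single-relation weighted networks — PPIN, BPN, MFN, CCN — a lossless
partition by edge type. Different relation types are mined separately
rather than collapsed into one score, because interactions of different
natures are not commensurable as evidence for the same complex.

## The detection procedure

Two quantities drive detection. The **weighted density** of a subgraph
with edges $e_1 \dots e_m$,

$$\mathrm{WD} = \frac{2 \sum_i w(e_i)}{\max_i w(e_i) \cdot |V|(|V|-1)},$$

measures cohesion relative to the subgraph's own heaviest edge (the
maximum is taken over the subgraph's edges, not the whole network; the
alternative global-maximum reading would make a candidate's density
depend on edges it does not contain). A single edge has WD 1; an
edgeless or singleton set is assigned WD 0. The **sub-network weighted
degree** $\mathrm{SWD}(u, S) = \sum_{v \in S,\, (u,v) \in E} w(u, v)$
measures how strongly $u$ couples to a vertex set $S$.

For each network in the fixed order PPIN, BPN, MFN, CCN, and for each
vertex as seed in lexicographic order:

1. **Growth.** The seed's neighbors are inserted one at a time into the
   candidate set CCS; any insertion that drops WD below the threshold WDT
   is undone. Insertion order is descending by edge weight to the seed,
   ties lexicographic — the natural greedy order, fixed so results are
   reproducible. Growth stays within the seed's neighborhood (one ring);
   since every vertex seeds its own candidate, recursive expansion would
   only duplicate work of neighboring seeds.
2. **Coupling pruning.** With NS the external neighbor set of CCS, every
   non-seed member $u$ with $\mathrm{SWD}(u, \mathrm{CCS} \setminus u) <
   \mathrm{SWD}(u, \mathrm{NS})$ is more strongly coupled outward than
   inward and is removed. The rule is iterated to a fixed point with NS
   recomputed each pass, because removals expose new boundary members.
   Ties retain the member; the seed is exempt, keeping each candidate
   anchored. `fig4_fixture()` reproduces the canonical worked example: a
   member with weight 0.2 into the candidate and 0.3 + 0.4 = 0.7 into the
   neighbor set is removed. Pruned members are not re-added by later
   steps.
3. **Subset screening.** A candidate no smaller than `min_size` enters
   the global complex set SC unless it is a subset of (or equal to) a
   complex already accepted. SC is shared across the four networks, so a
   BPN candidate contained in an earlier PPIN complex is suppressed.
4. **Redundancy filtering.** Seeds with similar neighborhoods produce
   near-duplicate candidates. After all networks are processed, any pair
   with matching score
   $\mathrm{MS}(A,B) = |A \cap B|^2 / (|A| \cdot |B|) \ge 0.8$
   loses one member: the smaller complex; at equal size the one with
   lower weighted density on its own source network; at equal density
   the lexicographically later member tuple. Size takes precedence
   because discarding the smaller of two redundant complexes preserves
   strictly more membership information. Pairs are processed in the
   deterministic output order (size descending, density descending,
   member tuple), which makes the filter a greedy keep-first scan.

The output is sorted by the same key. Every step iterates in sorted
order, so identical inputs give byte-identical outputs regardless of
hashing or file ordering.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `wdt` | 0.05 | weighted-density floor during growth (unitless, in $[0,1]$); detection quality on yeast data peaks at 0.05 — low values admit loosely connected neighbors, high values fragment complexes |
| `overlap_threshold` | 0.8 | matching-score level at (and above) which two predictions are redundant |
| `min_size` | 2 | smallest reported complex; 2 is the weakest meaningful value and no stronger floor is imposed |
| match threshold | 0.2 | MS level at which a prediction counts as matching a benchmark complex |

## Evaluation

Against a benchmark catalogue $B$, a prediction set $P$ is scored by
$N_{cp}$ (predictions matched at MS ≥ 0.2), $N_{cb}$ (benchmark
complexes matched), $N_{pcp}$ (perfect matches, MS = 1, i.e. set
equality), precision $N_{cp}/|P|$, recall $N_{cb}/|B|$, and their
harmonic mean (F-measure).

Functional coherence is scored per complex as the minimum, over all GO
terms annotating at least one member, of the hypergeometric upper-tail
probability of drawing at least $k$ term carriers in a complex of size
$n$ from a background of $N$ proteins containing $K$ carriers. The
background is the PPI protein universe — the self-contained choice, since
detection only ever sees those proteins. A complex is significant when
its minimal p-value is below 0.01 (strict), and the p-score is the mean
of $-\log_{10} p$ *over the significant complexes only* (the conditional
reading of the defining sum; dividing by all complexes instead would just
rescale by the significance proportion). P-values are raw by default, as
the conventional scoring prescribes; `enrichment_report(..., adjust =
"BH")` optionally applies Benjamini–Hochberg across complexes.

## The synthetic generator

`generate_synthetic()` emulates exactly the premises the method relies
on: complexes are Erdős–Rényi-dense subgraphs ($p_{in}$, default 0.95)
planted in a sparse background ($p_{out}$, default 0.01, plus 40
unassigned noise proteins), and complex members share annotation — two
fresh GO terms per aspect per complex given to all members, leaked to
outsiders at rate 0.05. Ten complexes of 4–8 proteins are planted by
default; a member left isolated by edge sampling is re-attached to its
complex so the ground truth stays inside the network. All randomness
flows from one seed in fixed call order, so a spec is a reproducible
fixture.

What the generator does *not* emulate: scale-free degree structure,
overlapping or core–attachment complex architecture, aspect-specific
annotation depth, or realistic GO term hierarchies. Passing recovery
tests on this generator therefore demonstrates correctness of the
machinery under the method's own assumptions, not performance on real
interactome data.

At the default study conditions the full pipeline recovers the planted
complexes essentially perfectly (recall ≥ 0.8 at MS ≥ 0.2 is asserted in
the test suite); the problem size (~80 proteins, ~170 interactions) keeps
the whole suite in the tens of seconds while still exercising all four
relation networks.

## Numerical and degenerate-input choices

* All arithmetic is double precision; file output rounds weights to six
  decimals, chosen so round-trips are stable.
* WD of a singleton, empty, or edgeless set is 0 ("cannot cohere"), which
  makes growth reject a disconnected neighbor at any WDT > 0.
* Thresholds compare with the conventions stated above: growth accepts at
  WD ≥ WDT; redundancy discards at MS ≥ 0.8; benchmark matching accepts
  at MS ≥ 0.2; significance requires p < 0.01. Boundary cases are pinned
  by tests.
* An empty PPI graph is an error; an empty relation network yields no
  candidates and is otherwise harmless.

## Limitations

The detector reports disjoint-ish (pairwise MS < 0.8) complexes and has
no notion of shared subunits between genuinely overlapping complexes, nor
of core–attachment structure. Enrichment p-values are computed from the
annotation table as given — no ontology propagation, no term filtering —
so they are comparable between runs of this package but not to tools that
propagate annotations. Protein identifiers are matched as exact strings;
cross-database identifier mapping is a preprocessing step for the user.
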