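---
title: "Detecting protein complexes and functional modules in dynamic PPI networks"
author: "dynppin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting protein complexes and functional modules in dynamic PPI networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynppin)
```

## The problem

A static protein–protein interaction (PPI) network aggregates interactions
that never co-occur in the cell: two proteins may both bind a common hub,
yet at different cell-cycle phases. Clustering such a network conflates two
biologically distinct objects:

* a **protein complex** — proteins binding each other *at the same time and
  place*;
* a **functional module** — proteins contributing to one process while
  assembling *at different times*.

`dynppin` separates the two. It first converts the static network plus a
time-course expression matrix into a *dynamic* network — an ordered series
of **time-sequenced subnetworks (TSNs)** — and detects complexes inside
individual TSNs. It then relates the detected complexes to each other in
time and membership, and groups them into functional modules on a
**complex–complex interaction network (CIN)**.

## Stage 1: the dynamic network

For each time point $t$, the active proteins are those whose expression
value is at least the activity threshold (default **0.7**, the usual choice
for scaled yeast time-course compendia); TSN$_t$ is the subgraph of the
static network induced on them.

Numerical choices:

* Activity uses `value >= threshold`. The boundary case (a value exactly at
  the threshold) is *kept*; a test pins this behaviour down.
* Missing measurements are never active — no imputation, which is the
  conservative reading of an expression filter.
* Proteins in the network but absent from the expression matrix are
  excluded from every TSN by default (`unmeasured = "inactive"`); a
  permissive `"active"` policy exists for networks much larger than the
  expression compendium.
* Degree-0 active proteins stay in the TSN. They are harmless to
  clustering and preserve the induced-subgraph semantics that the
  containment invariants (and their tests) rely on.
* One TSN per expression column; replicate collapsing, smoothing or
  periodicity detection are out of scope.

## Stage 2: complexes within a TSN

Each TSN is clustered by hierarchical agglomeration driven by the **edge
clustering value**

$$ECV(u,v) = \frac{\sum_{k \in I_{uv}} w(u,k)\,\cdot \sum_{k \in I_{uv}} w(v,k)}
                  {\sum_{s \in N_u} w(u,s)\,\cdot \sum_{t \in N_v} w(v,t)},
\qquad I_{uv} = N_u \cap N_v,$$

which is 1 on an edge completely surrounded by shared neighbours and 0 on
an edge with none. Vertices start as singletons; edges are processed in
non-increasing ECV order and merge the clusters of their endpoints. Two
rules control the agglomeration:

* **Positive evidence only.** Edges with $ECV = 0$ never merge: such an
  edge has no shared neighbourhood and is, by the method's own logic, not
  evidence of co-complex membership. This is also what keeps two dense
  regions joined by a single bridge apart.
* **λ-module locking.** A cluster $K$ is *locked* once
  $\sum_{v \in K} d^{in}_w(K,v) > \lambda \sum_{v \in K} d^{out}_w(K,v)$
  and $|K| \ge s$. A merge is rejected only when *both* clusters are
  locked. We considered the stricter rule (reject when *either* side is
  locked) and discarded it: it cannot keep a 5-clique together — once four
  of its vertices have merged they form a λ-module and the fifth would be
  orphaned — whereas the both-locked rule assembles any clique fully and
  still refuses to fuse two saturated complexes.

Ties in ECV are broken by the lexicographic order of the sorted endpoint
pair, so results are identical across platforms. After the queue empties,
every cluster with at least $s$ proteins is emitted. Defaults: $\lambda =
1.0$ (the recommended tightness) and $s = 3$ (the smallest complexes worth
reporting; exposed as `minSize`).

Complexes found in several TSNs are identical *as sets* only; the catalogue
collapses exact duplicates, records the TSN indices as the activity-time
set $T_C$, and defines the **frequency** $f_T(C) = |T_C|$. Sets differing
by one protein remain distinct entries — the deliberate, strict definition
of a complex.

## Stage 3: functional modules on the CIN

Two complexes are **synchronous** when their activity-time sets intersect
and **adjacent** when some activity times differ by exactly one (the time
axis is linear by default; a cyclic option exists for periodic designs).
An edge joins two complexes when they are synchronous or adjacent *and*
their membership similarity reaches `th` (default **0.5**); the weight is
the similarity.

The default similarity is the squared-overlap form
$S_C(C_i, C_j) = |C_i \cap C_j|^2 / (|C_i|\,|C_j|)$ — the same convention
as the overlap score used for benchmarking. The plain ratio
$|C_i \cap C_j| / (|C_i|\,|C_j|)$ is also selectable (`"literal"`), but
note it cannot exceed $1/\max(|C_i|,|C_j|)$, so a threshold of 0.5 would
disconnect every pair of complexes of size ≥ 3; the geometric-mean variant
(`"geometric"`) sits between the two.

Modules grow by greedy local modularity maximisation. For a vertex set
$K$,

$$M_K = \frac{\sum_{v \in K} d^{in}_w(K,v)}
             {\sum_{v \in K} d^{in}_w(K,v) + \sum_{v \in K} d^{out}_w(K,v)},$$

with $M_K = 0$ for a set with no incident edges (the 0/0 guard that turns
isolated complexes into singleton modules). Seeds are taken from a queue of
complexes in non-increasing frequency order (ties: larger CIN weighted
degree, then lexicographic ID). A cluster repeatedly adds the unassigned
neighbour with the largest strictly positive gain
$\delta_K M(v) = M_{K \cup \{v\}} - M_K$ (ties: larger edge weight into
$K$, then ID), stopping when no neighbour helps. Emitted vertices leave
the queue and can never be re-assigned, so modules partition the CIN
vertex set. `sMax` refuses any addition that would push the module's
*protein union* above the cap; modules whose union falls below `sMin` are
kept (dropping them would orphan their complexes) but flagged. Size bounds
count proteins, not complexes, because module sizes are conventionally
reported in proteins.

## Evaluation

Predicted complexes are matched to a gold standard by the **overlap
score** $OS(P,K) = |P \cap K|^2/(|P||K|)$; a pair matches when OS reaches
the threshold. TP counts matched predicted complexes, FP the rest, FN the
unmatched known complexes, and
$Sn = TP/(TP+FN)$, $Sp = TP/(TP+FP)$, $f = 2\,Sn\,Sp/(Sn+Sp)$. This Sn/Sp
convention mixes the predicted and known sides; it is the convention of
complex-detection benchmarking and is kept verbatim — fidelity over
contingency-table orthodoxy. Reports round OS to two decimals, three below
0.1, matching how benchmark tables print values such as 0.083 and 0.002.

Module enrichment uses the standard upper-tail hypergeometric test of each
term's occurrence among a module's annotated members, over the annotated
background; the raw minimum p per module is compared against the common
0.001 cutoff (no multiple-testing correction by default — the screening
convention this reproduces; Benjamini–Hochberg is available). Dedicated
curated-annotation tooling would propagate terms through the ontology
graph; we deliberately test the supplied annotations as-is.

## The synthetic study generator

`fixtureSpec()` / `generateFixture()` produce fully self-contained inputs:

* **Network**: planted complexes are cliques with dropout `1 - intraEdgeP`
  (default 1.0 — exact cliques, the clean reference condition; dropout is
  exercised explicitly in tests), plus Erdős–Rényi noise at
  `backgroundEdgeP` (default 0.02) over every other pair.
* **Expression**: each protein scores `exprHigh` (1.0) inside its activity
  window and `exprLow` (0.3) outside, ±0.05 uniform jitter that never
  crosses the 0.7 threshold — so the planted activity schedule is exact
  while floating-point paths are exercised. Background proteins receive
  their own random windows: without that, noise edges would never surface
  inside any TSN and recovery tests would be vacuous.
* **Schedule**: 30 time points; per-complex contiguous windows of length
  3–6 drawn at random (or given explicitly).
* **Process variants**: by default 2 planted complexes get a *twin* (same
  members minus one, plus one new protein) active in the adjacent window.
  Twins are what give the CIN edges and the module stage something real to
  group; each original–twin pair shares a synthetic process term, so
  enrichment can be validated end to end.

What the generator does *not* emulate: scale-free degree structure,
periodic expression, measurement dropout correlated with abundance.
Passing the planted-recovery tests therefore shows the machinery is
correct under its own model, not that real interactome data will be as
forgiving.

Default sizes were chosen so the whole reference study (10 planted
complexes of sizes 4–8, 100 background proteins, 30 TSNs, 20 seeds) runs
comfortably on a laptop; the brute-force oracle tests enumerate all graphs
on up to 5 vertices and 200 random weighted graphs.

## Worked example

```{r example, eval = FALSE}
fx <- generateFixture(fixtureSpec(seed = 7))
tsns <- buildTSNSeries(fx$network, fx$expression, threshold = 0.7)
complexes <- discoverComplexes(tsns, lambda = 1, minSize = 3)
complexes
cin <- buildCIN(complexes, th = 0.5)
modules <- detectModules(cin, complexes)
modules
matchComplexes(complexes, fx$truth, osThreshold = 0.2)
```

## Known limitations

* Overlapping complexes within one TSN are out of scope — the strict
  set-identity definition means heavily overlapping variants are separate
  catalogue entries (by design), and one vertex belongs to one module.
* The agglomeration merge rule is a reconstruction of a hierarchical
  λ-module scheme that the surrounding literature describes only in
  outline; it is isolated behind a single predicate (`locked` inside
  `hcpinCluster`) so it can be swapped.
* Identifier matching is exact-string after whitespace trimming; supply an
  alias table upstream if your network and expression sources use
  different naming schemes.
* Pure-R loops bound the practical scale to networks of a few thousand
  active proteins per TSN; the reference interactome-scale analyses this
  design targets are within that, but genome-scale weighted graphs are
  not.
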