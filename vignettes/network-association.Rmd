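---
title: "Quantifying pathway crosstalk with the network association algorithm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying pathway crosstalk with the network association algorithm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(naatools)
```

## The model

Given two pathway networks $a$ and $b$ — simple undirected graphs over
gene symbols — `naatools` measures their association on the *associated
network* $a\!-\!b$: the union of both graphs, optionally augmented with
edges from a reference interactome.  With $N_{ab}$ union nodes,
$E_{ab}$ union edges, $N_r$ overlapping nodes, $E_r$ overlapping edges
and $E_d$ derived (interactome-contributed) edges, the coefficients are

$$C_N = \frac{N_r}{N_{ab}}, \qquad
  C_E = \frac{E_r + E_d}{E_{ab}}, \qquad
  C = \sqrt{\tfrac{1}{2}\left(C_N^2 + C_E^2\right)},$$

with $C = C_N$ when $E_{ab} = 0$ (an edgeless union carries only node
information, so the edge term is dropped rather than treated as zero).
All three lie in $[0,1]$; $C = 1$ exactly when the two networks are
identical.  Weighted counterparts $C_{Nw}, C_{Ew}, C_w$ replace counts
by weighted sums with per-node weights $w_n$ and per-edge weights
$w_e$; the intended weights are TOPSIS node scores and edge
betweenness, computed *per pathway pair on that pair's own associated
network* so that no weight is shared across pairs.

Three definitional choices were genuinely open and are fixed as
follows:

* **Overlapping edge** means present in *both input edge sets*, not
  merely joining two shared nodes — parallel to the overlapping-node
  definition.
* **Derived edge** means an interactome edge between union nodes that
  is in *neither* input edge set, including edges between two
  same-side-only nodes.  Reconstruction from protein interactions does
  not restrict itself to cross-pathway pairs, so the permissive reading
  is the default; the stricter cross-pathway-only variant is a pure
  filter, exposed as `derived = "cross-only"`.
* The edgeless fallback $C = C_N$ is extended verbatim to the weighted
  score ($C_w = C_{Nw}$), which keeps the two families structurally
  identical.

## Topology indicators

Node ranking uses five nonnegative indicators: degree centrality
$\deg(v)/(n-1)$, normalized shortest-path betweenness (Brandes-style,
all shortest paths counted, hop metric), closeness, the local
clustering coefficient (0 for degree < 2), and the topological
coefficient in the Cytoscape NetworkAnalyzer convention
$T(v) = \overline{J(v,m)}/\deg(v)$ over nodes $m$ sharing at least one
neighbor with $v$, where $J$ counts shared neighbors plus one if
$v \sim m$ ($T(v)=0$ for degree $\le 1$ or no such $m$).

Associated networks are frequently disconnected, so closeness uses the
Wasserman–Faust component correction
$\frac{r}{n-1}\cdot\frac{r}{\sum_u d(v,u)}$ (with $r$ the number of
reachable nodes): it stays finite, rewards membership in large
components, and keeps the indicator positively oriented, which the
TOPSIS standardization assumes.  Whether centralities are normalized is
immaterial downstream — TOPSIS standardization is scale-invariant per
column (and a test asserts this) — so the normalized variants are used
for interpretability.

## Entropy weights and TOPSIS

The entropy weight method computes column shares
$p_{ij} = x_{ij} / \sum_i x_{ij}$, entropies
$e_j = -\frac{1}{\ln n}\sum_i p_{ij}\ln p_{ij}$ (with
$0\ln 0 := 0$) and weights $w_j = (1-e_j)/\sum_k (1-e_k)$: indicators
that vary more across nodes carry more weight.  Constant columns
(including all-zero) are assigned entropy exactly 1 and weight 0; if
*every* column is constant the method degenerates and uniform weights
are used with a warning.  Shares are computed on the raw nonnegative
indicator values — the topology module guarantees nonnegativity, and a
negative input is an explicit error rather than a silent shift.

TOPSIS standardizes by column Euclidean norm
$z_{ij} = x_{ij}/\sqrt{\sum_i x_{ij}^2}$ (standard practice; no
direction flipping since all indicators are positively oriented),
weights the normalized matrix $v_{ij} = w_j z_{ij}$, takes column-wise
ideal/anti-ideal points $Z^\pm$ of $v$, and scores each node by
$c = D^-/(D^+ + D^-)$ with Euclidean distances.  Weights enter through
$v$ — the common entropy–TOPSIS coupling — rather than inside the
distance post-hoc.  Degenerate rows with $D^+ + D^- = 0$ (all rows
identical) score 0.5.  Key nodes are those with $c > 0.6$ strictly,
sorted by descending score with lexicographic tie-breaks.

When TOPSIS scores are reused as NAA node weights they are floored at
$10^{-6}$ (the worst-ranked node scores exactly 0 and would otherwise
vanish from weighted sums); edge betweenness values are floored at
$10^{-9}$ for the same reason.

## Protected k-core

The target network is extracted by repeatedly deleting any
*non-protected* node whose current degree is below $k$, until none
qualifies.  Protected nodes — key proteins and DEPs — are never
removed, and their edges keep counting toward neighbors' degrees
throughout: protection shields the node itself, not merely its label,
because the decomposition preserves surviving nodes *with their
incident edges* and no contrary rule applies.  The maximum coreness
$K_s$ is the largest $k$ whose core still contains at least one
non-protected node; defining it over non-protected survivors prevents a
fully protected residue from making $K_s$ unbounded.  The result is
order-independent (each sweep removes all currently eligible nodes; the
tests additionally verify one-at-a-time random removal orders).  Final
curation of the target network on biological grounds is supported only
as an explicit user-supplied amendment table — never automatic.

## The pipeline

`run_pipeline()` fixes the stage order: DEP filter → pathway loading →
*unweighted* pairwise screening → top pair → topology → entropy weights
→ TOPSIS → weighted NAA → protected maximum core.  When
`weighted: true`, the full per-pair weight computation is performed for
every pair of the matrix (correctness over speed); the weighted score
needs TOPSIS weights, which need the pair's own associated-network
topology, which is why screening cannot precede weighting in any other
order.  The DEP filter uses strict inequalities (`p_value < p_max`,
`|log2fc| > min_abs_lfc`, defaults 0.05 and 0) so boundary rows are
excluded, and applies no multiple-testing adjustment — it consumes
whatever p-value column it is given.

Pathway names resolve first against an edge-list file
(`<name>.tsv`/`.sif`) in `network_dir`, then against a GMT gene set,
whose network is constructed as the interactome-induced subgraph over
its genes — the offline equivalent of querying an interaction database
for the physical interactions within a gene set.

Outputs are fixed-column TSVs with coefficients in 6-decimal fixed
point plus a `report.json`, so identical inputs yield byte-identical
artifacts.

## The synthetic generator

`synth_pathway_pair()` emulates the structural features the method
responds to: two Erdős–Rényi pathway graphs with an exact shared-node
count, a controllable edge density, and an interactome that contains
every pathway edge plus an exact number of derived edges drawn
uniformly from the remaining union pairs.  It does **not** emulate the
degree heterogeneity, clustering or annotation bias of real
interactomes, nor noisy/incomplete pathway membership; passing tests
therefore demonstrate algorithmic correctness and determinism, not
biological validity on real data.  Default study conditions used
throughout the tests and the acceptance script: 15 + 15 node pathways
sharing 12 nodes at edge density 0.45 with 4 derived edges for the
engineered high-overlap pair, 10-node density-0.3 decoys, and
quantification tables with squared-uniform p-values (so roughly a
quarter fall below 0.05) and $\mathcal{N}(0, 1.2^2)$ log2 fold changes.
Property tests run on a few hundred random pairs of up to ~30 nodes and
random graphs of up to 15 nodes (10 for the exhaustive shortest-path
oracle, whose path enumeration grows combinatorially) — sizes at which
brute-force oracles are exact and fast.

## Limitations

* Association coefficients carry no significance measure; none is
  defined for them.
* The k-core convention for counting protected neighbors' degrees
  follows the preservation rule above; a variant that excludes
  protected nodes from degree support would shrink cores.
* Edge weights from betweenness make weighted edge coefficients
  path-structure dependent; on very sparse graphs most betweenness mass
  sits on bridges, which can dominate $C_{Ew}$.
* GMT-induced pathway networks are only as complete as the supplied
  interactome.
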