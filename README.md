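# naatools

Quantifying crosstalk between biological pathways from their
protein–protein interaction networks.

Pathway databases describe signal-transduction pathways (e.g. HIF-1
signaling) and cellular processes (e.g. mitophagy) as separate gene sets
and networks, but drug-response studies routinely need to ask *how
strongly two pathways are coupled* and *which proteins carry that
coupling*. `naatools` implements a network association algorithm (NAA)
that answers both questions from plain edge lists, with no web services
involved.

## The method

Two pathway networks *a* and *b* (node counts *N_a*, *N_b*) are merged —
optionally augmented with reference-interactome edges — into an
**associated network** *a–b* with *N_ab* nodes and *E_ab* edges.  Within
it we count overlapping nodes *N_r* (present in both pathways),
overlapping edges *E_r* (present in both edge sets), and derived edges
*E_d* (interactome edges present in neither).  The association
coefficients are

```
C_N = N_r / N_ab
C_E = (E_r + E_d) / E_ab
C   = sqrt((C_N^2 + C_E^2) / 2)        (C = C_N when E_ab = 0)
```

all in [0, 1], with *C* = 1 exactly when the two networks coincide.
Weighted variants `C_Nw`, `C_Ew`, `C_w` replace counts with weighted
sums; node weights are TOPSIS scores and edge weights are edge
betweenness.

Node importance is ranked by **entropy-weighted TOPSIS** over five
topology indicators (degree, betweenness, closeness, clustering and
topological coefficients).  The entropy weight method gives indicator
*j* the weight `w_j = (1 - e_j) / sum_k (1 - e_k)` where
`e_j = -(1/ln n) * sum_i p_ij ln p_ij` over the column shares `p_ij`;
TOPSIS scores each node by its relative closeness
`D- / (D+ + D-)` to the column-wise ideal and anti-ideal points of the
weighted normalized matrix.  Nodes scoring above 0.6 are **key
proteins**.

Finally a **protected k-core decomposition** repeatedly removes
non-protected nodes of degree < k — key proteins and differentially
expressed proteins (DEPs, `p < 0.05` and `|log2FC| > 0`) are never
removed — and reports the maximum coreness *Ks* core as the target
network.

## Worked example

```r
library(naatools)
a <- pathway_network(rbind(c("A","B"), c("B","C"), c("A","C")), name = "a")
b <- pathway_network(rbind(c("B","C"), c("C","D"), c("B","D")), name = "b")
assoc <- build_association(a, b)
association_coefficient(count_components(assoc))
#> association_score: C_N = 0.500000, C_E = 0.200000, C = 0.380789
```

Two triangles sharing the edge B–C: the union has 4 nodes (2 shared) and
5 edges (1 overlapping), so half the nodes but only a fifth of the edges
are common — the combined coefficient 0.38 summarizes both views.
Weighting the shared nodes B, C twice as heavily raises the node
coefficient accordingly:

```r
weighted_association(assoc,
                     node_w = c(A = 1, B = 2, C = 2, D = 1),
                     edge_w = setNames(rep(1, 5),
                                       edge_key(assoc$edges$from, assoc$edges$to)))
#>           weighted: C_Nw = 0.666667, C_Ew = 0.200000, C_w = 0.492161
```

The full workflow (DEP filter → pairwise matrix → TOPSIS → weighted NAA
→ protected max-core) runs from one YAML config via `run_pipeline()`, or
from the shell via the thin CLI at `inst/cli/naa`
(`naa pipeline --config cfg.yaml`).  See the methods vignette
(`vignettes/network-association.Rmd`) for the modeling choices.

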