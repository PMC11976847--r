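#' Five topology indicators per node
#'
#' Computes the decision matrix used for entropy-TOPSIS node ranking:
#' degree centrality `deg(v)/(n-1)`, normalized shortest-path betweenness,
#' Wasserman-Faust component-corrected closeness, local clustering
#' coefficient (0 for degree < 2), and the topological coefficient in the
#' Cytoscape NetworkAnalyzer convention:
#' `T(v) = mean_m J(v, m) / deg(v)` over nodes `m != v` sharing at least
#' one neighbor with `v`, where `J` counts shared neighbors plus 1 if `v`
#' and `m` are adjacent; `T(v) = 0` when `deg(v) <= 1` or no such `m`
#' exists.  All indicators are nonnegative and finite; rows are ordered
#' lexicographically by node id.  Shortest paths are unweighted (hop
#' counts).
#'
#' @param g a [pathway_network()] or `associated_network`.
#' @return Data frame with columns `node`, `degree`, `betweenness`,
#'   `closeness`, `clustering`, `topological`.
#' @examples
#' tri <- pathway_network(rbind(c("A","B"), c("B","C"), c("A","C")))
#' node_indicators(tri)
#' @export
node_indicators <- function(g) {
  ig <- as_igraph(g)
  n <- igraph::vcount(ig)
  if (n == 0L) stop("empty graph", call. = FALSE)
  nm <- igraph::V(ig)$name
  deg <- igraph::degree(ig)
  degree_c <- if (n > 1L) deg / (n - 1) else rep(0, n)
  btw <- if (n > 2L) {
    igraph::betweenness(ig, directed = FALSE) / ((n - 1) * (n - 2) / 2)
  } else rep(0, n)
  d <- igraph::distances(ig)
  closeness <- vapply(seq_len(n), function(i) {
    di <- d[i, -i]
    reach <- di[is.finite(di)]
    if (length(reach) == 0L || n == 1L) return(0)
    # Wasserman-Faust: fraction reachable times closeness within component
    (length(reach) / (n - 1)) * (length(reach) / sum(reach))
  }, numeric(1))
  clust <- igraph::transitivity(ig, type = "localundirected",
                                isolates = "zero")
  nbrs <- lapply(seq_len(n), function(i)
    as.integer(igraph::neighbors(ig, i)))
  adj <- igraph::as_adjacency_matrix(ig, sparse = FALSE) > 0
  topo <- vapply(seq_len(n), function(i) {
    if (deg[i] <= 1L) return(0)
    ni <- nbrs[[i]]
    jvals <- numeric(0)
    for (m in seq_len(n)) {
      if (m == i) next
      shared <- length(intersect(ni, nbrs[[m]]))
      if (shared == 0L) next
      jvals <- c(jvals, shared + as.integer(adj[i, m]))
    }
    if (length(jvals) == 0L) return(0)
    mean(jvals) / deg[i]
  }, numeric(1))
  out <- data.frame(node = nm, degree = degree_c, betweenness = btw,
                    closeness = closeness, clustering = clust,
                    topological = topo, stringsAsFactors = FALSE)
  out <- out[order(out$node), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Normalized edge betweenness table
#'
#' Shortest-path edge betweenness of every edge, normalized by the number
#' of vertex pairs `n(n-1)/2`, plus a floor of 1e-9 so that downstream
#' weighted edge sums are never all-zero.  Returns an empty table on an
#' edgeless graph.
#'
#' @param g a [pathway_network()] or `associated_network`.
#' @return Named numeric vector keyed by canonical edge key
#'   (see [edge_key()]).
#' @export
edge_betweenness_table <- function(g) {
  ig <- as_igraph(g)
  m <- igraph::ecount(ig)
  if (m == 0L) return(stats::setNames(numeric(0), character(0)))
  n <- igraph::vcount(ig)
  eb <- igraph::edge_betweenness(ig, directed = FALSE) / (n * (n - 1) / 2)
  ends <- igraph::ends(ig, igraph::E(ig))
  stats::setNames(eb + 1e-9, edge_key(ends[, 1L], ends[, 2L]))
}
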