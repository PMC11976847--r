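nodes_of <- function(g) {
  if (inherits(g, "associated_network")) g$nodes$node else g$nodes
}
edges_of <- function(g) g$edges[, c("from", "to"), drop = FALSE]

#' Protected k-core of a network
#'
#' Repeatedly removes any non-protected node whose current degree is below
#' `k` (together with its incident edges) until none qualifies.  Protected
#' nodes are never removed, and their edges to surviving nodes are kept;
#' a protected node's edges keep counting toward its neighbors' degrees
#' throughout (protection shields the node, not only its label).  The
#' result is the induced subgraph on the surviving nodes and is
#' independent of removal order.
#'
#' @param g a [pathway_network()] or `associated_network`.
#' @param protected character vector of node ids exempt from removal
#'   (must all be present in `g`).
#' @param k nonnegative integer degree threshold.
#' @return A [pathway_network()] induced on the surviving nodes.
#' @export
protected_kcore <- function(g, protected = character(), k) {
  stopifnot(k >= 0)
  nodes <- nodes_of(g)
  protected <- normalize_symbols(protected)
  absent <- setdiff(protected, nodes)
  if (length(absent))
    stop("protected node(s) absent from graph: ",
         paste(absent, collapse = ", "), call. = FALSE)
  edges <- edges_of(g)
  alive <- stats::setNames(rep(TRUE, length(nodes)), nodes)
  repeat {
    live_edges <- edges[alive[edges$from] & alive[edges$to], , drop = FALSE]
    deg <- table(factor(c(live_edges$from, live_edges$to),
                        levels = nodes[alive]))
    victims <- names(deg)[deg < k & !(names(deg) %in% protected)]
    if (length(victims) == 0L) break
    alive[victims] <- FALSE
  }
  survivors <- nodes[alive]
  keep <- edges$from %in% survivors & edges$to %in% survivors
  pathway_network(edges[keep, , drop = FALSE], nodes = survivors,
                  name = paste0(g$name, "_core", k))
}

#' Maximum Ks-core with protected nodes
#'
#' Finds the largest `k` for which the protected k-core still contains at
#' least one non-protected node (so a fully protected residue can never
#' make the coreness unbounded), and returns that core as the target
#' network.  `ks = 0` when the graph has no non-protected node surviving
#' any positive threshold (e.g. an edgeless graph).
#'
#' @inheritParams protected_kcore
#' @return A `kcore_result` list: integer `ks` (maximum coreness), `core`
#'   (the [pathway_network()] at `ks`), and `protected_retained` (the
#'   protected nodes present in the core).
#' @export
max_ks_core <- function(g, protected = character()) {
  protected <- normalize_symbols(protected)
  best_k <- 0L
  best <- protected_kcore(g, protected, 0L)
  k <- 1L
  repeat {
    core <- protected_kcore(g, protected, k)
    if (length(setdiff(core$nodes, protected)) == 0L) break
    best_k <- k
    best <- core
    k <- k + 1L
  }
  structure(list(ks = best_k, core = best,
                 protected_retained = intersect(protected, best$nodes)),
            class = "kcore_result")
}

#' @export
print.kcore_result <- function(x, ...) {
  cat(sprintf("kcore_result: Ks = %d; core has %d nodes, %d edges (%d protected retained)\n",
              x$ks, length(x$core$nodes), nrow(x$core$edges),
              length(x$protected_retained)))
  invisible(x)
}

#' Apply a manual amendment list to a network
#'
#' Target networks are often curated after decomposition (nodes or edges
#' added or removed on biological grounds).  This applies an explicit
#' user-supplied amendment table; nothing is ever amended automatically.
#' The table has columns `action` (`add_edge`, `remove_edge`, `add_node`,
#' `remove_node`), `node1`, and `node2` (empty for node actions).
#'
#' @param net a [pathway_network()].
#' @param amendments data frame with columns `action`, `node1`, `node2`.
#' @return The amended [pathway_network()].
#' @export
amend_network <- function(net, amendments) {
  stopifnot(inherits(net, "pathway_network"))
  nodes <- net$nodes
  edges <- net$edges
  for (i in seq_len(NROW(amendments))) {
    act <- amendments$action[i]
    a <- normalize_symbols(amendments$node1[i])
    b <- if ("node2" %in% names(amendments))
      normalize_symbols(amendments$node2[i]) else character()
    if (act == "add_node") {
      nodes <- union(nodes, a)
    } else if (act == "remove_node") {
      nodes <- setdiff(nodes, a)
      edges <- edges[edges$from != a & edges$to != a, , drop = FALSE]
    } else if (act == "add_edge") {
      nodes <- union(nodes, c(a, b))
      edges <- rbind(edges, data.frame(from = min(a, b), to = max(a, b),
                                       stringsAsFactors = FALSE))
    } else if (act == "remove_edge") {
      edges <- edges[edge_keys(edges) != edge_key(a, b), , drop = FALSE]
    } else {
      stop("unknown amendment action: ", act, call. = FALSE)
    }
  }
  pathway_network(edges, nodes = nodes, name = paste0(net$name, "_amended"))
}
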