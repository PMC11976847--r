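#' Build the associated network of two pathway networks
#'
#' The associated network a-b is the union graph of two pathway networks,
#' optionally augmented with reference-interactome edges.  Every node is
#' labeled `a_only`, `b_only` or `shared`; every edge is labeled `a_only`,
#' `b_only`, `overlapping` (present in both input edge sets) or `derived`
#' (an interactome edge between union nodes that appears in neither input
#' edge set).  The interactome contributes edges only, never new nodes.
#'
#' @param net_a,net_b [pathway_network()] objects.
#' @param interactome optional [interactome()]; when absent no derived
#'   edges are added.
#' @param derived `"any"` (default) keeps every interactome edge between
#'   union nodes; `"cross-only"` keeps only edges whose endpoints span the
#'   two pathways (a shared endpoint counts as belonging to both).
#' @return An object of class `associated_network` with fields `name`,
#'   `nodes` (data frame `node`, `label`), `edges` (data frame `from`,
#'   `to`, `label`) and the input node counts `n_a`, `n_b`.
#' @examples
#' a <- pathway_network(rbind(c("A","B"), c("B","C"), c("A","C")), name = "a")
#' b <- pathway_network(rbind(c("B","C"), c("C","D"), c("B","D")), name = "b")
#' build_association(a, b)
#' @export
build_association <- function(net_a, net_b, interactome = NULL,
                              derived = c("any", "cross-only")) {
  derived <- match.arg(derived)
  stopifnot(inherits(net_a, "pathway_network"),
            inherits(net_b, "pathway_network"))
  va <- net_a$nodes; vb <- net_b$nodes
  nodes <- sort(unique(c(va, vb)))
  label <- ifelse(nodes %in% va & nodes %in% vb, "shared",
                  ifelse(nodes %in% va, "a_only", "b_only"))
  ka <- edge_keys(net_a$edges); kb <- edge_keys(net_b$edges)
  union_edges <- canonical_edges(c(net_a$edges$from, net_b$edges$from),
                                 c(net_a$edges$to, net_b$edges$to))
  uk <- edge_keys(union_edges)
  elabel <- ifelse(uk %in% ka & uk %in% kb, "overlapping",
                   ifelse(uk %in% ka, "a_only", "b_only"))
  edges <- union_edges
  edges$label <- elabel
  if (!is.null(interactome)) {
    stopifnot(inherits(interactome, "interactome"))
    ie <- interactome$edges
    in_union <- ie$from %in% nodes & ie$to %in% nodes
    new_edge <- !(edge_keys(ie) %in% uk)
    keep <- in_union & new_edge
    if (derived == "cross-only" && any(keep)) {
      lab <- stats::setNames(label, nodes)
      lu <- lab[ie$from]; lv <- lab[ie$to]
      cross <- !((lu == "a_only" & lv == "a_only") |
                 (lu == "b_only" & lv == "b_only"))
      keep <- keep & cross
    }
    if (any(keep)) {
      de <- ie[keep, , drop = FALSE]
      de$label <- "derived"
      edges <- rbind(edges, de)
      edges <- edges[order(edges$from, edges$to), , drop = FALSE]
    }
  }
  rownames(edges) <- NULL
  structure(list(
    name = paste0(net_a$name, "-", net_b$name),
    nodes = data.frame(node = nodes, label = label,
                       stringsAsFactors = FALSE),
    edges = edges,
    n_a = length(va), n_b = length(vb)),
    class = "associated_network")
}

#' @export
print.associated_network <- function(x, ...) {
  cat(sprintf("associated_network '%s': %d nodes (%d shared), %d edges (%d overlapping, %d derived)\n",
              x$name, nrow(x$nodes), sum(x$nodes$label == "shared"),
              nrow(x$edges), sum(x$edges$label == "overlapping"),
              sum(x$edges$label == "derived")))
  invisible(x)
}

#' Count the components of an associated network
#'
#' Reads the counts that parameterize the association coefficients directly
#' off the provenance labels: union node and edge counts `N_ab`, `E_ab`,
#' overlapping nodes `N_r`, overlapping edges `E_r`, and derived edges
#' `E_d`, alongside the input sizes `N_a`, `N_b`.
#'
#' @param assoc an `associated_network` from [build_association()].
#' @return An `association_counts` list with elements `n_a`, `n_b`, `n_ab`,
#'   `e_ab`, `n_r`, `e_r`, `e_d`.
#' @export
count_components <- function(assoc) {
  stopifnot(inherits(assoc, "associated_network"))
  structure(list(
    n_a = assoc$n_a, n_b = assoc$n_b,
    n_ab = nrow(assoc$nodes), e_ab = nrow(assoc$edges),
    n_r = sum(assoc$nodes$label == "shared"),
    e_r = sum(assoc$edges$label == "overlapping"),
    e_d = sum(assoc$edges$label == "derived")),
    class = "association_counts")
}

#' Association coefficients from component counts
#'
#' The node association coefficient is the fraction of associated-network
#' nodes shared by both pathways, `C_N = N_r / N_ab`.  The edge association
#' coefficient is the fraction of associated-network edges that are
#' overlapping or derived, `C_E = (E_r + E_d) / E_ab`.  The combined
#' coefficient is their root mean square, `C = sqrt((C_N^2 + C_E^2) / 2)`.
#' When the associated network has no edges, `C_E` is undefined and `C`
#' reduces to `C_N` (the `edgeless` flag is set).
#'
#' @param counts an `association_counts` object from [count_components()].
#' @return An `association_score` list with elements `c_n`, `c_e` (`NA` when
#'   edgeless), `c`, and logical `edgeless`.
#' @export
association_coefficient <- function(counts) {
  stopifnot(inherits(counts, "association_counts"))
  if (counts$n_ab == 0L)
    stop("association undefined for an empty associated network (N_ab = 0)",
         call. = FALSE)
  c_n <- counts$n_r / counts$n_ab
  if (counts$e_ab == 0L) {
    return(structure(list(c_n = c_n, c_e = NA_real_, c = c_n,
                          edgeless = TRUE),
                     class = "association_score"))
  }
  c_e <- (counts$e_r + counts$e_d) / counts$e_ab
  structure(list(c_n = c_n, c_e = c_e,
                 c = sqrt((c_n^2 + c_e^2) / 2), edgeless = FALSE),
            class = "association_score")
}

#' @export
print.association_score <- function(x, ...) {
  cat(sprintf("association_score: C_N = %.6f, C_E = %s, C = %.6f%s\n",
              x$c_n, ifelse(is.na(x$c_e), "NA", sprintf("%.6f", x$c_e)),
              x$c, if (isTRUE(x$edgeless)) " (edgeless)" else ""))
  if (!is.null(x$c_w))
    cat(sprintf("          weighted: C_Nw = %.6f, C_Ew = %s, C_w = %.6f\n",
                x$c_nw, ifelse(is.na(x$c_ew), "NA", sprintf("%.6f", x$c_ew)),
                x$c_w))
  invisible(x)
}

#' Weighted association coefficients
#'
#' Reweights the association coefficients by per-node and per-edge
#' importance: `C_Nw` is the weighted sum of shared nodes over the weighted
#' sum of all nodes, `C_Ew` the weighted sum of overlapping and derived
#' edges over the weighted sum of all edges, and
#' `C_w = sqrt((C_Nw^2 + C_Ew^2) / 2)` (reducing to `C_Nw` on an edgeless
#' associated network, mirroring the unweighted special case).  In the
#' intended workflow node weights are TOPSIS scores and edge weights are
#' edge betweenness values (see [naa_weights()]).
#'
#' @param assoc an `associated_network`.
#' @param node_w named nonnegative numeric vector covering every node.
#' @param edge_w named nonnegative numeric vector covering every edge,
#'   keyed by [edge_key()].
#' @return An `association_score` carrying both the unweighted (`c_n`,
#'   `c_e`, `c`) and weighted (`c_nw`, `c_ew`, `c_w`) coefficients.
#' @export
weighted_association <- function(assoc, node_w, edge_w = NULL) {
  stopifnot(inherits(assoc, "associated_network"))
  nodes <- assoc$nodes$node
  missing_n <- setdiff(nodes, names(node_w))
  if (length(missing_n))
    stop("missing node weights for: ", paste(missing_n, collapse = ", "),
         call. = FALSE)
  wn <- node_w[nodes]
  if (any(wn < 0)) stop("node weights must be nonnegative", call. = FALSE)
  if (sum(wn) <= 0) stop("all-zero node weights", call. = FALSE)
  score <- association_coefficient(count_components(assoc))
  c_nw <- sum(wn[assoc$nodes$label == "shared"]) / sum(wn)
  if (nrow(assoc$edges) == 0L) {
    c_ew <- NA_real_
    c_w <- c_nw
  } else {
    keys <- edge_keys(assoc$edges)
    missing_e <- setdiff(keys, names(edge_w))
    if (length(missing_e))
      stop("missing edge weights for: ", paste(missing_e, collapse = ", "),
           call. = FALSE)
    we <- edge_w[keys]
    if (any(we < 0)) stop("edge weights must be nonnegative", call. = FALSE)
    if (sum(we) <= 0) stop("all-zero edge weights", call. = FALSE)
    sel <- assoc$edges$label %in% c("overlapping", "derived")
    c_ew <- sum(we[sel]) / sum(we)
    c_w <- sqrt((c_nw^2 + c_ew^2) / 2)
  }
  score$c_nw <- c_nw
  score$c_ew <- c_ew
  score$c_w <- c_w
  score
}

#' Default NAA weights for an associated network
#'
#' Computes the node and edge weights the weighted association coefficients
#' are designed around: each node is weighted by its entropy-TOPSIS score
#' over the five topology indicators (floored at 1e-6 so the worst-ranked
#' node never zeroes out of weighted sums) and each edge by its normalized
#' edge betweenness (floored at 1e-9).  Networks with fewer than two nodes
#' fall back to uniform node weights, as a one-row decision matrix has no
#' entropy.
#'
#' @param assoc an `associated_network` (or `pathway_network`).
#' @return List with named numeric vectors `node_w` and `edge_w` and the
#'   intermediate `topsis` result (`NULL` under the fallback).
#' @export
naa_weights <- function(assoc) {
  g_nodes <- if (inherits(assoc, "associated_network")) assoc$nodes$node
             else assoc$nodes
  if (length(g_nodes) < 2L) {
    node_w <- stats::setNames(rep(1, length(g_nodes)), g_nodes)
    return(list(node_w = node_w, edge_w = edge_betweenness_table(assoc),
                topsis = NULL))
  }
  dm <- node_indicators(assoc)
  ew <- entropy_weights(dm)
  ts <- topsis(dm, ew)
  node_w <- pmax(stats::setNames(ts$scores$c_score, ts$scores$node), 1e-6)
  list(node_w = node_w, edge_w = edge_betweenness_table(assoc), topsis = ts)
}

#' Union of several pathway networks
#'
#' Combines pathways into a single network (union of node and edge sets),
#' e.g. to score a combination of signal-transduction pathways against a
#' cellular process.
#'
#' @param nets list of [pathway_network()] objects (at least one).
#' @param name label for the combined network.
#' @return A [pathway_network()].
#' @export
combine_pathways <- function(nets, name = "combined") {
  stopifnot(length(nets) >= 1L,
            all(vapply(nets, inherits, logical(1), "pathway_network")))
  edges <- do.call(rbind, lapply(nets, function(n) n$edges))
  nodes <- unique(unlist(lapply(nets, function(n) n$nodes)))
  pathway_network(edges, nodes = nodes, name = name)
}

#' Pairwise pathway association matrix
#'
#' Scores every (signal, process) pathway pair with the association
#' coefficient; with `weighted = TRUE` the node/edge weights are computed
#' per pair on that pair's own associated network (topology indicators ->
#' entropy weights -> TOPSIS node scores; edge betweenness), never shared
#' across pairs.  Also reports the argmax pair.
#'
#' @param signal_sets,process_sets named lists of [pathway_network()]s
#'   (at least one on each side).
#' @param interactome optional [interactome()] contributing derived edges.
#' @param weighted use weighted coefficients for the matrix.
#' @param derived derived-edge mode passed to [build_association()].
#' @return A `pairwise_association` object: numeric `matrix` (rows =
#'   signal, cols = process) of combined coefficients, the per-pair
#'   `scores` list, and `top_pair` (row/col names and score of the argmax;
#'   ties resolved toward the first in row-major order).
#' @export
pairwise_matrix <- function(signal_sets, process_sets, interactome = NULL,
                            weighted = FALSE,
                            derived = c("any", "cross-only")) {
  derived <- match.arg(derived)
  stopifnot(length(signal_sets) >= 1L, length(process_sets) >= 1L)
  sn <- names(signal_sets)
  pn <- names(process_sets)
  if (is.null(sn)) sn <- vapply(signal_sets, function(x) x$name, "")
  if (is.null(pn)) pn <- vapply(process_sets, function(x) x$name, "")
  m <- matrix(NA_real_, length(signal_sets), length(process_sets),
              dimnames = list(sn, pn))
  scores <- vector("list", length(sn) * length(pn))
  k <- 0L
  for (i in seq_along(signal_sets)) {
    for (j in seq_along(process_sets)) {
      k <- k + 1L
      assoc <- build_association(signal_sets[[i]], process_sets[[j]],
                                 interactome, derived = derived)
      sc <- tryCatch({
        if (weighted) {
          w <- naa_weights(assoc)
          s <- weighted_association(assoc, w$node_w, w$edge_w)
          s
        } else {
          association_coefficient(count_components(assoc))
        }
      }, error = function(e) {
        stop(sprintf("pair (%s, %s): %s", sn[i], pn[j], conditionMessage(e)),
             call. = FALSE)
      })
      m[i, j] <- if (weighted) sc$c_w else sc$c
      scores[[k]] <- list(signal = sn[i], process = pn[j], score = sc)
    }
  }
  best <- which(m == max(m), arr.ind = TRUE)[1L, , drop = TRUE]
  structure(list(matrix = m, scores = scores,
                 top_pair = list(signal = sn[best[["row"]]],
                                 process = pn[best[["col"]]],
                                 value = m[best[["row"]], best[["col"]]])),
            class = "pairwise_association")
}

#' @export
print.pairwise_association <- function(x, ...) {
  cat("pairwise_association matrix:\n")
  print(round(x$matrix, 4))
  cat(sprintf("top pair: %s ~ %s (%.4f)\n", x$top_pair$signal,
              x$top_pair$process, x$top_pair$value))
  invisible(x)
}
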