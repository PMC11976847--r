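#' Construct a pathway network
#'
#' A `pathway_network` is a named, simple, undirected graph over gene-symbol
#' nodes.  Gene symbols are whitespace-trimmed and uppercased so that overlap
#' counting never depends on the capitalization of source files.  Self-loops
#' are dropped (with a message) and duplicate edges are collapsed; edges are
#' stored in canonical form (lexicographically sorted endpoint pair).
#'
#' @param edges a two-column character matrix or data frame of edge
#'   endpoints, or `NULL` for an edgeless network.
#' @param nodes additional (possibly isolated) node symbols beyond the edge
#'   endpoints.
#' @param name short label for the network.
#' @return An object of class `pathway_network` with fields `name`,
#'   `nodes` (sorted character vector) and `edges` (data frame with columns
#'   `from`, `to`, canonical order).
#' @examples
#' net <- pathway_network(rbind(c("a", "B"), c("B", "C")), name = "demo")
#' net$nodes
#' @export
pathway_network <- function(edges = NULL, nodes = character(), name = "network") {
  nodes <- normalize_symbols(nodes)
  if (is.null(edges) || NROW(edges) == 0L) {
    em <- data.frame(from = character(), to = character(),
                     stringsAsFactors = FALSE)
  } else {
    edges <- as.matrix(edges)
    if (ncol(edges) < 2L) stop("edges must have two columns", call. = FALSE)
    u <- normalize_symbols(edges[, 1L])
    v <- normalize_symbols(edges[, 2L])
    loops <- u == v
    if (any(loops)) {
      message(sum(loops), " self-loop(s) dropped")
      u <- u[!loops]; v <- v[!loops]
    }
    em <- canonical_edges(u, v)
  }
  all_nodes <- sort(unique(c(nodes, em$from, em$to)))
  structure(list(name = name, nodes = all_nodes, edges = em),
            class = "pathway_network")
}

#' @export
print.pathway_network <- function(x, ...) {
  cat(sprintf("pathway_network '%s': %d nodes, %d edges\n",
              x$name, length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Construct a reference interactome
#'
#' An interactome is an undirected simple edge set used to contribute
#' "derived" edges when two pathway networks are merged into an associated
#' network.  Lookup is symmetric: (u, v) and (v, u) denote the same edge.
#'
#' @param edges two-column character matrix/data frame of interacting pairs.
#' @return An object of class `interactome` with a canonical `edges` frame.
#' @export
interactome <- function(edges = NULL) {
  net <- pathway_network(edges, name = "interactome")
  structure(list(edges = net$edges), class = "interactome")
}

#' @export
print.interactome <- function(x, ...) {
  cat(sprintf("interactome: %d edges\n", nrow(x$edges)))
  invisible(x)
}

normalize_symbols <- function(x) {
  x <- toupper(trimws(as.character(x)))
  x[nzchar(x)]
}

# canonical edge form shared by every module: endpoints sorted, duplicates
# collapsed
canonical_edges <- function(u, v) {
  from <- pmin(u, v)
  to <- pmax(u, v)
  key <- paste(from, to, sep = "\r")
  keep <- !duplicated(key)
  df <- data.frame(from = from[keep], to = to[keep], stringsAsFactors = FALSE)
  df[order(df$from, df$to), , drop = FALSE]
}

edge_keys <- function(edges) {
  if (NROW(edges) == 0L) return(character())
  paste(edges$from, edges$to, sep = "|")
}

#' Edge key helper
#'
#' Canonical string key for an unordered node pair, used to index edge
#' weight tables (`"A|B"` with endpoints sorted).
#' @param u,v character vectors of endpoints.
#' @return character vector of keys.
#' @export
edge_key <- function(u, v) {
  u <- normalize_symbols(u); v <- normalize_symbols(v)
  paste(pmin(u, v), pmax(u, v), sep = "|")
}

#' Read an edge list as a pathway network
#'
#' Supports two-column TSV (`node1 <TAB> node2`) and SIF
#' (`node1 relation node2 [node3 ...]`, whitespace-separated) dialects.
#' Symbols are uppercased, duplicate edges collapsed and self-loops dropped.
#'
#' @param path path to the edge-list file.
#' @param dialect `"tsv"` or `"sif"`.
#' @param name label for the resulting network (defaults to the file name
#'   without extension).
#' @return A [pathway_network()].
#' @export
read_edge_list <- function(path, dialect = c("tsv", "sif"), name = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) return(pathway_network(name = name))
  u <- character(); v <- character()
  for (i in nonblank) {
    fields <- if (dialect == "tsv") {
      strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    } else {
      strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    }
    fields <- trimws(fields)
    fields <- fields[nzchar(fields)]
    if (dialect == "tsv") {
      if (length(fields) < 2L)
        stop(sprintf("malformed edge row at line %d of %s", i, path),
             call. = FALSE)
      u <- c(u, fields[1L]); v <- c(v, fields[2L])
    } else {
      if (length(fields) < 3L)
        stop(sprintf("malformed SIF row at line %d of %s", i, path),
             call. = FALSE)
      targets <- fields[-(1:2)]
      u <- c(u, rep(fields[1L], length(targets))); v <- c(v, targets)
    }
  }
  pathway_network(cbind(u, v), name = name)
}

#' Write a network as a two-column TSV edge list
#'
#' Isolated nodes are appended as single-column rows only when
#' `keep_isolates` is `TRUE` (off by default so the output is a valid strict
#' edge list; round-tripping a network with isolated nodes requires the node
#' table instead).
#'
#' @param net a [pathway_network()].
#' @param path output path.
#' @param keep_isolates append isolated nodes as one-column rows.
#' @export
write_edge_list <- function(net, path, keep_isolates = FALSE) {
  stopifnot(inherits(net, "pathway_network"))
  lines <- paste(net$edges$from, net$edges$to, sep = "\t")
  if (keep_isolates) {
    iso <- setdiff(net$nodes, unique(c(net$edges$from, net$edges$to)))
    lines <- c(lines, iso)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' Standard GMT: set name, description, then member gene symbols, all
#' tab-separated.  Genes are uppercased and deduplicated; records are kept
#' in file order.
#'
#' @param path path to the GMT file.
#' @return A named list of character gene-symbol vectors; descriptions are
#'   attached as the `"descriptions"` attribute.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  sets <- list(); descs <- character()
  for (i in nonblank) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L)
      stop(sprintf("malformed GMT row at line %d of %s (need >= 3 columns)",
                   i, path), call. = FALSE)
    nm <- trimws(fields[1L])
    genes <- unique(normalize_symbols(fields[-(1:2)]))
    sets[[nm]] <- genes
    descs[nm] <- trimws(fields[2L])
  }
  attr(sets, "descriptions") <- descs
  sets
}

#' Read a protein quantification table
#'
#' TSV with header columns `protein_id`, `log2fc`, `p_value`.  Protein ids
#' must be unique, p-values must lie in `[0, 1]` and fold changes must be
#' finite.
#'
#' @param path path to the TSV file.
#' @return A data frame with columns `protein_id`, `log2fc`, `p_value`.
#' @export
read_quant_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "log2fc", "p_value")
  if (!all(need %in% names(df)))
    stop("quant table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  df <- df[need]
  df$protein_id <- toupper(trimws(as.character(df$protein_id)))
  if (anyDuplicated(df$protein_id))
    stop("duplicate protein ids in quant table", call. = FALSE)
  if (any(!is.finite(df$log2fc)))
    stop("non-finite log2fc values in quant table", call. = FALSE)
  if (any(df$p_value < 0 | df$p_value > 1 | !is.finite(df$p_value)))
    stop("p_value outside [0, 1] in quant table", call. = FALSE)
  df
}

#' Filter differentially expressed proteins
#'
#' Selects proteins with `p_value < p_max` and `|log2fc| > min_abs_lfc`,
#' both inequalities strict; rows sitting exactly on either boundary are
#' excluded.  Defaults correspond to the common proteomics DEP definition
#' (p < 0.05, any nonzero fold change).
#'
#' @param table data frame with columns `protein_id`, `log2fc`, `p_value`
#'   (as returned by [read_quant_table()]).
#' @param p_max p-value cutoff in (0, 1]; strict upper bound.
#' @param min_abs_lfc absolute log2 fold-change cutoff (>= 0); strict lower
#'   bound.
#' @return Character vector of selected protein ids (may be empty).
#' @export
filter_deps <- function(table, p_max = 0.05, min_abs_lfc = 0) {
  stopifnot(p_max > 0, p_max <= 1, min_abs_lfc >= 0)
  if (NROW(table) == 0L) return(character())
  sel <- table$p_value < p_max & abs(table$log2fc) > min_abs_lfc
  as.character(table$protein_id[sel])
}

#' Generate a synthetic pathway pair with a reference interactome
#'
#' Builds two Erdos-Renyi-style pathway graphs that share exactly
#' `n_shared` nodes, plus an interactome that contains every pathway edge
#' and exactly `n_derived` extra edges between union nodes that appear in
#' neither pathway's edge set.  Fully reproducible for a fixed seed.
#'
#' @param n_a,n_b node counts of the two pathways.
#' @param n_shared number of nodes present in both (<= min(n_a, n_b)).
#' @param p_edge within-pathway edge probability in `[0, 1]`.
#' @param n_derived exact number of extra interactome edges outside both
#'   pathway edge sets.
#' @param seed integer RNG seed.
#' @return A list with elements `net_a`, `net_b` ([pathway_network()]s) and
#'   `interactome` (an [interactome()]).
#' @export
synth_pathway_pair <- function(n_a, n_b, n_shared, p_edge, n_derived = 0,
                               seed = 1) {
  stopifnot(n_a >= 1, n_b >= 1, n_shared >= 0, n_shared <= min(n_a, n_b),
            p_edge >= 0, p_edge <= 1, n_derived >= 0)
  withr::with_seed(as.integer(seed), {
    n_total <- n_a + n_b - n_shared
    ids <- sprintf("G%03d", seq_len(n_total))
    shared <- ids[seq_len(n_shared)]
    a_nodes <- c(shared, ids[seq_len(n_a - n_shared) + n_shared])
    b_nodes <- c(shared,
                 ids[seq_len(n_b - n_shared) + n_a])
    er_edges <- function(nodes) {
      if (length(nodes) < 2L) {
        return(data.frame(from = character(), to = character(),
                          stringsAsFactors = FALSE))
      }
      pairs <- utils::combn(sort(nodes), 2L)
      keep <- stats::runif(ncol(pairs)) < p_edge
      data.frame(from = pairs[1L, keep], to = pairs[2L, keep],
                 stringsAsFactors = FALSE)
    }
    ea <- er_edges(a_nodes)
    eb <- er_edges(b_nodes)
    net_a <- pathway_network(ea, nodes = a_nodes, name = "pathway_a")
    net_b <- pathway_network(eb, nodes = b_nodes, name = "pathway_b")
    union_nodes <- sort(unique(c(a_nodes, b_nodes)))
    pathway_keys <- union(edge_keys(net_a$edges), edge_keys(net_b$edges))
    all_pairs <- utils::combn(union_nodes, 2L)
    cand_keys <- paste(all_pairs[1L, ], all_pairs[2L, ], sep = "|")
    cand <- which(!(cand_keys %in% pathway_keys))
    if (n_derived > length(cand))
      stop(sprintf("n_derived = %d exceeds the %d available non-pathway pairs",
                   n_derived, length(cand)), call. = FALSE)
    pick <- if (n_derived > 0L) sample(cand, n_derived) else integer()
    inter_edges <- rbind(
      as.matrix(net_a$edges), as.matrix(net_b$edges),
      t(all_pairs[, pick, drop = FALSE]))
    list(net_a = net_a, net_b = net_b,
         interactome = interactome(inter_edges))
  })
}

#' Read a node or edge weight table
#'
#' Two-column TSV (`node <TAB> weight`) yields a named numeric vector keyed
#' by node symbol; three-column TSV (`node1 <TAB> node2 <TAB> weight`)
#' yields a vector keyed by the canonical edge key (see [edge_key()]).
#' Weights must be nonnegative and keys unique after canonicalization.
#'
#' @param path path to the TSV file (no header).
#' @return Named numeric weight vector.
#' @export
read_weight_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) == 2L) {
    keys <- normalize_symbols(df[[1L]])
    w <- as.numeric(df[[2L]])
  } else if (ncol(df) >= 3L) {
    keys <- edge_key(df[[1L]], df[[2L]])
    w <- as.numeric(df[[3L]])
  } else {
    stop("weight table needs 2 (node) or 3 (edge) columns", call. = FALSE)
  }
  if (any(!is.finite(w)) || any(w < 0))
    stop("weights must be finite and nonnegative", call. = FALSE)
  if (anyDuplicated(keys))
    stop("duplicate keys in weight table after canonicalization",
         call. = FALSE)
  stats::setNames(w, keys)
}

# igraph view of a pathway_network / associated_network, preserving
# isolated nodes
as_igraph <- function(net) {
  if (inherits(net, "associated_network")) {
    nodes <- net$nodes$node
    edges <- net$edges[, c("from", "to")]
  } else {
    nodes <- net$nodes
    edges <- net$edges
  }
  igraph::graph_from_data_frame(edges, directed = FALSE,
                                vertices = data.frame(name = nodes))
}
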