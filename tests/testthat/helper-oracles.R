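# Independent oracles used by the tests.  These deliberately avoid the
# package's code paths (and igraph, where the implementation uses it):
# brute-force set intersections for association counts, exhaustive
# shortest-path enumeration for centralities, and straight-line
# step-by-step recomputations for entropy weights and TOPSIS.

`%||%` <- function(a, b) if (is.null(a)) b else a

okey <- function(u, v) paste(pmin(u, v), pmax(u, v), sep = "|")

# association counts by plain set intersection
oracle_counts <- function(net_a, net_b, inter = NULL, derived = "any") {
  ka <- if (nrow(net_a$edges)) okey(net_a$edges$from, net_a$edges$to) else character()
  kb <- if (nrow(net_b$edges)) okey(net_b$edges$from, net_b$edges$to) else character()
  nodes_u <- union(net_a$nodes, net_b$nodes)
  uk <- union(ka, kb)
  e_d <- 0L
  if (!is.null(inter) && nrow(inter$edges)) {
    ie <- inter$edges
    cand <- ie$from %in% nodes_u & ie$to %in% nodes_u &
      !(okey(ie$from, ie$to) %in% uk)
    if (derived == "cross-only") {
      in_a <- function(x) x %in% net_a$nodes
      in_b <- function(x) x %in% net_b$nodes
      cross <- (in_a(ie$from) & in_b(ie$to)) | (in_b(ie$from) & in_a(ie$to))
      cand <- cand & cross
    }
    e_d <- sum(cand)
  }
  list(n_ab = length(nodes_u), e_ab = length(uk) + e_d,
       n_r = length(intersect(net_a$nodes, net_b$nodes)),
       e_r = length(intersect(ka, kb)), e_d = e_d)
}

oracle_coefficient <- function(cnt) {
  c_n <- cnt$n_r / cnt$n_ab
  if (cnt$e_ab == 0) return(list(c_n = c_n, c_e = NA_real_, c = c_n))
  c_e <- (cnt$e_r + cnt$e_d) / cnt$e_ab
  list(c_n = c_n, c_e = c_e, c = sqrt((c_n^2 + c_e^2) / 2))
}

# exhaustive shortest-path enumeration: normalized node betweenness,
# normalized (+1e-9 floor) edge betweenness, Wasserman-Faust closeness
oracle_sp_stats <- function(net) {
  nodes <- net$nodes
  n <- length(nodes)
  adj <- stats::setNames(vector("list", n), nodes)
  for (i in seq_len(nrow(net$edges))) {
    u <- net$edges$from[i]; v <- net$edges$to[i]
    adj[[u]] <- c(adj[[u]], v); adj[[v]] <- c(adj[[v]], u)
  }
  dist_from <- function(s) {
    d <- stats::setNames(rep(Inf, n), nodes); d[s] <- 0
    q <- s
    while (length(q)) {
      w <- q[1]; q <- q[-1]
      for (x in adj[[w]]) if (!is.finite(d[x])) { d[x] <- d[w] + 1; q <- c(q, x) }
    }
    d
  }
  dmat <- t(vapply(nodes, dist_from, stats::setNames(numeric(n), nodes)))
  enum_paths <- function(s, t, d) {
    if (s == t) return(list(s))
    out <- list()
    for (u in adj[[t]]) if (is.finite(d[u]) && d[u] == d[t] - 1) {
      for (p in enum_paths(s, u, d)) out[[length(out) + 1L]] <- c(p, t)
    }
    out
  }
  btw <- stats::setNames(numeric(n), nodes)
  ebtw <- list()
  if (n >= 2) {
    pairs <- t(utils::combn(nodes, 2))
    for (r in seq_len(nrow(pairs))) {
      s <- pairs[r, 1]; t <- pairs[r, 2]
      d <- dmat[s, ]
      if (!is.finite(d[t])) next
      paths <- enum_paths(s, t, d)
      np <- length(paths)
      for (p in paths) {
        for (v in p[-c(1, length(p))]) btw[v] <- btw[v] + 1 / np
        for (j in seq_len(length(p) - 1))
          ebtw[[okey(p[j], p[j + 1])]] <-
            (ebtw[[okey(p[j], p[j + 1])]] %||% 0) + 1 / np
      }
    }
  }
  btw <- if (n > 2) btw / ((n - 1) * (n - 2) / 2) else stats::setNames(numeric(n), nodes)
  clos <- vapply(nodes, function(v) {
    d <- dmat[v, setdiff(nodes, v)]
    reach <- d[is.finite(d)]
    if (length(reach) == 0 || n == 1) return(0)
    (length(reach) / (n - 1)) * (length(reach) / sum(reach))
  }, numeric(1))
  eb_vec <- if (length(ebtw)) {
    stats::setNames(unlist(ebtw), names(ebtw)) / (n * (n - 1) / 2) + 1e-9
  } else stats::setNames(numeric(0), character(0))
  list(betweenness = btw, closeness = clos, edge_betweenness = eb_vec)
}

# step-by-step entropy weights + TOPSIS, written as explicit loops
oracle_entropy_topsis <- function(x, weights = NULL) {
  n <- nrow(x); k <- ncol(x)
  e <- numeric(k)
  for (j in seq_len(k)) {
    col <- x[, j]
    if (max(col) == min(col)) { e[j] <- 1; next }
    p <- col / sum(col)
    s <- 0
    for (i in seq_len(n)) if (p[i] > 0) s <- s + p[i] * log(p[i])
    e[j] <- -s / log(n)
  }
  w <- weights
  if (is.null(w)) {
    d <- 1 - e
    w <- if (sum(d) <= 0) rep(1 / k, k) else d / sum(d)
  }
  z <- x
  for (j in seq_len(k)) {
    nrm <- sqrt(sum(x[, j]^2))
    z[, j] <- if (nrm > 0) x[, j] / nrm else 0
  }
  v <- z
  for (j in seq_len(k)) v[, j] <- w[j] * z[, j]
  zp <- apply(v, 2, max); zm <- apply(v, 2, min)
  dp <- dm <- numeric(n)
  for (i in seq_len(n)) {
    dp[i] <- sqrt(sum((v[i, ] - zp)^2))
    dm[i] <- sqrt(sum((v[i, ] - zm)^2))
  }
  cs <- ifelse(dp + dm > 0, dm / (dp + dm), 0.5)
  list(entropy = e, weights = w, c_score = cs)
}

# sequential k-core variant removing ONE random eligible node at a time,
# used to check that protected_kcore never depends on removal order
sequential_kcore <- function(net, protected, k, seed) {
  withr::with_seed(seed, {
    nodes <- net$nodes
    edges <- net$edges
    repeat {
      deg <- table(factor(c(edges$from, edges$to), levels = nodes))
      eligible <- nodes[deg[nodes] < k & !(nodes %in% protected)]
      if (length(eligible) == 0L) break
      victim <- sample(eligible, 1L)
      nodes <- setdiff(nodes, victim)
      edges <- edges[edges$from != victim & edges$to != victim, , drop = FALSE]
    }
    list(nodes = sort(nodes), edges = edges[order(edges$from, edges$to), ])
  })
}

as_igraph_test <- function(net) {
  igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                vertices = data.frame(name = net$nodes))
}

# synth_pathway_pair, falling back to zero derived edges when the requested
# count is infeasible for a dense small fixture
synth_pair_safe <- function(n_a, n_b, n_shared, p_edge, n_derived, seed) {
  tryCatch(
    synth_pathway_pair(n_a, n_b, n_shared, p_edge, n_derived, seed),
    error = function(e)
      synth_pathway_pair(n_a, n_b, n_shared, p_edge, 0, seed))
}

# small random simple graph as a pathway_network
random_net <- function(n, p, seed, name = "rnd", prefix = "N") {
  withr::with_seed(seed, {
    ids <- sprintf("%s%02d", prefix, seq_len(n))
    if (n >= 2) {
      pairs <- utils::combn(ids, 2)
      keep <- stats::runif(ncol(pairs)) < p
      edges <- t(pairs[, keep, drop = FALSE])
    } else edges <- NULL
    pathway_network(edges, nodes = ids, name = name)
  })
}
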