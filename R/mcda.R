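as_decision_matrix <- function(m) {
  if (is.data.frame(m)) {
    node_col <- which(names(m) == "node")
    if (length(node_col)) {
      x <- as.matrix(m[-node_col])
      rownames(x) <- m$node
    } else {
      x <- as.matrix(m)
    }
  } else {
    x <- as.matrix(m)
  }
  storage.mode(x) <- "double"
  if (any(!is.finite(x))) stop("decision matrix has non-finite entries",
                               call. = FALSE)
  if (any(x < 0))
    stop("decision matrix has negative entries; indicators must be nonnegative",
         call. = FALSE)
  x
}

#' Entropy weights for decision-matrix indicators
#'
#' Objective indicator weighting by information entropy.  Column shares
#' `p_ij = x_ij / sum_i x_ij` give the entropy
#' `e_j = -(1/ln n) * sum_i p_ij ln p_ij` (with `0 ln 0 := 0`); indicator
#' weights are `w_j = (1 - e_j) / sum_k (1 - e_k)`, so low-entropy
#' (high-dispersion) indicators receive higher weight.  Constant columns
#' (including all-zero columns) have entropy exactly 1 and weight 0; if
#' every column is constant the weights fall back to uniform with a
#' warning.
#'
#' @param m decision matrix: numeric matrix or the data frame returned by
#'   [node_indicators()] (>= 2 rows, nonnegative entries).
#' @return An `entropy_weights` list with named numeric vectors `entropy`
#'   and `weights` (weights sum to 1).
#' @export
entropy_weights <- function(m) {
  x <- as_decision_matrix(m)
  n <- nrow(x)
  if (n < 2L)
    stop("entropy weights need at least 2 rows (ln 1 = 0)", call. = FALSE)
  e <- vapply(seq_len(ncol(x)), function(j) {
    col <- x[, j]
    if (max(col) == min(col)) return(1)   # constant column: entropy exactly 1
    p <- col / sum(col)
    terms <- ifelse(p > 0, p * log(p), 0)
    -sum(terms) / log(n)
  }, numeric(1))
  names(e) <- colnames(x)
  d <- 1 - e
  if (sum(d) <= 0) {
    warning("all indicators constant; falling back to uniform weights")
    w <- rep(1 / ncol(x), ncol(x))
  } else {
    w <- d / sum(d)
  }
  names(w) <- colnames(x)
  structure(list(entropy = e, weights = w), class = "entropy_weights")
}

#' TOPSIS ranking of decision-matrix rows
#'
#' Technique for Order of Preference by Similarity to Ideal Solution.
#' Columns are standardized by vector normalization
#' `z_ij = x_ij / sqrt(sum_i x_ij^2)` (all-zero columns stay zero; the
#' topology indicators are all positively oriented so no direction
#' flipping is applied), weighted into `v_ij = w_j z_ij`, and each row is
#' scored by its relative closeness `c = D- / (D+ + D-)` to the
#' column-wise ideal (max) and anti-ideal (min) points of `v`, with
#' Euclidean distances `D+`, `D-`.  Rows indistinguishable from both
#' ideal points (`D+ + D- = 0`, all rows identical) score 0.5 by
#' convention.
#'
#' @param m decision matrix (as for [entropy_weights()]; >= 2 rows).
#' @param w an `entropy_weights` object or a numeric weight vector of
#'   length `ncol(m)` summing to 1.
#' @return A `topsis_result` list: `scores` data frame (`node`, `d_plus`,
#'   `d_minus`, `c_score`), matrices `z` and `v`, and the ideal points
#'   `z_plus`, `z_minus`.
#' @export
topsis <- function(m, w) {
  x <- as_decision_matrix(m)
  if (nrow(x) < 2L) stop("TOPSIS needs at least 2 rows", call. = FALSE)
  if (inherits(w, "entropy_weights")) w <- w$weights
  w <- as.numeric(w)
  if (length(w) != ncol(x))
    stop("weight vector length does not match indicator count", call. = FALSE)
  norms <- sqrt(colSums(x^2))
  z <- sweep(x, 2, ifelse(norms > 0, norms, 1), "/")
  v <- sweep(z, 2, w, "*")
  z_plus <- apply(v, 2, max)
  z_minus <- apply(v, 2, min)
  d_plus <- sqrt(rowSums(sweep(v, 2, z_plus)^2))
  d_minus <- sqrt(rowSums(sweep(v, 2, z_minus)^2))
  denom <- d_plus + d_minus
  c_score <- ifelse(denom > 0, d_minus / denom, 0.5)
  ids <- rownames(x)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(x)))
  structure(list(
    scores = data.frame(node = ids, d_plus = d_plus, d_minus = d_minus,
                        c_score = c_score, stringsAsFactors = FALSE,
                        row.names = NULL),
    z = z, v = v, z_plus = z_plus, z_minus = z_minus),
    class = "topsis_result")
}

#' @export
print.topsis_result <- function(x, ...) {
  cat("topsis_result (top rows by c_score):\n")
  o <- order(-x$scores$c_score, x$scores$node)
  print(utils::head(x$scores[o, ], 10), row.names = FALSE)
  invisible(x)
}

#' Select key nodes from a TOPSIS result
#'
#' Nodes whose final evaluation index exceeds the threshold (strictly;
#' the conventional key-protein cutoff is 0.6), sorted by descending
#' score with ties broken lexicographically by node id.
#'
#' @param r a `topsis_result`.
#' @param threshold score cutoff in `[0, 1]`.
#' @return Character vector of key node ids (possibly empty).
#' @export
select_key_nodes <- function(r, threshold = 0.6) {
  stopifnot(inherits(r, "topsis_result"), threshold >= 0, threshold <= 1)
  s <- r$scores[r$scores$c_score > threshold, , drop = FALSE]
  s$node[order(-s$c_score, s$node)]
}
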