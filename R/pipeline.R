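#' Validate a pipeline configuration file
#'
#' Reads a flat key-value YAML configuration, checks every key, fills in
#' defaults, and verifies that referenced files exist and thresholds are in
#' range.  Recognized keys: `quant` (TSV quantification table), `gmt`,
#' `network_dir`, `interactome` (TSV edge list), `signal` and `process`
#' (pathway name lists), `p_max` (default 0.05), `min_abs_lfc` (default 0),
#' `topsis_threshold` (default 0.6), `weighted` (default TRUE), `derived`
#' (`any`/`cross-only`, default `any`), `amend` (amendment TSV), `seed`
#' (default 1), `out_dir`.
#'
#' @param path path to the YAML config file.
#' @return A validated `pipeline_config` list.
#' @export
validate_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  known <- c("quant", "gmt", "network_dir", "interactome", "signal",
             "process", "p_max", "min_abs_lfc", "topsis_threshold",
             "weighted", "derived", "amend", "seed", "out_dir")
  errs <- character()
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    errs <- c(errs, paste0("unknown config key(s): ",
                           paste(unknown, collapse = ", ")))
  cfg <- list(
    quant = raw$quant, gmt = raw$gmt, network_dir = raw$network_dir,
    interactome = raw$interactome,
    signal = as.character(unlist(raw$signal)),
    process = as.character(unlist(raw$process)),
    p_max = if (is.null(raw$p_max)) 0.05 else as.numeric(raw$p_max),
    min_abs_lfc = if (is.null(raw$min_abs_lfc)) 0
                  else as.numeric(raw$min_abs_lfc),
    topsis_threshold = if (is.null(raw$topsis_threshold)) 0.6
                       else as.numeric(raw$topsis_threshold),
    weighted = if (is.null(raw$weighted)) TRUE else isTRUE(raw$weighted),
    derived = if (is.null(raw$derived)) "any" else as.character(raw$derived),
    amend = raw$amend,
    seed = if (is.null(raw$seed)) 1L else as.integer(raw$seed),
    out_dir = if (is.null(raw$out_dir)) "naa_out" else raw$out_dir)
  for (key in c("quant", "gmt", "network_dir", "interactome", "amend")) {
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]]))
      errs <- c(errs, sprintf("%s: file not found (%s)", key, cfg[[key]]))
  }
  if (length(cfg$signal) == 0L) errs <- c(errs, "signal: at least one pathway name required")
  if (length(cfg$process) == 0L) errs <- c(errs, "process: at least one pathway name required")
  if (!(cfg$p_max > 0 && cfg$p_max <= 1))
    errs <- c(errs, "p_max: must be in (0, 1]")
  if (!(cfg$min_abs_lfc >= 0))
    errs <- c(errs, "min_abs_lfc: must be >= 0")
  if (!(cfg$topsis_threshold >= 0 && cfg$topsis_threshold <= 1))
    errs <- c(errs, "topsis_threshold: must be in [0, 1]")
  if (!cfg$derived %in% c("any", "cross-only"))
    errs <- c(errs, "derived: must be 'any' or 'cross-only'")
  if (length(errs))
    stop("invalid config:\n  - ", paste(errs, collapse = "\n  - "),
         call. = FALSE)
  structure(cfg, class = "pipeline_config")
}

# resolve one pathway name to a network: edge-list file in network_dir, or
# the interactome-induced subgraph of its GMT gene set
resolve_pathway <- function(name, network_dir, gmt_sets, inter) {
  if (!is.null(network_dir)) {
    for (ext in c(".tsv", ".sif")) {
      f <- file.path(network_dir, paste0(name, ext))
      if (file.exists(f))
        return(read_edge_list(f, dialect = sub("^\\.", "", ext), name = name))
    }
  }
  if (!is.null(gmt_sets) && name %in% names(gmt_sets)) {
    genes <- gmt_sets[[name]]
    if (is.null(inter))
      stop(sprintf("pathway '%s' is only in the GMT; an interactome is needed to induce its network",
                   name), call. = FALSE)
    keep <- inter$edges$from %in% genes & inter$edges$to %in% genes
    return(pathway_network(inter$edges[keep, , drop = FALSE], nodes = genes,
                           name = name))
  }
  stop(sprintf("pathway '%s' not found in network_dir or GMT", name),
       call. = FALSE)
}

fmt_num <- function(x) sprintf("%.6f", x)

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full target-network pipeline
#'
#' Executes the fixed stage order: DEP filter -> pathway loading ->
#' pairwise association matrix -> top pair -> topology indicators ->
#' entropy weights -> TOPSIS key nodes -> weighted association ->
#' protected maximum Ks-core (protected set = key nodes plus DEPs present
#' in the top-pair associated network) -> optional manual amendment.
#' Every intermediate artifact is written to the output directory as a
#' fixed-column TSV (coefficients in 6-decimal fixed point) plus a
#' structured `report.json`; identical config and inputs produce
#' byte-identical outputs.
#'
#' @param cfg a `pipeline_config` from [validate_config()], or a path to a
#'   config file.
#' @return A `target_network_report` list (invisibly also serialized to
#'   `out_dir/report.json`): DEP ids, the score matrix, top pair with its
#'   counts and scores, entropy weights, TOPSIS scores, key nodes, the
#'   k-core result and the (possibly amended) target network.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- validate_config(cfg)
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_stage <- function(...) message("[naa] ", sprintf(...))

  ## stage 1: DEP filter
  deps <- character()
  if (!is.null(cfg$quant)) {
    quant <- read_quant_table(cfg$quant)
    deps <- sort(filter_deps(quant, cfg$p_max, cfg$min_abs_lfc))
    if (length(deps) == 0L) warning("DEP filter selected no proteins")
    log_stage("DEP filter: %d of %d proteins selected", length(deps),
              nrow(quant))
  }
  write_tsv(data.frame(protein_id = deps), file.path(cfg$out_dir, "deps.tsv"))

  ## stage 2: load pathway networks and interactome
  inter <- if (!is.null(cfg$interactome))
    interactome(as.matrix(utils::read.delim(cfg$interactome, header = FALSE,
                                            stringsAsFactors = FALSE)))
  else NULL
  gmt_sets <- if (!is.null(cfg$gmt)) read_gmt(cfg$gmt) else NULL
  load_side <- function(names) {
    nets <- lapply(names, resolve_pathway, network_dir = cfg$network_dir,
                   gmt_sets = gmt_sets, inter = inter)
    stats::setNames(nets, names)
  }
  signal_nets <- load_side(cfg$signal)
  process_nets <- load_side(cfg$process)
  log_stage("loaded %d signal and %d process pathway networks",
            length(signal_nets), length(process_nets))

  ## stage 3: pairwise association matrix
  pw <- pairwise_matrix(signal_nets, process_nets, inter,
                        weighted = cfg$weighted, derived = cfg$derived)
  mtab <- data.frame(signal = rownames(pw$matrix)[row(pw$matrix)],
                     process = colnames(pw$matrix)[col(pw$matrix)],
                     coefficient = fmt_num(as.vector(pw$matrix)))
  mtab <- mtab[order(mtab$signal, mtab$process), ]
  write_tsv(mtab, file.path(cfg$out_dir, "matrix.tsv"))
  top <- pw$top_pair
  log_stage("top pair: %s ~ %s (C = %s)", top$signal, top$process,
            fmt_num(top$value))

  ## stage 4: associated network of the top pair
  assoc <- build_association(signal_nets[[top$signal]],
                             process_nets[[top$process]], inter,
                             derived = cfg$derived)
  counts <- count_components(assoc)
  if (counts$n_r == 0L) warning("top pathway pair has no overlapping nodes")
  write_tsv(assoc$edges, file.path(cfg$out_dir, "assoc_edges.tsv"))
  write_tsv(assoc$nodes, file.path(cfg$out_dir, "assoc_nodes.tsv"))

  ## stage 5-7: topology -> entropy -> TOPSIS -> weighted NAA
  dm <- node_indicators(assoc)
  ind_out <- dm
  for (cl in setdiff(names(ind_out), "node"))
    ind_out[[cl]] <- fmt_num(ind_out[[cl]])
  write_tsv(ind_out, file.path(cfg$out_dir, "indicators.tsv"))
  ew <- entropy_weights(dm)
  ts <- topsis(dm, ew)
  key_nodes <- select_key_nodes(ts, cfg$topsis_threshold)
  log_stage("TOPSIS: %d key node(s) above %.2f", length(key_nodes),
            cfg$topsis_threshold)
  ts_out <- ts$scores
  ts_out$key <- ts_out$node %in% key_nodes
  for (cl in c("d_plus", "d_minus", "c_score"))
    ts_out[[cl]] <- fmt_num(ts_out[[cl]])
  write_tsv(ts_out[order(ts$scores$node), ],
            file.path(cfg$out_dir, "topsis.tsv"))
  node_w <- pmax(stats::setNames(ts$scores$c_score, ts$scores$node), 1e-6)
  edge_w <- edge_betweenness_table(assoc)
  score <- if (nrow(assoc$edges) > 0L || counts$n_ab > 0L)
    weighted_association(assoc, node_w, edge_w)
  else association_coefficient(counts)

  ## stage 8: protected maximum Ks-core
  protected <- sort(union(key_nodes, intersect(deps, assoc$nodes$node)))
  core <- max_ks_core(assoc, protected)
  log_stage("max Ks-core: Ks = %d, %d nodes, %d edges", core$ks,
            length(core$core$nodes), nrow(core$core$edges))
  target <- core$core

  ## stage 9: optional manual amendment
  if (!is.null(cfg$amend)) {
    am <- utils::read.delim(cfg$amend, stringsAsFactors = FALSE)
    target <- amend_network(target, am)
    log_stage("amendments applied: %d action(s)", nrow(am))
  }
  core_nodes <- data.frame(node = target$nodes,
                           protected = target$nodes %in% protected)
  write_tsv(target$edges, file.path(cfg$out_dir, "core.tsv"))
  write_tsv(core_nodes, file.path(cfg$out_dir, "core_nodes.tsv"))

  report <- structure(list(
    deps = deps,
    matrix = pw$matrix,
    top_pair = list(signal = top$signal, process = top$process),
    counts = unclass(counts),
    score = unclass(score),
    entropy = as.list(ew$entropy),
    weights = as.list(ew$weights),
    topsis = ts$scores,
    key_nodes = key_nodes,
    protected = protected,
    ks = core$ks,
    core_nodes = target$nodes,
    core_edges = target$edges),
    class = "target_network_report")
  json <- jsonlite::toJSON(list(
    n_deps = length(deps),
    top_pair = c(top$signal, top$process),
    top_coefficient = round(top$value, 6),
    counts = unclass(counts),
    c_n = round(score$c_n, 6), c_e = round(score$c_e, 6),
    c = round(score$c, 6),
    c_nw = if (!is.null(score$c_nw)) round(score$c_nw, 6) else NULL,
    c_ew = if (!is.null(score$c_ew)) round(score$c_ew, 6) else NULL,
    c_w = if (!is.null(score$c_w)) round(score$c_w, 6) else NULL,
    key_nodes = key_nodes,
    protected = protected,
    ks = core$ks,
    core_n_nodes = length(target$nodes),
    core_n_edges = nrow(target$edges)),
    auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null",
    na = "null")
  writeLines(json, file.path(cfg$out_dir, "report.json"))
  invisible(report)
}
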