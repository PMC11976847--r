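# Builds a complete on-disk pipeline fixture: two signal and two process
# pathway networks (one signal/process pair engineered to share most of its
# nodes and edges, the other pathways mutually disjoint), a reference
# interactome, a protein quantification table over the node universe, and a
# YAML config.  Returns the config path.
make_pipeline_fixture <- function(dir, seed = 17) {
  net_dir <- file.path(dir, "networks")
  dir.create(net_dir, showWarnings = FALSE, recursive = TRUE)
  fx <- synth_pathway_pair(n_a = 15, n_b = 15, n_shared = 12, p_edge = 0.45,
                           n_derived = 4, seed = seed)
  sig2 <- random_net(10, 0.3, seed + 1, name = "SIG2", prefix = "S")
  proc2 <- random_net(10, 0.3, seed + 2, name = "PROC2", prefix = "Q")
  write_edge_list(fx$net_a, file.path(net_dir, "SIG1.tsv"))
  write_edge_list(fx$net_b, file.path(net_dir, "PROC1.tsv"))
  write_edge_list(sig2, file.path(net_dir, "SIG2.tsv"))
  write_edge_list(proc2, file.path(net_dir, "PROC2.tsv"))
  inter_edges <- rbind(as.matrix(fx$interactome$edges),
                       as.matrix(sig2$edges), as.matrix(proc2$edges))
  utils::write.table(inter_edges, file.path(dir, "interactome.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  universe <- sort(unique(c(fx$net_a$nodes, fx$net_b$nodes, sig2$nodes,
                            proc2$nodes)))
  quant <- withr::with_seed(seed + 3, data.frame(
    protein_id = universe,
    log2fc = round(stats::rnorm(length(universe), sd = 1.2), 4),
    p_value = round(stats::runif(length(universe))^2, 6)))
  utils::write.table(quant, file.path(dir, "quant.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cfg_path <- file.path(dir, "config.yaml")
  writeLines(c(
    paste0("quant: ", file.path(dir, "quant.tsv")),
    paste0("network_dir: ", net_dir),
    paste0("interactome: ", file.path(dir, "interactome.tsv")),
    "signal:", "  - SIG1", "  - SIG2",
    "process:", "  - PROC1", "  - PROC2",
    "weighted: true",
    paste0("seed: ", seed),
    paste0("out_dir: ", file.path(dir, "out"))), cfg_path)
  cfg_path
}

# directory fingerprint for byte-identity checks
dir_digest <- function(dir) {
  files <- sort(list.files(dir, recursive = TRUE, full.names = TRUE))
  vapply(files, function(f) paste(readLines(f, warn = FALSE), collapse = "\n"),
         character(1))
}
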