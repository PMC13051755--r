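#!/usr/bin/env Rscript
# Cross-kingdom co-occurrence networks per cultivar class (Spearman,
# |rho| > 0.6 & p < 0.01), Louvain modules, Zi-Pi keystone roles, edge
# accounting by kingdom pair and sign, and keystone-score regressions.

suppressMessages(library(phyllokbs))
if (!file.exists("results/data/metadata.tsv"))
  stop("run analysis/01_simulate.R first")

seed <- 1L
meta <- read_metadata("results/data/metadata.tsv")
tabs <- list(
  bacteria = filter_low_count(read_count_table(
    "results/data/counts_bacteria.tsv", "bacteria",
    orientation = "taxa_rows"), 20),
  fungi = filter_low_count(read_count_table(
    "results/data/counts_fungi.tsv", "fungi",
    orientation = "taxa_rows"), 20))
truth <- jsonlite::read_json("results/data/ground_truth.json",
                             simplifyVector = TRUE)

for (cl in c("susceptible", "resistant")) {
  keep <- meta$sample_id[meta$resistance == cl]
  sub <- lapply(tabs, function(tb)
    count_table(tb$counts[, intersect(sample_ids(tb), keep)], tb$kingdom))
  net <- build_network(sub)
  net <- zi_pi(detect_modules(net, seed = derive_seed(seed, paste0("mod_", cl))))
  topo <- net_topology(net)
  message(sprintf("%s: %d nodes, %d edges, avg degree %.1f",
                  cl, topo$n_nodes, topo$n_edges, topo$avg_degree))
  message(sprintf("  roles: %s",
                  paste(names(table(net$nodes$role)), table(net$nodes$role),
                        sep = "=", collapse = " ")))
  found <- intersect(truth$bacteria$hubs, net$nodes$taxon_id)
  deg <- stats::setNames(net$nodes$degree, net$nodes$taxon_id)
  message(sprintf("  planted hubs present: %d/%d, of which in top degree decile: %d",
                  length(found), length(truth$bacteria$hubs),
                  sum(deg[found] >= stats::quantile(deg, 0.9))))
  write.table(net$edges, sprintf("results/network_edges_%s.tsv", cl),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(net$nodes, sprintf("results/network_nodes_%s.tsv", cl),
              sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(n_nodes = topo$n_nodes, n_edges = topo$n_edges,
                            avg_degree = topo$avg_degree,
                            edge_proportions = as.data.frame(
                              topo$edge_proportions)),
                       sprintf("results/network_topology_%s.json", cl),
                       auto_unbox = TRUE, digits = NA)
  reg <- keystone_regressions(net)
  print(reg)
}
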