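#!/usr/bin/env Rscript
# The keystone-beneficial-specialist screen: intersect Zi-Pi keystones,
# niche specialists and the beneficial-genus list per cultivar class, then
# quantify KBS relative abundance, class-level composition and the
# KBS-yield relationship per resistance class.

suppressMessages(library(phyllokbs))
if (!file.exists("results/data/metadata.tsv"))
  stop("run analysis/01_simulate.R first")

seed <- 1L
meta <- read_metadata("results/data/metadata.tsv")
tax <- read_taxonomy("results/data/taxonomy_bacteria.tsv")
ben <- read_beneficial("results/data/beneficial.tsv", rank = "genus")
tabs <- list(
  bacteria = filter_low_count(read_count_table(
    "results/data/counts_bacteria.tsv", "bacteria",
    orientation = "taxa_rows"), 20),
  fungi = filter_low_count(read_count_table(
    "results/data/counts_fungi.tsv", "fungi",
    orientation = "taxa_rows"), 20))

for (cl in c("susceptible", "resistant")) {
  keep <- meta$sample_id[meta$resistance == cl]
  sub <- lapply(tabs, function(tb)
    count_table(tb$counts[, intersect(sample_ids(tb), keep)], tb$kingdom))
  net <- zi_pi(detect_modules(build_network(sub),
                              seed = derive_seed(seed, paste0("mod_", cl))))
  nc <- classify_niche(sub$bacteria, n_perm = 1000,
                       seed = derive_seed(seed, paste0("niche_", cl)))
  kbs <- screen_kbs(net, nc, tax, ben)
  message(sprintf("%s: keystone %d, specialist %d, beneficial %d -> KBS %d",
                  cl, kbs$counts["keystone"], kbs$counts["specialist"],
                  kbs$counts["beneficial"], kbs$counts["kbs"]))
  ab <- kbs_abundance(kbs, sub$bacteria, meta)
  message(sprintf("  KBS relative abundance: %.2f%% (mean over samples)",
                  100 * mean(ab$per_sample)))
  comp <- kbs_composition(kbs, sub$bacteria, tax)
  if (length(comp))
    message(sprintf("  composition: %s",
                    paste(names(comp), sprintf("%.0f%%", 100 * comp),
                          collapse = ", ")))
  ky <- kbs_yield_correlation(kbs, sub$bacteria, meta)
  message(sprintf("  KBS-yield: r = %.2f (p = %.3g, slope %.1f)",
                  ky$r[1], ky$p[1], ky$slope[1]))
  write.table(kbs$provenance, sprintf("results/kbs_taxa_%s.tsv", cl),
              sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(counts = as.list(kbs$counts),
                            mean_abundance = mean(ab$per_sample),
                            composition = as.list(comp),
                            yield = ky),
                       sprintf("results/kbs_summary_%s.json", cl),
                       auto_unbox = TRUE, digits = NA)
}
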