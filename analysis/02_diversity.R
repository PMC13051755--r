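#!/usr/bin/env Rscript
# Alpha richness, Bray-Curtis PCoA and PERMANOVA (999 permutations) on the
# phyllosphere tables, contrasting resistant vs susceptible cultivars.

suppressMessages(library(phyllokbs))
if (!file.exists("results/data/metadata.tsv"))
  stop("run analysis/01_simulate.R first")

seed <- 1L
meta <- read_metadata("results/data/metadata.tsv")

for (kd in c("bacteria", "fungi")) {
  tb <- read_count_table(sprintf("results/data/counts_%s.tsv", kd), kd,
                         orientation = "taxa_rows")
  tb <- filter_low_count(tb, 20)
  tb <- rarefy(tb, min(colSums(tb$counts)), derive_seed(seed, kd))
  cls <- meta$resistance[match(sample_ids(tb), meta$sample_id)]

  rich <- richness(tb)
  tt <- group_tests(rich, cls)
  d <- bray_curtis(tb)
  ord <- pcoa(d)
  pv <- permanova(d, cls, n_perm = 999, seed = derive_seed(seed, paste0("pm_", kd)))

  message(sprintf(
    "%s: richness %s mean %.0f vs %s %.0f (t p = %.3g); PERMANOVA F = %.2f, R2 = %.3f, p = %.3g",
    kd, names(tt$means)[1], tt$means[1], names(tt$means)[2], tt$means[2],
    tt$p, pv$pseudo_F, pv$R2, pv$p))
  message(sprintf("  PCoA1 explains %.1f%% of distance mass",
                  100 * ord$prop_explained[1]))

  write.table(data.frame(sample_id = sample_ids(tb), richness = rich,
                         class = cls, PCoA1 = ord$coords[, 1],
                         PCoA2 = ord$coords[, 2]),
              sprintf("results/diversity_%s.tsv", kd),
              sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(pv, sprintf("results/permanova_%s.json", kd),
                       auto_unbox = TRUE, digits = NA)
}
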