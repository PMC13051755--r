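#!/usr/bin/env Rscript
# Levins niche breadth with the fixed-fixed permutation null (1000
# permutations): specialist / neutral / generalist labels per cultivar
# class, the class contrast (t-test), and the CS/CR/FS/FR comparison
# (ANOVA + LSD letters).

suppressMessages(library(phyllokbs))
if (!file.exists("results/data/metadata.tsv"))
  stop("run analysis/01_simulate.R first")

seed <- 1L
meta <- read_metadata("results/data/metadata.tsv")
tb <- read_count_table("results/data/counts_bacteria.tsv", "bacteria",
                       orientation = "taxa_rows")
tb <- filter_low_count(tb, 20)
cls <- meta$resistance[match(sample_ids(tb), meta$sample_id)]

per_class <- lapply(c("susceptible", "resistant"), function(cl) {
  sub <- count_table(tb$counts[, cls == cl, drop = FALSE], "bacteria")
  nc <- classify_niche(sub, n_perm = 1000,
                       seed = derive_seed(seed, paste0("niche_", cl)))
  write.table(nc, sprintf("results/niche_%s.tsv", cl), sep = "\t",
              quote = FALSE, row.names = FALSE)
  message(sprintf("%s: %d specialists, %d neutral, %d generalists", cl,
                  sum(nc$label == "specialist"),
                  sum(nc$label == "neutral_taxon"),
                  sum(nc$label == "generalist")))
  list(table = sub, niche = nc)
})
names(per_class) <- c("susceptible", "resistant")

cmp <- compare_breadth(per_class$susceptible$niche,
                       per_class$resistant$niche,
                       labels = c("susceptible", "resistant"))
message(sprintf("breadth t-test: mean B %.2f vs %.2f, p = %.3g (wider: %s)",
                cmp$means[1], cmp$means[2], cmp$p, cmp$direction))

# four-group comparison on community-weighted sample breadth
nc_all <- classify_niche(tb, n_perm = 1000, seed = derive_seed(seed, "all"))
sb <- sample_breadth(tb, nc_all)
groups <- sample_groups(meta)[match(names(sb), meta$sample_id)]
an <- group_tests(sb, groups)
message(sprintf("CS/CR/FS/FR ANOVA F = %.2f, p = %.3g; LSD letters: %s",
                an$statistic, an$p,
                paste(names(an$letters), an$letters, sep = "=",
                      collapse = " ")))
jsonlite::write_json(list(t_test = cmp, anova_letters = as.list(an$letters)),
                     "results/niche_comparisons.json", auto_unbox = TRUE,
                     digits = NA)
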