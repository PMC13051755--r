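#!/usr/bin/env Rscript
# Path-model (SEM) attribution of yield per cultivar class: soil PC1,
# community PCoA1, keystone and KBS relative abundance into yield, fitted
# by maximum likelihood with chi-square / GFI / RMSEA fit indices and
# total effects on yield.

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

fits <- list()
for (cl in c("susceptible", "resistant")) {
  keep <- meta$sample_id[meta$resistance == cl]
  sub <- lapply(tabs, function(tb)
    count_table(tb$counts[, intersect(sample_ids(tb), keep)], tb$kingdom))
  net <- zi_pi(detect_modules(build_network(sub),
                              seed = derive_seed(seed, paste0("mod_", cl))))
  nc <- classify_niche(sub$bacteria, n_perm = 1000,
                       seed = derive_seed(seed, paste0("niche_", cl)))
  kbs <- screen_kbs(net, nc, tax, ben)
  sm <- suppressMessages(build_study_model(sub$bacteria, net, kbs, meta))
  fit <- fit_sem(sm$data, sm$model, seed = derive_seed(seed, paste0("sem_", cl)))
  message(sprintf("%s: chi2 = %.3g (df = %d), GFI = %.3f, RMSEA = %.3f",
                  cl, fit$chi_square, fit$df, fit$GFI, fit$RMSEA))
  print(fit$estimates[, c("from", "to", "std", "p")], digits = 3)
  te <- total_effects(fit, "yield")
  message(sprintf("  total effects on yield: %s",
                  paste(names(te)[names(te) != "yield"],
                        sprintf("%.2f", te[names(te) != "yield"]),
                        sep = "=", collapse = " ")))
  fits[[cl]] <- list(chi_square = fit$chi_square, df = fit$df,
                     GFI = fit$GFI, RMSEA = fit$RMSEA,
                     estimates = fit$estimates,
                     total_effects_on_yield = as.list(te))
}
jsonlite::write_json(fits, "results/sem_fits.json", auto_unbox = TRUE,
                     digits = NA)
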