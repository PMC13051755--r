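#!/usr/bin/env Rscript
# Generate the synthetic phyllosphere study: 60 samples (10 sorghum
# cultivars x control/fertilized x 3 replicates, 5 cultivars resistant),
# bacterial and fungal OTU tables with planted co-occurrence modules and
# hub taxa, trees, taxonomy, a beneficial-genus list, soil properties and
# yield coupled to soil PC1 and KBS abundance with a genotype-dependent
# sign. Everything downstream reads the files this writes.

suppressMessages(library(phyllokbs))

seed <- 1L
dir.create("results", showWarnings = FALSE)

spec_b <- synth_spec(n_taxa = 120, reads_per_sample = 20000,
                     n_modules = 4, module_size = 25, seed = seed)
out <- synth_bundle(spec_b, dir = "results/data")

message("wrote study bundle under results/data:")
for (p in out[names(out) != "truth"]) message("  ", p)
message(sprintf("ground truth: m = %.2f, %d planted bacterial hubs, %d beneficial genera",
                out$truth$migration_m, length(out$truth$bacteria$hubs),
                length(out$truth$beneficial)))
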