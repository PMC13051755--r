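#' Default pipeline configuration
#'
#' One master seed drives every stochastic stage (stage seeds are derived
#' deterministically); null/permutation counts default to the full-study
#' values and can be reduced for quick runs.
#'
#' @param seed master seed.
#' @param out_dir output directory.
#' @param ... overrides for any default field.
#' @return named list of configuration values.
#' @export
pipeline_config <- function(seed = 1L, out_dir = tempfile("phyllokbs_run_"),
                            ...) {
  cfg <- list(
    seed = seed,
    out_dir = out_dir,
    synth = list(),             # overrides for synth_spec (bacteria)
    min_total = 20L,            # low-count taxon filter
    n_null_assembly = 999L,     # betaNTI / RC-Bray replicates
    n_perm_niche = 1000L,       # fixed-fixed permutations
    n_perm_permanova = 999L,
    rho_min = 0.6, p_max = 0.01, prevalence_min = 0.2,
    assembly_kingdom = "bacteria",
    kbs_kingdoms = "bacteria")
  utils::modifyList(cfg, list(...))
}

#' Load a pipeline configuration from YAML
#' @param path YAML file with any subset of [pipeline_config()] fields.
#' @return configuration list.
#' @export
read_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the full synthetic-study pipeline
#'
#' synth -> io round trip -> filter/rarefy -> diversity (richness, PCoA,
#' PERMANOVA) -> assembly partition -> neutral-model fits -> niche
#' classification -> co-occurrence networks with Zi-Pi -> KBS screen ->
#' path-model SEM, all per cultivar class where the study stratifies.
#' Deterministic given the config's master seed; results are returned and
#' key tables written under `out_dir`.
#'
#' @param config list from [pipeline_config()] or [read_config()].
#' @return list with one element per stage.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  spec_b <- do.call(synth_spec, utils::modifyList(list(seed = seed),
                                                  config$synth))
  bundle <- synth_bundle(spec_b, dir = file.path(config$out_dir, "data"))
  # read everything back through the io layer
  tabs <- list(
    bacteria = read_count_table(bundle$counts_bacteria, "bacteria",
                                orientation = "taxa_rows"),
    fungi = read_count_table(bundle$counts_fungi, "fungi",
                             orientation = "taxa_rows"))
  tax <- list(bacteria = read_taxonomy(bundle$taxonomy_bacteria),
              fungi = read_taxonomy(bundle$taxonomy_fungi))
  trees <- list(bacteria = read_tree(bundle$tree_bacteria),
                fungi = read_tree(bundle$tree_fungi))
  meta <- read_metadata(bundle$metadata)
  beneficial <- read_beneficial(bundle$beneficial, rank = "genus")
  # filter + rarefy to the minimum column total
  tabs <- lapply(tabs, filter_low_count, min_total = config$min_total)
  tabs <- lapply(names(tabs), function(kd) {
    tb <- tabs[[kd]]
    rarefy(tb, min(colSums(tb$counts)), derive_seed(seed, paste0("rarefy_", kd)))
  })
  names(tabs) <- c("bacteria", "fungi")
  cls <- meta$resistance[match(sample_ids(tabs$bacteria), meta$sample_id)]
  # diversity
  div <- lapply(tabs, function(tb) {
    d <- bray_curtis(tb)
    list(richness = richness(tb), dist = d, ord = pcoa(d),
         permanova = permanova(d, cls, n_perm = config$n_perm_permanova,
                               seed = derive_seed(seed, "permanova")))
  })
  # assembly partition (within-class pairs), one kingdom by default
  kd <- config$assembly_kingdom
  asm <- assembly_analysis(tabs[[kd]], trees[[kd]], cls,
                           n_null = config$n_null_assembly,
                           seed = derive_seed(seed, "assembly"))
  # per-class stages
  classes <- c("susceptible", "resistant")
  per_class <- lapply(classes, function(cl) {
    sub <- lapply(tabs, function(tb) {
      keep <- cls == cl
      count_table(tb$counts[, keep, drop = FALSE], tb$kingdom)
    })
    ncm <- lapply(sub, function(tb) fit_ncm(tb))
    niche <- lapply(sub, function(tb)
      classify_niche(tb, n_perm = config$n_perm_niche,
                     seed = derive_seed(seed, paste(cl, tb$kingdom, "niche"))))
    net <- build_network(sub, rho_min = config$rho_min,
                         p_max = config$p_max,
                         prevalence_min = config$prevalence_min)
    net <- zi_pi(detect_modules(net, seed = derive_seed(seed,
                                                        paste(cl, "modules"))))
    kbs <- screen_kbs(net, do.call(rbind, niche), tax$bacteria, beneficial,
                      kingdoms = config$kbs_kingdoms)
    sem_in <- build_study_model(sub$bacteria, net, kbs, meta)
    fit <- fit_sem(sem_in$data, sem_in$model,
                   seed = derive_seed(seed, paste(cl, "sem")))
    list(tables = sub, ncm = ncm, niche = niche, network = net, kbs = kbs,
         kbs_yield = kbs_yield_correlation(kbs, sub$bacteria, meta),
         sem = fit)
  })
  names(per_class) <- classes
  res <- list(config = config, truth = bundle$truth, tables = tabs,
              metadata = meta, diversity = div, assembly = asm,
              per_class = per_class)
  write_pipeline_outputs(res)
  res
}

# key tables to disk: per-pair assembly TSV, process fractions, NCM JSON,
# KBS provenance, SEM estimates
write_pipeline_outputs <- function(res) {
  out <- res$config$out_dir
  utils::write.table(res$assembly$pairs,
                     file.path(out, "assembly_pairs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(fractions = as.data.frame(res$assembly$fractions)),
    file.path(out, "assembly_fractions.json"), auto_unbox = TRUE, digits = NA)
  summ <- lapply(res$per_class, function(cl) list(
    ncm = lapply(cl$ncm, function(f) list(m = f$m, R2 = f$R2, N = f$N)),
    network = list(n_nodes = nrow(cl$network$nodes),
                   n_edges = nrow(cl$network$edges)),
    kbs = list(n = length(cl$kbs$kbs_taxa),
               counts = as.list(cl$kbs$counts)),
    sem = list(chi_square = cl$sem$chi_square, df = cl$sem$df,
               GFI = cl$sem$GFI, RMSEA = cl$sem$RMSEA)))
  jsonlite::write_json(summ, file.path(out, "class_summaries.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out)
}
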