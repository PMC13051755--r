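#' Specification for a synthetic phyllosphere study
#'
#' Bundles every knob of the generator. Defaults emulate the study design:
#' 10 sorghum cultivars (5 resistant, 5 susceptible) x 2 fertilization
#' treatments x 3 replicates = 60 phyllosphere samples, a lognormal
#' metacommunity sampled through a Dirichlet-multinomial neutral process
#' with migration rate `migration_m`, optional phylogenetically
#' autocorrelated habitat selection, planted correlation modules with hub
#' taxa, a beneficial subset, and yield coupled to soil PC1 and KBS
#' abundance with a genotype-dependent sign.
#'
#' @param n_taxa number of taxa in the metacommunity.
#' @param migration_m Sloan migration rate in (0, 1].
#' @param reads_per_sample sequencing depth N per sample.
#' @param meta_mu,meta_sigma lognormal parameters of metacommunity abundances.
#' @param selection_strength phylogenetic habitat-filtering strength (0 = neutral).
#' @param n_modules,module_size,within_module_corr,n_hubs_per_module planted
#'   correlation-module structure for the co-occurrence generator;
#'   `module_size = NULL` scales it to cover at most half the taxa.
#' @param beneficial_fraction fraction of genera flagged beneficial.
#' @param b_soil,b_kbs_resistant,b_kbs_susceptible,noise_sd yield model
#'   coefficients: yield = intercept + b_soil*soilPC1 + b_kbs(class)*KBS + eps.
#' @param n_replicates biological replicates per cultivar x treatment.
#' @param seed master seed; all generators derive stage seeds from it.
#' @return list of class `synth_spec`.
#' @export
synth_spec <- function(n_taxa = 400L,
                       migration_m = 0.10,
                       reads_per_sample = 2000L,
                       meta_mu = 0, meta_sigma = 2,
                       selection_strength = 0,
                       n_modules = 4L, module_size = NULL,
                       within_module_corr = 0.8, n_hubs_per_module = 1L,
                       beneficial_fraction = 0.10,
                       b_soil = 0.4, b_kbs_resistant = 80,
                       b_kbs_susceptible = -80, noise_sd = 0.25,
                       n_replicates = 3L,
                       seed = 1L) {
  stopifnot(migration_m > 0, migration_m <= 1,
            abs(within_module_corr) < 1, beneficial_fraction >= 0,
            beneficial_fraction <= 1, selection_strength >= 0,
            n_taxa >= 2, reads_per_sample >= 1, noise_sd >= 0)
  if (is.null(module_size))  # default: modules cover at most half the taxa
    module_size <- max(2L, min(25L, n_taxa %/% (2L * n_modules)))
  if (n_modules * module_size > n_taxa)
    abort("planted modules need %d taxa but n_taxa = %d",
          n_modules * module_size, n_taxa)
  structure(as.list(environment()), class = "synth_spec")
}

#' The 10 x 2 x r sample design
#'
#' Cultivars R1..R5 are resistant, S1..S5 susceptible; each appears under
#' control and fertilized treatments with `n_replicates` replicates.
#'
#' @param spec a `synth_spec`.
#' @return data.frame with sample_id, cultivar, resistance, fertilization, replicate.
#' @export
synth_design <- function(spec) {
  cultivars <- c(paste0("R", 1:5), paste0("S", 1:5))
  d <- expand.grid(replicate = seq_len(spec$n_replicates),
                   fertilization = c("control", "fertilized"),
                   cultivar = cultivars, stringsAsFactors = FALSE)
  d <- d[, c("cultivar", "fertilization", "replicate")]
  d$resistance <- ifelse(grepl("^R", d$cultivar), "resistant", "susceptible")
  d$sample_id <- sprintf("%s_%s_%d", d$cultivar,
                         substr(d$fertilization, 1, 4), d$replicate)
  d[, c("sample_id", "cultivar", "resistance", "fertilization", "replicate")]
}

#' Simulate an ultrametric pure-birth phylogeny
#'
#' @param n_taxa number of tips.
#' @param seed integer seed.
#' @param labels optional tip labels (length n_taxa); default t1..tn.
#' @return an ultrametric `phylo` with total depth scaled to 1.
#' @export
gen_tree <- function(n_taxa, seed, labels = NULL) {
  stopifnot(n_taxa >= 2)
  set.seed(seed)
  tr <- ape::rphylo(n_taxa, birth = 1, death = 0)
  depth <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length / depth
  if (!is.null(labels)) {
    stopifnot(length(labels) == n_taxa)
    tr$tip.label <- labels[as.integer(sub("^t", "", tr$tip.label))]
  }
  tr
}

# metacommunity relative abundances: lognormal ranked draw, normalized
meta_abundances <- function(spec) {
  set.seed(derive_seed(spec$seed, "metacommunity"))
  p <- stats::rlnorm(spec$n_taxa, spec$meta_mu, spec$meta_sigma)
  p / sum(p)
}

# Dirichlet-multinomial sampling core shared by the neutral and selected
# generators: column s of `pmat` is the source pool of sample s.
sample_counts <- function(pmat, N, m, seed, sample_names) {
  set.seed(seed)
  S <- ncol(pmat)
  out <- matrix(0L, nrow(pmat), S)
  for (s in seq_len(S)) {
    a <- N * m * pmat[, s]
    g <- stats::rgamma(length(a), shape = a)
    if (sum(g) <= 0) g <- pmat[, s]
    out[, s] <- stats::rmultinom(1L, N, g / sum(g))[, 1L]
  }
  rownames(out) <- rownames(pmat)
  colnames(out) <- sample_names
  out
}

taxon_labels <- function(spec, kingdom) {
  prefix <- if (kingdom == "bacteria") "b" else "f"
  sprintf("%s%04d", prefix, seq_len(spec$n_taxa))
}

#' Generate neutral-assembly counts
#'
#' Every sample's composition is a Dirichlet draw with concentration
#' N*m*p around the shared metacommunity p, then multinomial reads: the
#' stationary approximation of Sloan's neutral birth-death dynamics, which
#' is exactly the occupancy-abundance relationship the neutral-model fit
#' targets.
#'
#' @param spec a `synth_spec`.
#' @param kingdom kingdom tag.
#' @return a `count_table` over the full design.
#' @export
gen_neutral_counts <- function(spec, kingdom = "bacteria") {
  p <- meta_abundances(spec)
  des <- synth_design(spec)
  pmat <- matrix(p, spec$n_taxa, nrow(des))
  rownames(pmat) <- taxon_labels(spec, kingdom)
  m <- sample_counts(pmat, spec$reads_per_sample, spec$migration_m,
                     derive_seed(spec$seed, "counts"), des$sample_id)
  count_table(m, kingdom)
}

#' Generate counts under phylogenetic habitat selection
#'
#' Habitat optima evolve by Brownian motion on the tree (so selection is
#' phylogenetically autocorrelated, the signal betaNTI detects); resistant
#' and susceptible cultivar classes are opposite habitats (+1 / -1), and
#' each class's source pool reweights the metacommunity by
#' exp(selection_strength * optimum * habitat). At selection_strength = 0
#' this reduces bit-for-bit to [gen_neutral_counts()].
#'
#' @param spec a `synth_spec`.
#' @param tree `phylo` whose tips are the taxa (see [gen_tree()]).
#' @param kingdom kingdom tag.
#' @return a `count_table`.
#' @export
gen_selected_counts <- function(spec, tree, kingdom = "bacteria") {
  labels <- taxon_labels(spec, kingdom)
  stopifnot(setequal(tree$tip.label, labels))
  p <- meta_abundances(spec)
  names(p) <- labels
  des <- synth_design(spec)
  set.seed(derive_seed(spec$seed, "bm_optima"))
  z <- ape::rTraitCont(tree, model = "BM", sigma = 1)
  z <- (z - mean(z)) / stats::sd(z)
  habitat <- ifelse(des$resistance == "resistant", 1, -1)
  pmat <- vapply(habitat, function(h) {
    w <- p * exp(spec$selection_strength * z[labels] * h)
    w / sum(w)
  }, numeric(spec$n_taxa))
  rownames(pmat) <- labels
  m <- sample_counts(pmat, spec$reads_per_sample, spec$migration_m,
                     derive_seed(spec$seed, "counts"), des$sample_id)
  count_table(m, kingdom)
}

#' Planted-module covariance as a latent factor model
#'
#' Each module has a module factor F and two contrast factors. Hubs load
#' (almost) purely on F; ordinary members split into three groups loading
#' sqrt(0.8 w) on F plus sqrt(0.2 w) times a 120-degree unit contrast
#' vector (w = `within_module_corr`). Latent correlations are then: w
#' within a group, 0.7 w across groups (the contrasts cancel half their
#' share, keeping cross-group pairs below the default edge threshold),
#' and ~sqrt(0.8 w) between a hub and every member — well above it. That
#' contrast is what gives planted hubs their degree advantage at
#' realistic sample sizes, and makes them either within-module hubs (if
#' community detection merges the groups) or connectors (if it splits
#' them). The factor construction is positive definite for |corr| < 1.
#'
#' @param spec a `synth_spec`.
#' @return list: loading matrix `lambda` (taxa x 3 factors per module),
#'   logical `is_hub`, integer `module` (NA for background taxa).
#' @export
module_loadings <- function(spec) {
  w <- spec$within_module_corr
  if (w >= 1) abort("within_module_corr must be < 1")
  T <- spec$n_taxa
  nm <- spec$n_modules; ms <- spec$module_size; nh <- spec$n_hubs_per_module
  stopifnot(nh < ms)
  lambda <- matrix(0, T, 3L * nm)
  module <- rep(NA_integer_, T)
  is_hub <- rep(FALSE, T)
  hub_load <- sqrt(min(0.99, 1.2 * w + 0.03))
  contrast <- rbind(c(1, 0), c(-0.5, sqrt(3) / 2), c(-0.5, -sqrt(3) / 2))
  for (k in seq_len(nm)) {
    fm <- 3L * k - 2L                       # module factor column
    idx <- ((k - 1L) * ms + 1L):(k * ms)
    module[idx] <- k
    hubs <- idx[seq_len(nh)]
    rest <- setdiff(idx, hubs)
    grp <- split(rest, rep(1:3, length.out = length(rest)))
    for (h in 1:3) {
      lambda[grp[[h]], fm] <- sqrt(0.8 * w)
      lambda[grp[[h]], fm + 1:2] <- rep(sqrt(0.2 * w) * contrast[h, ],
                                        each = length(grp[[h]]))
    }
    lambda[hubs, fm] <- hub_load
    is_hub[hubs] <- TRUE
  }
  list(lambda = lambda, is_hub = is_hub, module = module)
}

#' Generate counts with planted correlation modules and hubs
#'
#' Latent log-abundances follow the factor covariance of
#' [module_loadings()]; samples are multinomial reads over the
#' exponentiated latents. Background taxa (outside modules) are
#' independent.
#'
#' @param spec a `synth_spec`.
#' @param kingdom kingdom tag.
#' @param sd_log standard deviation of latent log-abundance.
#' @return list: `table` (a `count_table`) and `truth` (module/hub ground truth).
#' @export
gen_correlated_abundances <- function(spec, kingdom = "bacteria", sd_log = 1.5) {
  ml <- module_loadings(spec)
  T <- spec$n_taxa
  des <- synth_design(spec)
  S <- nrow(des)
  set.seed(derive_seed(spec$seed, "modules"))
  f <- matrix(stats::rnorm(S * ncol(ml$lambda)), S)
  resid_sd <- sqrt(pmax(1 - rowSums(ml$lambda^2), 0))
  x <- f %*% t(ml$lambda) + matrix(stats::rnorm(S * T), S) * rep(resid_sd, each = S)
  base <- stats::rnorm(T, 0, 0.5)           # taxon-specific mean log-abundance
  base[ml$is_hub] <- 0.5                    # hubs equally, moderately abundant
  w <- exp(sweep(sd_log * x, 2L, base, "+")) # S x T abundance weights
  counts <- vapply(seq_len(S), function(s)
    stats::rmultinom(1L, spec$reads_per_sample, w[s, ])[, 1L], integer(T))
  labels <- taxon_labels(spec, kingdom)
  rownames(counts) <- labels
  colnames(counts) <- des$sample_id
  list(table = count_table(counts, kingdom),
       truth = list(module = stats::setNames(ml$module, labels),
                    hubs = labels[ml$is_hub]))
}

#' Generate sample metadata with soil and genotype-dependent yield
#'
#' Soil vectors are drawn from a fixed multivariate normal; yield is
#' intercept + b_soil * soilPC1 + b_kbs(class) * KBS + noise, where b_kbs
#' switches sign between resistant and susceptible cultivars and the
#' intercept is chosen (affine shift) so all yields are positive.
#'
#' @param spec a `synth_spec`.
#' @param kbs_abundance named numeric: per-sample KBS relative abundance
#'   (names = sample ids of [synth_design()]).
#' @return a `sample_metadata` data.frame.
#' @export
gen_metadata_yield <- function(spec, kbs_abundance) {
  des <- synth_design(spec)
  stopifnot(all(des$sample_id %in% names(kbs_abundance)))
  kbs <- kbs_abundance[des$sample_id]
  set.seed(derive_seed(spec$seed, "soil"))
  mu <- c(pH = 6.5, AP = 20, moisture = 25, DOC = 150, NH4N = 10, NO3N = 15)
  sds <- c(0.4, 5, 4, 30, 2.5, 4)
  R <- diag(6); R[lower.tri(R)] <- 0.3; R <- R + t(R) - diag(6) * 1
  diag(R) <- 1
  soil <- MASS::mvrnorm(nrow(des), mu = mu, Sigma = diag(sds) %*% R %*% diag(sds))
  colnames(soil) <- soil_vars()
  pc1 <- soil_pc1(soil)
  set.seed(derive_seed(spec$seed, "yield"))
  b_kbs <- ifelse(des$resistance == "resistant",
                  spec$b_kbs_resistant, spec$b_kbs_susceptible)
  y <- spec$b_soil * pc1 + b_kbs * kbs + stats::rnorm(nrow(des), 0, spec$noise_sd)
  y <- y - min(y) + 5   # affine shift onto a positive yield scale (t/ha-like)
  meta <- cbind(des, yield = y, as.data.frame(soil))
  as_metadata(meta)
}

#' First principal coordinate of the soil variables
#'
#' PCoA of Euclidean distances on z-scored soil variables (equivalently PCA
#' PC1); the sign is oriented to correlate positively with DOC so results
#' are deterministic.
#'
#' @param soil numeric matrix samples x 6 soil variables.
#' @return numeric vector, one score per sample.
#' @export
soil_pc1 <- function(soil) {
  z <- scale(as.matrix(soil))
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  s <- pc$x[, 1L]
  if (stats::cor(s, z[, "DOC"]) < 0) s <- -s
  unname(s)
}

#' Arbitrary labeled taxonomy for synthetic taxa
#'
#' One genus per taxon (Genus_<id>); classes cycle through a small set of
#' realistic bacterial or fungal class names so composition summaries have
#' structure.
#'
#' @param spec a `synth_spec`.
#' @param kingdom kingdom tag.
#' @return a `taxonomy` data.frame.
#' @export
gen_taxonomy <- function(spec, kingdom = "bacteria") {
  ids <- taxon_labels(spec, kingdom)
  classes <- if (kingdom == "bacteria")
    c("Bacilli", "Bacteroidia", "Gammaproteobacteria",
      "Alphaproteobacteria", "Actinobacteria")
  else c("Sordariomycetes", "Dothideomycetes", "Agaricomycetes",
         "Tremellomycetes", "Eurotiomycetes")
  phyla <- if (kingdom == "bacteria")
    c("Firmicutes", "Bacteroidetes", "Proteobacteria",
      "Proteobacteria", "Actinobacteria")
  else c("Ascomycota", "Ascomycota", "Basidiomycota",
         "Basidiomycota", "Ascomycota")
  k <- rep_len(seq_along(classes), length(ids))
  df <- data.frame(taxon_id = ids,
                   domain = if (kingdom == "bacteria") "Bacteria" else "Fungi",
                   phylum = phyla[k], class = classes[k],
                   order = paste0("Order_", ids), family = paste0("Family_", ids),
                   genus = paste0("Genus_", ids), species = "",
                   stringsAsFactors = FALSE)
  class(df) <- c("taxonomy", "data.frame")
  df
}

#' Draw the beneficial genus subset
#'
#' The beneficial set always contains the genera of the planted hub taxa
#' (so the keystone/specialist/beneficial screen has a recoverable ground
#' truth, mirroring the yield model's coupling to KBS abundance), padded
#' with random genera up to `beneficial_fraction` of all genera.
#'
#' @param spec a `synth_spec`.
#' @param taxonomy a `taxonomy` to draw genera from.
#' @param hub_taxa taxon ids of planted hubs to include (optional).
#' @return a `beneficial_list` at genus rank.
#' @export
gen_beneficial <- function(spec, taxonomy, hub_taxa = NULL) {
  set.seed(derive_seed(spec$seed, "beneficial"))
  genera <- unique(taxonomy$genus)
  n <- max(1L, round(spec$beneficial_fraction * length(genera)))
  seeded <- unique(taxonomy$genus[taxonomy$taxon_id %in% hub_taxa])
  pool <- setdiff(genera, seeded)
  fill <- sample(pool, max(0L, n - length(seeded)))
  beneficial_list(c(seeded, fill), "genus")
}

#' Write a complete synthetic study bundle
#'
#' Emits everything the pipeline reads: bacterial and fungal count tables
#' (independent spec instances so cross-kingdom edge accounting is
#' exercised), taxonomies, trees, metadata with yield, a beneficial list
#' and a ground-truth JSON.
#'
#' @param spec_b,spec_f `synth_spec` for bacteria and fungi (fungal spec
#'   defaults to the bacterial one with a shifted seed).
#' @param dir output directory (created).
#' @return invisibly, a named list of file paths plus the ground truth.
#' @export
synth_bundle <- function(spec_b, spec_f = NULL, dir) {
  if (is.null(spec_f)) {
    args <- spec_b
    class(args) <- NULL
    args$seed <- spec_b$seed + 1000L
    args$n_taxa <- max(50L, spec_b$n_taxa %/% 2L)
    args$n_modules <- max(1L, spec_b$n_modules %/% 2L)
    args$module_size <- min(spec_b$module_size,
                            args$n_taxa %/% (2L * args$n_modules))
    spec_f <- do.call(synth_spec, args)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  truth <- list(migration_m = spec_b$migration_m,
                yield = list(b_soil = spec_b$b_soil,
                             b_kbs_resistant = spec_b$b_kbs_resistant,
                             b_kbs_susceptible = spec_b$b_kbs_susceptible))
  tabs <- list()
  for (kd in c("bacteria", "fungi")) {
    sp <- if (kd == "bacteria") spec_b else spec_f
    tree <- gen_tree(sp$n_taxa, derive_seed(sp$seed, "tree"),
                     labels = taxon_labels(sp, kd))
    gen <- gen_correlated_abundances(sp, kd)
    tax <- gen_taxonomy(sp, kd)
    paths[[paste0("counts_", kd)]] <- write_count_table(
      gen$table, file.path(dir, paste0("counts_", kd, ".tsv")))
    paths[[paste0("taxonomy_", kd)]] <- write_taxonomy(
      tax, file.path(dir, paste0("taxonomy_", kd, ".tsv")))
    tp <- file.path(dir, paste0("tree_", kd, ".nwk"))
    ape::write.tree(tree, tp)
    paths[[paste0("tree_", kd)]] <- tp
    truth[[kd]] <- list(module = as.list(gen$truth$module), hubs = gen$truth$hubs)
    tabs[[kd]] <- gen$table
  }
  tax_b <- gen_taxonomy(spec_b, "bacteria")
  ben <- gen_beneficial(spec_b, tax_b, hub_taxa = truth$bacteria$hubs)
  bp <- file.path(dir, "beneficial.tsv")
  utils::write.table(data.frame(key = ben$keys), bp, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths$beneficial <- bp
  truth$beneficial <- ben$keys
  # KBS stand-in for yield coupling: summed relative abundance of the
  # beneficial hub taxa (the taxa the screen is designed to find)
  rel <- prop.table(tabs$bacteria$counts, 2L)
  hub_ids <- truth$bacteria$hubs
  ben_hubs <- hub_ids[paste0("Genus_", hub_ids) %in% ben$keys]
  kbs_ab <- if (length(ben_hubs)) colSums(rel[ben_hubs, , drop = FALSE])
            else colSums(rel[hub_ids[1], , drop = FALSE])
  meta <- gen_metadata_yield(spec_b, kbs_ab)
  paths$metadata <- write_metadata(meta, file.path(dir, "metadata.tsv"))
  truth$kbs_proxy_taxa <- if (length(ben_hubs)) ben_hubs else hub_ids[1]
  gt <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(truth, gt, auto_unbox = TRUE, digits = NA)
  paths$ground_truth <- gt
  invisible(c(paths, list(truth = truth)))
}
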