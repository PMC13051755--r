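#' Build a signed Spearman co-occurrence network
#'
#' Taxa from one or two kingdoms (converted to per-kingdom relative
#' abundances, then merged over shared samples) are prefiltered to a
#' minimum prevalence, all pairwise Spearman correlations are computed with
#' mid-ranks, p-values come from the t approximation, and edges are kept
#' when |rho| > `rho_min` and p < `p_max` (raw p by default, as the
#' thresholding is defined; optional BH correction). Isolated nodes are
#' dropped; constant taxon vectors are skipped with a log message.
#'
#' @param tables a `count_table` or list of them (e.g. bacteria + fungi);
#'   sample sets are intersected.
#' @param rho_min correlation magnitude threshold (default 0.6).
#' @param p_max p-value threshold (default 0.01).
#' @param prevalence_min keep taxa present in at least this fraction of
#'   samples (default 0.2).
#' @param fdr apply Benjamini-Hochberg correction to edge p-values.
#' @return list of class `co_network`: `graph` (igraph), `nodes`
#'   (taxon_id, kingdom, mean_rel_abund, degree, betweenness), `edges`
#'   (from, to, rho, p, sign, kingdom_pair), `n_samples`.
#' @export
build_network <- function(tables, rho_min = 0.6, p_max = 0.01,
                          prevalence_min = 0.2, fdr = FALSE) {
  if (inherits(tables, "count_table")) tables <- list(tables)
  samples <- Reduce(intersect, lapply(tables, sample_ids))
  if (length(samples) < 4L) abort("need >= 4 shared samples")
  mats <- lapply(tables, function(tb) {
    rel <- prop.table(tb$counts[, samples, drop = FALSE], 2L)
    keep <- rowMeans(rel > 0) >= prevalence_min
    rel[keep, , drop = FALSE]
  })
  kingdom <- rep(vapply(tables, function(tb) tb$kingdom, character(1)),
                 vapply(mats, nrow, integer(1)))
  m <- do.call(rbind, mats)
  if (anyDuplicated(rownames(m))) abort("duplicate taxon ids across tables")
  const <- apply(m, 1L, function(v) length(unique(v)) == 1L)
  if (any(const)) {
    log_msg("build_network: skipping %d constant taxon vector(s)", sum(const))
    m <- m[!const, , drop = FALSE]
    kingdom <- kingdom[!const]
  }
  n <- length(samples)
  ranks <- t(apply(m, 1L, rank))        # mid-ranks for ties
  rho <- stats::cor(t(ranks))
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(rho) >= 1 - 1e-12] <- 0
  ut <- upper.tri(rho)
  if (fdr) p[ut] <- stats::p.adjust(p[ut], "BH")
  pass <- ut & abs(rho) > rho_min & p < p_max
  idx <- which(pass, arr.ind = TRUE)
  taxa <- rownames(m)
  kd <- stats::setNames(kingdom, taxa)
  edges <- data.frame(from = taxa[idx[, 1L]], to = taxa[idx[, 2L]],
                      rho = rho[pass], p = p[pass],
                      sign = ifelse(rho[pass] > 0, "positive", "negative"),
                      stringsAsFactors = FALSE)
  edges$kingdom_pair <- kingdom_pair(kd[edges$from], kd[edges$to])
  g <- igraph::graph_from_data_frame(edges[, c("from", "to")],
                                     directed = FALSE)
  nodes <- data.frame(taxon_id = igraph::V(g)$name,
                      kingdom = kd[igraph::V(g)$name],
                      mean_rel_abund = rowMeans(m)[igraph::V(g)$name],
                      degree = igraph::degree(g),
                      betweenness = igraph::betweenness(g, directed = FALSE,
                                                        weights = NA),
                      stringsAsFactors = FALSE)
  rownames(nodes) <- NULL
  structure(list(graph = g, nodes = nodes, edges = edges, n_samples = n),
            class = "co_network")
}

# field notation: BB, FF within kingdom, FB across
kingdom_pair <- function(a, b) {
  ifelse(a == b, ifelse(a == "bacteria", "BB", "FF"), "FB")
}

#' @export
print.co_network <- function(x, ...) {
  cat(sprintf("co_network: %d nodes, %d edges (%d samples)\n",
              nrow(x$nodes), nrow(x$edges), x$n_samples))
  invisible(x)
}

#' Network topology summary
#'
#' @param net a `co_network`.
#' @return list: n_nodes, n_edges, avg_degree (2E/N), betweenness summary,
#'   and edge proportions by kingdom pair (BB/FB/FF) x sign.
#' @export
net_topology <- function(net) {
  tab <- table(net$edges$kingdom_pair, net$edges$sign)
  list(n_nodes = nrow(net$nodes), n_edges = nrow(net$edges),
       avg_degree = 2 * nrow(net$edges) / nrow(net$nodes),
       betweenness = summary(net$nodes$betweenness),
       edge_proportions = tab / sum(tab))
}

#' Detect modules by modularity maximization
#'
#' Seeded Louvain on the unweighted simple graph. Modules smaller than
#' `min_size` are merged into a "rest" pool (module 0) that is excluded
#' from Zi standardization.
#'
#' @param net a `co_network`.
#' @param seed integer seed.
#' @param min_size minimum module size (default 3).
#' @return the network with a `module` column added to `nodes`.
#' @export
detect_modules <- function(net, seed = 1L, min_size = 3L) {
  set.seed(seed)
  cl <- igraph::cluster_louvain(net$graph)
  mem <- igraph::membership(cl)
  sizes <- table(mem)
  small <- as.integer(names(sizes)[sizes < min_size])
  mem[mem %in% small] <- 0L
  ids <- sort(unique(mem[mem != 0L]))
  mem[mem != 0L] <- match(mem[mem != 0L], ids)
  net$nodes$module <- as.integer(mem[net$nodes$taxon_id])
  net
}

#' Within-module (Zi) and among-module (Pi) connectivity roles
#'
#' Zi is the z-score of a node's within-module degree relative to the other
#' nodes of its module (modules with zero spread, or the "rest" pool, give
#' Zi = 0); Pi = 1 - sum_s (k_is / k_i)^2 over modules s. Roles: module hub
#' (Zi > 2.5), connector (Pi > 0.62), network hub (both), else peripheral.
#' Keystone taxa are all non-peripheral nodes; the keystone score
#' sqrt((Zi/2.5)^2 + (Pi/0.62)^2) is a threshold-normalized proxy combining
#' both axes.
#'
#' @param net a `co_network` with modules (see [detect_modules()]).
#' @param zi_hub Zi threshold (default 2.5).
#' @param pi_connector Pi threshold (default 0.62).
#' @return the network with Zi, Pi, role, keystone and keystone_score
#'   columns added to `nodes`.
#' @export
zi_pi <- function(net, zi_hub = 2.5, pi_connector = 0.62) {
  if (is.null(net$nodes$module)) abort("run detect_modules() first")
  adj <- igraph::as_adjacency_matrix(net$graph, sparse = FALSE)
  adj <- adj[net$nodes$taxon_id, net$nodes$taxon_id]
  mod <- net$nodes$module
  mods <- sort(unique(mod))
  # k_is: links of node i into module s
  k_is <- vapply(mods, function(s) rowSums(adj[, mod == s, drop = FALSE]),
                 numeric(nrow(adj)))
  k <- rowSums(k_is)
  pi_val <- 1 - rowSums((k_is / pmax(k, 1))^2)
  pi_val[k == 0] <- 0
  k_within <- k_is[cbind(seq_along(mod), match(mod, mods))]
  zi <- numeric(length(mod))
  for (s in setdiff(mods, 0L)) {
    in_s <- mod == s
    mu <- mean(k_within[in_s]); sdv <- stats::sd(k_within[in_s])
    zi[in_s] <- if (is.na(sdv) || sdv == 0) 0 else (k_within[in_s] - mu) / sdv
  }
  role <- ifelse(zi > zi_hub & pi_val > pi_connector, "network_hub",
          ifelse(zi > zi_hub, "module_hub",
          ifelse(pi_val > pi_connector, "connector", "peripheral")))
  net$nodes$Zi <- zi
  net$nodes$Pi <- pi_val
  net$nodes$role <- factor(role, levels = c("peripheral", "module_hub",
                                            "connector", "network_hub"))
  net$nodes$keystone <- role != "peripheral"
  net$nodes$keystone_score <- sqrt((zi / zi_hub)^2 + (pi_val / pi_connector)^2)
  net
}

#' Keystone-score regressions against network metrics
#'
#' Pearson correlations of log-transformed keystone scores with
#' betweenness centrality and degree over keystone nodes, optionally
#' restricted to specialist keystones.
#'
#' @param net a `co_network` after [zi_pi()].
#' @param niche_labels optional named factor of niche labels per taxon (for
#'   the specialist-restricted regression).
#' @return data.frame: subset, metric, n, r, p.
#' @export
keystone_regressions <- function(net, niche_labels = NULL) {
  ks <- net$nodes[net$nodes$keystone, , drop = FALSE]
  one <- function(sub, name) {
    do.call(rbind, lapply(c("betweenness", "degree"), function(metric) {
      if (nrow(sub) < 3L || stats::sd(sub[[metric]]) == 0 ||
          stats::sd(log(sub$keystone_score)) == 0)
        return(data.frame(subset = name, metric = metric, n = nrow(sub),
                          r = NA_real_, p = NA_real_))
      ct <- stats::cor.test(log(sub$keystone_score), sub[[metric]])
      data.frame(subset = name, metric = metric, n = nrow(sub),
                 r = unname(ct$estimate), p = ct$p.value)
    }))
  }
  out <- one(ks, "all_keystones")
  if (!is.null(niche_labels)) {
    spec <- ks[niche_labels[ks$taxon_id] == "specialist", , drop = FALSE]
    out <- rbind(out, one(spec, "specialist_keystones"))
  }
  rownames(out) <- NULL
  out
}
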