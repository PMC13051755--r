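# fixture builders and independent oracles shared across test files

# small deterministic count table
tiny_table <- function() {
  m <- matrix(c(5L, 0L, 3L,
                0L, 2L, 1L,
                7L, 7L, 0L), nrow = 3, byrow = TRUE,
              dimnames = list(c("t1", "t2", "t3"), c("s1", "s2", "s3")))
  count_table(m, "bacteria")
}

write_tsv_table <- function(x, path = tempfile(fileext = ".tsv")) {
  write_count_table(x, path)
  path
}

# the 4-tip reference tree used throughout: ((a:1,b:1):1,(c:1,d:1):1);
four_tip_tree <- function() {
  ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
}

# brute-force double-loop betaMNTD oracle, independent of the package path
bmntd_oracle <- function(counts, d, i, j, weighted = TRUE) {
  a <- counts[, i]; b <- counts[, j]
  A <- which(a > 0); B <- which(b > 0)
  fa <- if (weighted) a[A] / sum(a[A]) else rep(1 / length(A), length(A))
  fb <- if (weighted) b[B] / sum(b[B]) else rep(1 / length(B), length(B))
  s1 <- 0
  for (k in seq_along(A)) {
    dm <- Inf
    for (l in seq_along(B)) dm <- min(dm, d[A[k], B[l]])
    s1 <- s1 + fa[k] * dm
  }
  s2 <- 0
  for (l in seq_along(B)) {
    dm <- Inf
    for (k in seq_along(A)) dm <- min(dm, d[B[l], A[k]])
    s2 <- s2 + fb[l] * dm
  }
  unname((s1 + s2) / 2)
}

# engineered 9-taxon x 12-sample counts: equal column totals, and exactly
# five taxon pairs pass |rho| > 0.6 & p < 0.01 (verified by the in-test
# all-pairs oracle): (t1,t2), (t3,t4), (t5,t6), (t5,t7), (t6,t7)
five_edge_fixture <- function() {
  m <- matrix(c(1, 9, 11, 7, 12, 4, 8, 6, 5, 10, 2, 3,
                1, 9, 8, 7, 12, 4, 5, 6, 11, 10, 2, 3,
                4, 7, 10, 12, 6, 3, 5, 1, 9, 2, 11, 8,
                5, 6, 10, 12, 3, 4, 2, 1, 9, 7, 11, 8,
                6, 1, 3, 8, 4, 11, 2, 10, 5, 12, 9, 7,
                6, 1, 3, 4, 8, 11, 2, 12, 7, 10, 9, 5,
                6, 1, 8, 4, 3, 11, 2, 12, 7, 10, 9, 5,
                9, 4, 10, 7, 1, 3, 8, 6, 12, 2, 5, 11),
              nrow = 8, ncol = 12, byrow = TRUE)
  counts <- m * 10L
  filler <- 1000L - colSums(counts)
  cnt <- rbind(counts, filler)
  dimnames(cnt) <- list(c(paste0("t", 1:8), "t9"), paste0("s", 1:12))
  count_table(cnt, "bacteria")
}

# all-pairs Spearman edge oracle (explicit ranks + t approximation)
edge_oracle <- function(x, rho_min = 0.6, p_max = 0.01) {
  rel <- prop.table(x$counts, 2)
  n <- ncol(rel)
  taxa <- rownames(rel)
  out <- NULL
  for (i in seq_len(nrow(rel) - 1)) for (j in (i + 1):nrow(rel)) {
    r <- stats::cor(rank(rel[i, ]), rank(rel[j, ]))
    tt <- r * sqrt((n - 2) / max(1 - r^2, 1e-15))
    p <- if (abs(r) >= 1 - 1e-12) 0 else 2 * stats::pt(-abs(tt), n - 2)
    if (abs(r) > rho_min && p < p_max)
      out <- rbind(out, data.frame(from = taxa[i], to = taxa[j], rho = r))
  }
  out
}

# sum over all directed paths of products of coefficients (DAG oracle)
total_effect_oracle <- function(B_std, from, to) {
  v <- colnames(B_std)
  total <- 0
  recurse <- function(node, acc) {
    heads <- v[B_std[, node] != 0]
    for (h in heads) {
      w <- acc * B_std[h, node]
      if (h == to) total <<- total + w else recurse(h, w)
    }
  }
  recurse(from, 1)
  total
}

# hand-built co_network with known module structure (for Zi/Pi closed forms)
manual_network <- function(edges, modules) {
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  nodes <- data.frame(taxon_id = igraph::V(g)$name,
                      kingdom = "bacteria",
                      mean_rel_abund = 1 / length(igraph::V(g)),
                      degree = igraph::degree(g),
                      betweenness = igraph::betweenness(g, directed = FALSE,
                                                        weights = NA),
                      stringsAsFactors = FALSE)
  nodes$module <- modules[nodes$taxon_id]
  structure(list(graph = g, nodes = nodes,
                 edges = cbind(edges, rho = 1, p = 0, sign = "positive",
                               kingdom_pair = "BB"),
                 n_samples = NA_integer_),
            class = "co_network")
}

# build a minimal screened environment with hand-placed sets
fake_screen_inputs <- function(keystone, specialist, beneficial_genera,
                               taxa = sprintf("t%02d", 1:12)) {
  nodes <- data.frame(taxon_id = taxa, kingdom = "bacteria",
                      mean_rel_abund = 1 / length(taxa),
                      degree = 1, betweenness = 0,
                      module = 1L, Zi = 0, Pi = 0,
                      role = factor(ifelse(taxa %in% keystone, "module_hub",
                                           "peripheral"),
                                    levels = c("peripheral", "module_hub",
                                               "connector", "network_hub")),
                      keystone = taxa %in% keystone,
                      keystone_score = 1,
                      stringsAsFactors = FALSE)
  net <- structure(list(graph = NULL, nodes = nodes,
                        edges = data.frame(), n_samples = 10L),
                   class = "co_network")
  niche <- data.frame(taxon_id = taxa, b_obs = 2, null_mean = 3,
                      null_lo = 1.5, null_hi = 4,
                      label = factor(ifelse(taxa %in% specialist,
                                            "specialist", "neutral_taxon"),
                                     levels = c("specialist", "neutral_taxon",
                                                "generalist")),
                      single_sample = FALSE, stringsAsFactors = FALSE)
  class(niche) <- c("niche_classification", "data.frame")
  tax <- data.frame(taxon_id = taxa, domain = "Bacteria", phylum = "P",
                    class = rep(c("Bacilli", "Bacteroidia"), 6),
                    order = "", family = "",
                    genus = paste0("Genus_", taxa), species = "",
                    stringsAsFactors = FALSE)
  class(tax) <- c("taxonomy", "data.frame")
  ben <- beneficial_list(beneficial_genera, "genus")
  list(net = net, niche = niche, tax = tax, ben = ben)
}
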