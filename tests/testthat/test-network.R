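test_that("monotone pairs produce signed edges at the thresholds", {
  m <- matrix(0L, 3, 10, dimnames = list(c("up", "up2", "down"),
                                         paste0("s", 1:10)))
  m["up", ] <- as.integer(1:10 * 10)
  m["up2", ] <- as.integer((1:10)^2)
  m["down", ] <- as.integer(10:1 * 10)
  filler <- as.integer(2000 - colSums(m))
  cnt <- rbind(m, filler = filler)
  net <- suppressMessages(build_network(count_table(cnt, "bacteria"),
                                        prevalence_min = 0))
  e <- net$edges
  key <- paste(pmin(e$from, e$to), pmax(e$from, e$to))
  expect_true("up up2" %in% key)
  expect_identical(e$sign[key == "up up2"], "positive")
  expect_identical(e$sign[key == "down up"], "negative")
  expect_equal(abs(e$rho[key == "down up"]), 1)
})

test_that("the engineered fixture yields exactly the oracle's five edges", {
  tb <- five_edge_fixture()
  net <- build_network(tb, prevalence_min = 0)
  expect_identical(nrow(net$edges), 5L)
  oracle <- edge_oracle(tb)
  expect_identical(nrow(oracle), 5L)
  got <- paste(pmin(net$edges$from, net$edges$to),
               pmax(net$edges$from, net$edges$to))
  want <- paste(pmin(oracle$from, oracle$to), pmax(oracle$from, oracle$to))
  expect_setequal(got, want)
  # network is invariant to sample and taxon ordering
  perm_t <- sample(nrow(tb$counts)); perm_s <- sample(ncol(tb$counts))
  net2 <- build_network(count_table(tb$counts[perm_t, perm_s], "bacteria"),
                        prevalence_min = 0)
  got2 <- paste(pmin(net2$edges$from, net2$edges$to),
                pmax(net2$edges$from, net2$edges$to))
  expect_setequal(got2, got)
})

test_that("topology summaries match closed forms on simple graphs", {
  tri <- manual_network(data.frame(from = c("a", "b", "c"),
                                   to = c("b", "c", "a")),
                        c(a = 1L, b = 1L, c = 1L))
  expect_equal(net_topology(tri)$avg_degree, 2)
  expect_true(all(tri$nodes$betweenness == 0))
  path <- manual_network(data.frame(from = c("a", "b"), to = c("b", "c")),
                         c(a = 1L, b = 1L, c = 1L))
  expect_equal(path$nodes$betweenness[path$nodes$taxon_id == "b"], 1)
  expect_equal(sum(net_topology(tri)$edge_proportions), 1)
})

test_that("module detection separates disjoint cliques and is seeded", {
  clique <- function(v) t(combn(v, 2))
  edges <- as.data.frame(rbind(clique(paste0("a", 1:4)),
                               clique(paste0("b", 1:4))))
  names(edges) <- c("from", "to")
  net <- manual_network(edges, NULL)
  net$nodes$module <- NULL
  net <- detect_modules(net, seed = 5)
  expect_identical(length(unique(net$nodes$module)), 2L)
  agree <- table(substr(net$nodes$taxon_id, 1, 1), net$nodes$module)
  expect_true(all(rowSums(agree > 0) == 1))   # each clique in one module
  net2 <- detect_modules(net, seed = 5)
  expect_identical(net$nodes$module, net2$nodes$module)
})

test_that("planted-partition graphs are recovered almost exactly", {
  set.seed(10)
  n_per <- 25; k <- 4
  truth <- rep(seq_len(k), each = n_per)
  n <- n_per * k
  prob <- ifelse(outer(truth, truth, "=="), 0.3, 0.01)
  adj <- matrix(runif(n * n) < prob, n, n)
  adj[lower.tri(adj, diag = TRUE)] <- FALSE
  idx <- which(adj, arr.ind = TRUE)
  ids <- sprintf("v%03d", seq_len(n))
  net <- manual_network(data.frame(from = ids[idx[, 1]], to = ids[idx[, 2]]),
                        NULL)
  net$nodes$module <- NULL
  net <- detect_modules(net, seed = 3)
  got <- net$nodes$module[match(ids, net$nodes$taxon_id)]
  keep <- !is.na(got)
  # adjusted Rand index against the planted partition
  tab <- table(got[keep], truth[keep])
  a <- sum(choose(tab, 2)); b <- sum(choose(rowSums(tab), 2))
  cc <- sum(choose(colSums(tab), 2)); nn <- choose(sum(tab), 2)
  ari <- (a - b * cc / nn) / ((b + cc) / 2 - b * cc / nn)
  expect_gte(ari, 0.9)
})

test_that("Zi and Pi match their closed forms and role thresholds", {
  # center node with degree 4 split evenly over 4 cliques -> Pi = 0.75
  clique <- function(v) t(combn(v, 2))
  edges <- do.call(rbind, lapply(letters[1:4], function(l)
    clique(paste0(l, 1:4))))
  edges <- rbind(edges, cbind("hub", paste0(letters[1:4], 1)))
  edges <- data.frame(from = edges[, 1], to = edges[, 2])
  mods <- c(stats::setNames(rep(1:4, each = 4),
                            paste0(rep(letters[1:4], each = 4), 1:4)),
            hub = 1L)
  net <- zi_pi(manual_network(edges, mods))
  hub <- net$nodes[net$nodes$taxon_id == "hub", ]
  expect_equal(hub$Pi, 1 - 4 * (1 / 16))
  expect_identical(as.character(hub$role), "connector")
  expect_true(hub$keystone)
  # all links inside own module -> Pi = 0
  a2 <- net$nodes[net$nodes$taxon_id == "a2", ]
  expect_equal(a2$Pi, 0)
  # Zi standardization: per-module mean 0, sd 1 where defined
  for (s in unique(net$nodes$module)) {
    zi <- net$nodes$Zi[net$nodes$module == s]
    if (length(zi) > 1 && stats::sd(zi) > 0) {
      expect_equal(mean(zi), 0, tolerance = 1e-12)
      expect_equal(stats::sd(zi), 1, tolerance = 1e-12)
    }
  }
  # keystone score closed form: Zi = 2.5, Pi = 0 -> 1
  expect_equal(sqrt((2.5 / 2.5)^2 + (0 / 0.62)^2), 1)
  expect_true(all(net$nodes$keystone_score >= 0))
})

test_that("module-hub z-scores are rare on random graphs", {
  set.seed(6)
  n <- 150
  adj <- matrix(runif(n * n) < 0.08, n, n)
  adj[lower.tri(adj, diag = TRUE)] <- FALSE
  idx <- which(adj, arr.ind = TRUE)
  ids <- sprintf("v%03d", seq_len(n))
  net <- manual_network(data.frame(from = ids[idx[, 1]], to = ids[idx[, 2]]),
                        NULL)
  net$nodes$module <- NULL
  net <- zi_pi(detect_modules(net, seed = 2))
  expect_lt(mean(net$nodes$Zi > 2.5), 0.05)
})

test_that("keystone regressions report correlations over keystone nodes", {
  sp <- synth_spec(n_taxa = 120, reads_per_sample = 20000, seed = 5)
  gen <- gen_correlated_abundances(sp)
  net <- zi_pi(detect_modules(build_network(gen$table), seed = 2))
  labels <- stats::setNames(
    rep("specialist", nrow(net$nodes)), net$nodes$taxon_id)
  reg <- keystone_regressions(net, labels)
  expect_true(all(c("all_keystones", "specialist_keystones") %in% reg$subset))
  expect_true(all(is.na(reg$r) | abs(reg$r) <= 1))
})
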