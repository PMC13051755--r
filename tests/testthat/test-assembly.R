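test_that("betaMNTD matches closed forms on the 4-tip tree", {
  tr <- four_tip_tree()
  m <- matrix(0L, 4, 3, dimnames = list(c("a", "b", "c", "d"),
                                        c("sA", "sB", "sC")))
  m["a", "sA"] <- 5L
  m["c", "sB"] <- 7L
  m[c("a", "c"), "sC"] <- c(2L, 2L)
  tb <- count_table(m, "bacteria")
  b <- beta_mntd(tb, tr)
  expect_equal(b["sA", "sA"], 0)
  expect_equal(b["sA", "sB"], 4)         # single patristic distance a-c
  expect_equal(b["sC", "sC"], 0)
  # shared taxa contribute zero nearest-taxon distance
  expect_equal(b["sA", "sC"], (1 * 0 + (0.5 * 0 + 0.5 * 4)) / 2)
})

test_that("betaMNTD equals the brute-force double-loop oracle", {
  for (s in 1:5) {
    set.seed(s)
    tr <- ape::rtree(6)
    d <- ape::cophenetic.phylo(tr)
    m <- matrix(rpois(6 * 4, 2), 6, 4,
                dimnames = list(tr$tip.label, paste0("s", 1:4)))
    m[, colSums(m) == 0] <- 1L
    tb <- count_table(m, "bacteria")
    d <- d[taxon_ids(tb), taxon_ids(tb)]
    got <- beta_mntd(tb, tr)
    for (i in 1:3) for (j in (i + 1):4)
      expect_equal(got[i, j], bmntd_oracle(m, d, i, j), tolerance = 1e-12)
    # unweighted mode agrees with the oracle under uniform weights
    gotu <- beta_mntd(tb, tr, weighted = FALSE)
    expect_equal(gotu[1, 2], bmntd_oracle(m, d, 1, 2, weighted = FALSE),
                 tolerance = 1e-12)
  }
})

test_that("betaMNTD agrees with an independent reference implementation", {
  skip_if_not_installed("picante")
  set.seed(42)
  tr <- ape::rtree(8)
  m <- matrix(rpois(8 * 5, 3), 8, 5,
              dimnames = list(tr$tip.label, paste0("s", 1:5)))
  m[1, colSums(m) == 0] <- 1L
  tb <- count_table(m, "bacteria")
  ref <- as.matrix(picante::comdistnt(t(m), ape::cophenetic.phylo(tr),
                                      abundance.weighted = TRUE))
  got <- beta_mntd(tb, tr)
  expect_equal(got[rownames(ref), colnames(ref)], ref, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("betaNTI is invariant to global branch-length scaling", {
  set.seed(3)
  tr <- ape::rtree(12)
  m <- matrix(rpois(12 * 5, 3), 12, 5,
              dimnames = list(tr$tip.label, paste0("s", 1:5)))
  tb <- count_table(m, "bacteria")
  b1 <- suppressWarnings(beta_nti(tb, tr, n_null = 49, seed = 11))
  tr2 <- tr; tr2$edge.length <- tr2$edge.length * 100
  b2 <- suppressWarnings(beta_nti(tb, tr2, n_null = 49, seed = 11))
  expect_equal(b1$bnti, b2$bnti, tolerance = 1e-9)
})

test_that("a permutation-invariant configuration yields undefined betaNTI", {
  # star tree with equal branch lengths: tip shuffles change nothing
  tr <- ape::read.tree(text = "(a:1,b:1,c:1,d:1);")
  m <- matrix(c(1L, 0L, 0L, 0L, 0L, 1L, 0L, 0L), 4, 2,
              dimnames = list(c("a", "b", "c", "d"), c("s1", "s2")))
  tb <- count_table(m, "bacteria")
  expect_warning(res <- beta_nti(tb, tr, n_null = 19, seed = 1), "undefined")
  expect_true(is.na(res$bnti["s1", "s2"]))
})

test_that("Raup-Crick stays in bounds and flags coincident samples", {
  sp <- synth_spec(n_taxa = 80, reads_per_sample = 300, meta_sigma = 2,
                   seed = 14)
  tb <- gen_neutral_counts(sp)
  sub <- count_table(tb$counts[rowSums(tb$counts) > 0, 1:6], "bacteria")
  rc <- rc_bray(sub, n_null = 99, seed = 4)
  off <- rc[upper.tri(rc)]
  expect_true(all(off >= -1 & off <= 1))
  expect_equal(rc, t(rc))
  # two identical samples drawn from a heterogeneous pool are far more
  # similar than richness-preserving null assemblies: RC -> -1
  m2 <- sub$counts
  m2[, 2] <- m2[, 1]
  rc2 <- rc_bray(count_table(m2, "bacteria"), n_null = 99, seed = 4)
  expect_lt(rc2[1, 2], -0.95)
})

test_that("process assignment follows the betaNTI / RC thresholds", {
  bnti <- c(-2.5, 2.5, 0, 0, 0, NA)
  rc <- c(0, 0, 0.96, -0.96, 0, 0)
  got <- assign_process(bnti, rc)
  expect_identical(as.character(got[1:5]),
                   c("homogeneous_selection", "heterogeneous_selection",
                     "dispersal_limitation", "homogenizing_dispersal",
                     "drift"))
  expect_true(is.na(got[6]))
  fr <- process_fractions(got)
  expect_equal(sum(fr), 1)
})

test_that("assembly analysis covers each within-group pair exactly once", {
  sp <- synth_spec(n_taxa = 50, reads_per_sample = 400, seed = 17)
  tb <- filter_low_count(gen_neutral_counts(sp), 5)
  tree <- gen_tree(50, seed = 2, labels = sprintf("b%04d", 1:50))
  cls <- factor(synth_design(sp)$resistance)
  keep <- c(1:5, 31:35)
  sub <- count_table(tb$counts[, keep], "bacteria")
  res <- suppressWarnings(
    assembly_analysis(sub, tree, cls[keep], n_null = 29, seed = 3))
  expect_equal(nrow(res$pairs), 2 * choose(5, 2))
  key <- with(res$pairs, paste(pmin(sample_1, sample_2),
                               pmax(sample_1, sample_2)))
  expect_false(anyDuplicated(key) > 0)
  expect_true(all(rowSums(res$fractions) - 1 < 1e-12))
  # pairs never straddle groups
  g <- stats::setNames(as.character(cls[keep]), sample_ids(sub))
  expect_true(all(g[res$pairs$sample_1] == g[res$pairs$sample_2]))
})
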