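test_that("richness counts taxa with positive counts per sample", {
  m <- matrix(0L, 5, 3, dimnames = list(paste0("t", 1:5), paste0("s", 1:3)))
  m[1:4, 1] <- 1L; m[2, 2] <- 9L
  tb <- count_table(m, "bacteria")
  expect_equal(unname(richness(tb)), c(4, 1, 0))
})

test_that("Bray-Curtis matches its closed form", {
  m <- matrix(c(1L, 2L, 2L, 1L, 3L, 3L, 1L, 0L), 2, 4,
              dimnames = list(c("a", "b"), paste0("s", 1:4)))
  tb <- count_table(m, "bacteria")
  d <- as.matrix(bray_curtis(tb))
  expect_equal(d["s1", "s2"], 2 / 6)     # |1-2|+|2-1| over 1+2+2+1
  expect_equal(d["s1", "s3"], 3 / 9)     # |1-3|+|2-3| over 1+2+3+3
  expect_equal(d["s3", "s4"], (2 + 3) / 7)
  expect_true(all(d >= 0 & d <= 1))
  expect_equal(d, t(d))
})

test_that("PCoA embeds Euclidean configurations exactly", {
  set.seed(8)
  pts <- cbind(runif(9), runif(9))
  rownames(pts) <- paste0("s", 1:9)
  d <- dist(pts)
  ord <- pcoa(d)
  # recovered coordinates reproduce all pairwise distances
  expect_equal(as.matrix(dist(ord$coords[, 1:2])), as.matrix(d),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_lte(sum(ord$prop_explained), 1 + 1e-12)
  expect_true(all(diff(ord$eig) <= 1e-12))   # descending eigenvalues
  # points on a line need one axis only
  line <- dist(cbind(c(0, 1, 3, 7)))
  expect_identical(ncol(pcoa(line)$coords), 1L)
  bad <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(pcoa(bad), "symmetric")
})

test_that("PCoA never errors on Bray-Curtis input and logs negative mass", {
  sp <- synth_spec(n_taxa = 40, reads_per_sample = 200, seed = 12)
  tb <- gen_neutral_counts(sp)
  ord <- suppressMessages(pcoa(bray_curtis(tb)))
  expect_true(is.finite(ord$negative_mass))
  expect_true(all(ord$eig > 0))
})

test_that("PERMANOVA attains the minimal p on separated clusters", {
  g <- rep(c("A", "B"), each = 6)
  pts <- rbind(matrix(rnorm(12, 0), 6), matrix(rnorm(12, 50), 6))
  res <- permanova(dist(pts), g, n_perm = 199, seed = 2)
  expect_equal(res$p, 1 / 200)
  expect_gt(res$R2, 0.9)

  # near-identical duplicated points across groups: no signal
  pts2 <- rbind(matrix(1:12, 6, 2), matrix(1:12, 6, 2) + 1e-6)
  res2 <- permanova(dist(pts2), g, n_perm = 199, seed = 2)
  expect_gt(res2$p, 0.05)
  expect_error(permanova(dist(pts), c("A", rep("B", 11)), seed = 1),
               ">= 2 samples")
})

test_that("PERMANOVA p is invariant to label renaming and joint reordering", {
  set.seed(5)
  pts <- matrix(rnorm(24), 12)
  g <- rep(c("A", "B"), each = 6)
  d <- as.matrix(dist(pts))
  p1 <- permanova(d, g, n_perm = 199, seed = 9)$p
  p2 <- permanova(d, ifelse(g == "A", "grp1", "grp2"), n_perm = 199, seed = 9)$p
  perm <- sample(12)
  p3 <- permanova(d[perm, perm], g[perm], n_perm = 199, seed = 9)$p
  expect_identical(p1, p2)
  f1 <- permanova(d, g, n_perm = 99, seed = 1)$pseudo_F
  f3 <- permanova(d[perm, perm], g[perm], n_perm = 99, seed = 1)$pseudo_F
  expect_equal(f1, f3)
  expect_lt(abs(p1 - p3), 0.2)   # same F, permutation p re-sampled
})

test_that("two-group t and four-group ANOVA/LSD behave on fixtures", {
  x <- c(1, 2, 3, 4)
  g <- c("a", "a", "b", "b")
  same <- group_tests(c(x[1:2], x[1:2]), g)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  # hand-computed pooled t: means 1.5 vs 3.5, s2p = 0.5, t = -2/sqrt(0.5)
  tt <- group_tests(x, g, var_equal = TRUE)
  expect_equal(tt$statistic, -2 / sqrt(0.5), tolerance = 1e-12)

  # one clearly separated group earns its own LSD letter
  vals <- c(10.1, 10.2, 9.9, 10.0, 10.2, 10.1, 30.0, 30.3, 29.8)
  gr <- rep(c("g1", "g2", "g3"), each = 3)
  res <- group_tests(vals, gr)
  expect_identical(res$type, "anova_lsd")
  expect_lt(res$pairwise_p["g1", "g3"], 0.05)
  expect_gt(res$pairwise_p["g1", "g2"], 0.05)
  letters_of <- res$letters
  expect_identical(letters_of[["g3"]], "a")
  expect_identical(letters_of[["g1"]], letters_of[["g2"]])
  expect_false(letters_of[["g1"]] == letters_of[["g3"]])
})
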