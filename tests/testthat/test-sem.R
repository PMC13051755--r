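test_that("path model validation catches cycles and overparameterization", {
  v <- c("a", "b", "c")
  expect_error(path_model(v, data.frame(from = c("a", "b", "c"),
                                        to = c("b", "c", "a"))), "cyclic")
  expect_error(path_model(v, data.frame(from = "a", to = "a")), "self-loop")
  pm <- path_model(v, data.frame(from = c("a", "a", "b"),
                                 to = c("b", "c", "c")))
  expect_identical(pm$df, 0)        # saturated: 6 moments, 6 free params
  expect_identical(pm$exogenous, "a")
})

test_that("a saturated model reproduces the sample covariance exactly", {
  set.seed(3)
  dat <- matrix(rnorm(200 * 3), 200, 3,
                dimnames = list(NULL, c("a", "b", "c")))
  pm <- path_model(c("a", "b", "c"),
                   data.frame(from = c("a", "a", "b"), to = c("b", "c", "c")))
  fit <- fit_sem(dat, pm)
  expect_lt(fit$chi_square, 1e-8)
  expect_equal(fit$GFI, 1, tolerance = 1e-8)
  expect_equal(fit$RMSEA, 0)
  expect_gte(fit$F_ml, 0)
})

test_that("a single path's standardized estimate equals the correlation", {
  set.seed(9)
  x <- rnorm(120) * 4 + 2
  y <- 0.5 * x + rnorm(120)
  pm <- path_model(c("x", "y"), data.frame(from = "x", to = "y"))
  fit <- fit_sem(cbind(x = x, y = y), pm)
  expect_equal(fit$estimates$std, cor(x, y), tolerance = 1e-8)
  # unstandardized equals the OLS slope
  expect_equal(fit$estimates$est, unname(coef(lm(y ~ x))[2]),
               tolerance = 1e-6)
})

test_that("a four-variable chain is recovered within 0.1 at n = 500", {
  set.seed(77)
  n <- 500
  a <- rnorm(n)
  b <- 0.6 * a + sqrt(1 - 0.36) * rnorm(n)
  cc <- 0.5 * b + sqrt(1 - 0.25) * rnorm(n)
  d <- 0.4 * cc + sqrt(1 - 0.16) * rnorm(n)
  pm <- path_model(c("a", "b", "c", "d"),
                   data.frame(from = c("a", "b", "c"), to = c("b", "c", "d")))
  fit <- fit_sem(cbind(a = a, b = b, c = cc, d = d), pm)
  expect_equal(fit$estimates$std, c(0.6, 0.5, 0.4), tolerance = 0.1)
  expect_true(all(fit$estimates$p < 0.001))
  # total effect of the chain head equals the product of its paths
  expect_equal(total_effects(fit)["d", "a"], prod(fit$estimates$std),
               tolerance = 1e-10)
})

test_that("total effects match the path-enumeration oracle on DAGs", {
  set.seed(15)
  for (rep in 1:4) {
    v <- letters[1:6]
    edges <- NULL
    for (i in 1:5) for (j in (i + 1):6)
      if (runif(1) < 0.4) edges <- rbind(edges, c(v[i], v[j]))
    if (is.null(edges) || nrow(edges) < 2) next
    edges <- data.frame(from = edges[, 1], to = edges[, 2])
    n <- 300
    dat <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, v))
    for (k in seq_len(nrow(edges)))   # induce real structure
      dat[, edges$to[k]] <- dat[, edges$to[k]] + 0.4 * dat[, edges$from[k]]
    fit <- fit_sem(dat, path_model(v, edges))
    for (from in v) for (to in setdiff(v, from)) {
      expect_equal(fit$total_effects[to, from],
                   total_effect_oracle(fit$B_std, from, to),
                   tolerance = 1e-8)
    }
  }
})

test_that("the fit is invariant to affine rescaling of inputs", {
  set.seed(21)
  n <- 150
  x <- rnorm(n); mvar <- 0.5 * x + rnorm(n); y <- 0.7 * mvar + rnorm(n)
  dat <- cbind(x = x, m = mvar, y = y)
  pm <- path_model(c("x", "m", "y"),
                   data.frame(from = c("x", "m"), to = c("m", "y")))
  f1 <- fit_sem(dat, pm)
  dat2 <- dat
  dat2[, "x"] <- dat2[, "x"] * 1000 + 5
  dat2[, "y"] <- dat2[, "y"] / 50 - 2
  f2 <- fit_sem(dat2, pm)
  expect_equal(f1$estimates$std, f2$estimates$std, tolerance = 1e-6)
  expect_equal(f1$chi_square, f2$chi_square, tolerance = 1e-6)
  expect_equal(f1$GFI, f2$GFI, tolerance = 1e-8)
})

test_that("the study model assembles five observed variables per class", {
  cfg <- pipeline_config(seed = 5, out_dir = tempfile(),
                         synth = list(n_taxa = 100, reads_per_sample = 5000,
                                      n_modules = 4, module_size = 20))
  sp <- do.call(synth_spec, utils::modifyList(list(seed = 5), cfg$synth))
  gen <- gen_correlated_abundances(sp)
  tb <- gen$table
  rel <- prop.table(tb$counts, 2)
  kbs_ab <- colSums(rel[gen$truth$hubs, , drop = FALSE])
  meta <- gen_metadata_yield(sp, kbs_ab)
  net <- zi_pi(detect_modules(build_network(tb), seed = 2))
  niche <- suppressWarnings(classify_niche(tb, n_perm = 120, seed = 3))
  tax <- gen_taxonomy(sp)
  ben <- gen_beneficial(sp, tax, hub_taxa = gen$truth$hubs)
  kbs <- screen_kbs(net, niche, tax, ben)
  sm <- suppressMessages(build_study_model(tb, net, kbs, meta))
  expect_true(all(colnames(sm$data) %in%
                    c("soil", "community", "keystone", "kbs", "yield")))
  expect_identical(nrow(sm$data), 60L)
  # soil PC1 reproduces PCoA axis 1 of Euclidean distances on z-scores
  z <- scale(as.matrix(meta[, soil_vars()]))
  ord <- pcoa(dist(z))
  expect_equal(abs(cor(sm$data[, "soil"],
                       ord$coords[, 1])), 1, tolerance = 1e-8)
  fit <- fit_sem(sm$data, sm$model, seed = 4)
  expect_gte(fit$df, 0)
  expect_true(is.finite(fit$chi_square))
})
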