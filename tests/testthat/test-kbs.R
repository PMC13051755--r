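test_that("the screen is the exact three-way intersection", {
  # 4 keystones, 6 specialists, 5 beneficials planted: triple overlap = 2
  keystone <- c("t01", "t02", "t03", "t04")
  specialist <- c("t01", "t02", "t05", "t06", "t07", "t08")
  beneficial <- paste0("Genus_", c("t01", "t02", "t06", "t09", "t10"))
  fx <- fake_screen_inputs(keystone, specialist, beneficial)
  res <- screen_kbs(fx$net, fx$niche, fx$tax, fx$ben)
  expect_setequal(res$kbs_taxa, c("t01", "t02"))
  expect_identical(unname(res$counts["kbs"]), 2L)
  expect_identical(unname(res$counts[c("keystone", "specialist",
                                       "beneficial")]),
                   c(4L, 6L, 5L))
  expect_true(all(res$kbs_taxa %in% keystone))
  expect_true(all(res$kbs_taxa %in% specialist))
  # idempotent / order-independent
  res2 <- screen_kbs(fx$net, fx$niche, fx$tax, fx$ben)
  expect_identical(res$kbs_taxa, res2$kbs_taxa)
})

test_that("tightening any single criterion never grows the KBS set", {
  keystone <- c("t01", "t02", "t03", "t04")
  specialist <- c("t01", "t02", "t03", "t05", "t06")
  beneficial <- paste0("Genus_", c("t01", "t02", "t03", "t07"))
  fx <- fake_screen_inputs(keystone, specialist, beneficial)
  base <- screen_kbs(fx$net, fx$niche, fx$tax, fx$ben)
  # shorter beneficial list
  fx2 <- fake_screen_inputs(keystone, specialist,
                            paste0("Genus_", c("t01", "t07")))
  expect_true(all(screen_kbs(fx2$net, fx2$niche, fx2$tax,
                             fx2$ben)$kbs_taxa %in% base$kbs_taxa))
  # smaller keystone set
  fx3 <- fake_screen_inputs(c("t01"), specialist, beneficial)
  expect_true(all(screen_kbs(fx3$net, fx3$niche, fx3$tax,
                             fx3$ben)$kbs_taxa %in% base$kbs_taxa))
  # narrower niche band (fewer specialists)
  fx4 <- fake_screen_inputs(keystone, c("t02"), beneficial)
  expect_true(all(screen_kbs(fx4$net, fx4$niche, fx4$tax,
                             fx4$ben)$kbs_taxa %in% base$kbs_taxa))
  # empty keystone set warns and returns none
  fx5 <- fake_screen_inputs(character(0), specialist, beneficial)
  expect_warning(none <- screen_kbs(fx5$net, fx5$niche, fx5$tax, fx5$ben),
                 "empty keystone")
  expect_length(none$kbs_taxa, 0)
})

test_that("KBS abundance and composition follow hand arithmetic", {
  m <- matrix(c(6L, 2L, 2L, 5L, 2L, 3L), 3, 2,
              dimnames = list(c("t01", "t02", "t03"), c("s1", "s2")))
  tb <- count_table(m, "bacteria")
  res <- structure(list(kbs_taxa = c("t01", "t02")), class = "kbs_result")
  ab <- kbs_abundance(res, tb)$per_sample
  expect_equal(unname(ab), c(8 / 10, 7 / 10))
  all_t <- structure(list(kbs_taxa = c("t01", "t02", "t03")),
                     class = "kbs_result")
  expect_true(all(kbs_abundance(all_t, tb)$per_sample == 1))
  empty <- structure(list(kbs_taxa = character(0)), class = "kbs_result")
  expect_true(all(kbs_abundance(empty, tb)$per_sample == 0))

  tax <- data.frame(taxon_id = c("t01", "t02", "t03"), domain = "Bacteria",
                    phylum = "", class = c("Bacilli", "Bacteroidia",
                                           "Bacilli"),
                    order = "", family = "", genus = "", species = "")
  comp <- kbs_composition(res, tb, tax)
  shares <- c(mean(c(0.6, 0.5)), mean(c(0.2, 0.2)))
  expect_equal(unname(comp[c("Bacilli", "Bacteroidia")]),
               shares / sum(shares))
  expect_equal(sum(comp), 1)
  one <- structure(list(kbs_taxa = "t01"), class = "kbs_result")
  expect_equal(unname(kbs_composition(one, tb, tax)), 1)
})

test_that("yield correlations are computed per class with guards", {
  sp <- synth_spec(seed = 23)
  des <- synth_design(sp)
  m <- matrix(0L, 2, 60, dimnames = list(c("k1", "x1"), des$sample_id))
  set.seed(1)
  m["k1", ] <- rpois(60, 40) + 1L
  m["x1", ] <- rpois(60, 400) + 1L
  tb <- count_table(m, "bacteria")
  kbs_ab <- prop.table(m, 2)["k1", ]
  meta <- gen_metadata_yield(sp, kbs_ab)
  res <- structure(list(kbs_taxa = "k1"), class = "kbs_result")
  ky <- kbs_yield_correlation(res, tb, meta)
  expect_identical(nrow(ky), 2L)
  expect_true(all(abs(ky$r) <= 1))
  expect_gt(ky$r[ky$class == "resistant"], 0)
  expect_lt(ky$r[ky$class == "susceptible"], 0)
  # constant yield: correlation undefined
  meta2 <- meta; meta2$yield <- 3
  ky2 <- kbs_yield_correlation(res, tb, meta2)
  expect_true(all(is.na(ky2$r)))
})
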