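small_cfg <- function(..., seed = 3) {
  screen_config(n_genes = 12, n_replicates = 3,
                cells_per_well = list(mean = 60, dispersion = 10),
                seed = seed, ...)
}

test_that("screen layout honours the array geometry and control counts", {
  cfg <- small_cfg()
  scr <- generate_primary_screen(cfg)
  lay <- scr$layout
  for (sl in unique(lay$slide)) {
    l <- lay[lay$slide == sl, ]
    expect_equal(sum(l$role == "negative"), 30)
    expect_equal(sum(l$role == "positive"), 8)
    expect_true(all(l$row %in% 0:9), info = sl)
    expect_true(all(l$col %in% 0:29))
    expect_false(any(duplicated(l[, c("row", "col")])))
  }
  # every gene exactly once per replicate, in all 3 replicates
  tg <- table(lay$gene[lay$role == "test"], lay$replicate[lay$role == "test"])
  expect_true(all(tg == 1))
  expect_equal(nrow(tg), 12)
  expect_setequal(colnames(scr$cells)[-(1:8)], feature_catalog())
})

test_that("generation is a pure function of config and seed", {
  a <- generate_primary_screen(small_cfg(seed = 11))
  b <- generate_primary_screen(small_cfg(seed = 11))
  c <- generate_primary_screen(small_cfg(seed = 12))
  expect_identical(a$cells, b$cells)
  expect_false(identical(a$cells, c$cells))
})

test_that("configuration errors are caught", {
  expect_error(screen_config(cells_per_well = list(mean = 0.5, dispersion = 1)),
               "configuration error")
  expect_error(screen_config(effect_table = data.frame(
    gene = "g1", feature = "NotAFeature", kind = "shift", size = 1)),
    "unknown effect target")
  expect_error(screen_config(effect_table = data.frame(
    gene = "g1", feature = "Fint1", kind = "wobble", size = 1)),
    "effect kind")
})

test_that("a shift effect moves the sample mean by the configured amount", {
  eff <- data.frame(gene = "g1", feature = "Fint3", kind = "shift",
                    size = 2, mix_fraction = 0.5)
  cfg <- screen_config(n_genes = 8, n_replicates = 3, effect_table = eff,
                       cells_per_well = list(mean = 200, dispersion = 20),
                       artifact = list(row = 0, col = 0, edge = 0),
                       seed = 17)
  scr <- generate_primary_screen(cfg)
  base <- cfg$baseline[cfg$baseline$feature == "Fint3", ]
  mom <- endoscreen:::baseline_moments(base$family, base$p1, base$p2)
  g1 <- scr$cells$Fint3[!is.na(scr$cells$gene) & scr$cells$gene == "g1"]
  neg <- scr$cells$Fint3[scr$cells$role == "negative"]
  # analytic: mean shift = 2 baseline SDs, up to sampling error
  shift_sigma <- (mean(g1) - mean(neg)) / mom["sd"]
  expect_lt(abs(shift_sigma - 2), 0.3)
})

test_that("a gene with no planted effect is indistinguishable from negatives", {
  cfg <- screen_config(n_genes = 6, n_replicates = 1,
                       cells_per_well = list(mean = 200, dispersion = 20),
                       artifact = list(row = 0, col = 0, edge = 0), seed = 23)
  scr <- generate_primary_screen(cfg)
  g <- scr$cells$Fint1[!is.na(scr$cells$gene) & scr$cells$gene == "g1"]
  neg <- scr$cells$Fint1[scr$cells$role == "negative"]
  expect_gt(suppressWarnings(stats::ks.test(g, neg)$p.value), 0.01)
})

test_that("positional artifacts scale unbounded features multiplicatively", {
  cfg <- small_cfg(seed = 31)
  scr <- generate_primary_screen(cfg)
  lay <- scr$layout
  sl <- lay$slide[1]
  l <- lay[lay$slide == sl & lay$role == "negative", ]
  hi <- l$well_id[which.max(l$artifact)]
  lo <- l$well_id[which.min(l$artifact)]
  ratio_expect <- max(l$artifact) / min(l$artifact)
  m_hi <- mean(scr$cells$Fint1[scr$cells$well_id == hi])
  m_lo <- mean(scr$cells$Fint1[scr$cells$well_id == lo])
  expect_gt(ratio_expect, 1.2)
  expect_lt(abs(m_hi / m_lo - ratio_expect), 0.5 * ratio_expect)
  # bounded fraction features stay within [0, 1]
  expect_true(all(scr$cells$Fmph2 >= 0 & scr$cells$Fmph2 <= 1))
})

test_that("secondary plate ground truth reflects the planted folds", {
  eff <- data.frame(gene = c("gA", "gB", "gC"),
                    pulse_fold = c(1.0, 1.5, 1.0),
                    chase_fold = c(1.0, 1.5, 0.5))
  pl <- generate_secondary_plate(c("gA", "gB", "gC"), eff, seed = 2)
  tr <- pl$truth
  expect_equal(tr$quadrant[tr$gene == "gA"], "null")
  expect_equal(tr$quadrant[tr$gene == "gB"], "1")
  expect_equal(tr$quadrant[tr$gene == "gC"], "2")
  # 3 test + 3 positive + 6 negative per local group
  expect_true(all(table(pl$wells$group, pl$wells$role) ==
                    matrix(rep(c(6, 3, 3), each = 3), 3)))
  expect_error(generate_secondary_plate("g", layout = list(
    n_test = 3, n_positive = 1, n_negative = 6)), "local-control")
})

test_that("annotation generator plants terms exactly and validates inputs", {
  uni <- paste0("g", 1:100)
  planted <- list(T = uni[1:10])
  ann <- generate_annotations(uni, n_terms = 5, planted = planted, seed = 4)
  expect_setequal(ann$term2gene$T, uni[1:10])
  # forward and inverse maps consistent
  for (g in uni[1:10]) expect_true("T" %in% ann$gene2term[[g]])
  expect_error(generate_annotations(character()), "empty")
  expect_error(generate_annotations(uni, planted = list(T = "not_there")),
               "outside universe")
  # planted term is recovered with an extreme hypergeometric p downstream
  p <- hypergeom_test(uni[1:10], ann$term2gene$T, uni)
  expect_lt(p, 1e-10)
})

test_that("network generator plants modules densely and merges duplicates", {
  uni <- paste0("g", 1:50)
  net <- generate_interaction_network(uni, modules = list(m = uni[1:6]),
                                      n_background = 100, seed = 6)
  within <- net$a %in% uni[1:6] & net$b %in% uni[1:6]
  expect_gte(sum(within), choose(6, 2))
  expect_false(any(net$a == net$b))
  key <- paste(pmin(net$a, net$b), pmax(net$a, net$b))
  expect_false(any(duplicated(key)))
  expect_true(all(net$confidence >= 0 & net$confidence <= 1))
  expect_error(generate_interaction_network(uni, modules = list(m = "zz")),
               "outside universe")
})
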