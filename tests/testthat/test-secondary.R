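test_that("local-control normalization computes fold ratios", {
  expect_equal(normalize_to_local_controls(c(10, 12, 14), rep(8, 6))$ratio,
               1.5)
  expect_equal(normalize_to_local_controls(c(8, 8), c(8, 8, 8))$ratio, 1)
  expect_equal(normalize_to_local_controls(c(16, 16), rep(8, 4))$ratio, 2)
  expect_error(normalize_to_local_controls(1, 5), ">= 2")
  expect_error(normalize_to_local_controls(c(1, 2), c(0, 0)), "zero")
})

test_that("the gene-vs-negatives test behaves across separations", {
  expect_equal(test_gene(c(5, 5, 5), c(5, 5, 5, 5)), 1)
  set.seed(71)
  p <- test_gene(rnorm(3, 10, 0.5), rnorm(6, 0, 0.5))
  expect_lt(p, 0.01)
  expect_error(test_gene(1, c(1, 2)), ">= 2")
  # Welch and pooled forms agree on balanced equal-variance data
  a <- c(1, 2, 3); b <- c(2, 3, 4, 3, 2, 4)
  expect_equal(test_gene(a, b, pooled = TRUE),
               stats::t.test(a, b, var.equal = TRUE)$p.value)
})

test_that("quadrant assignment follows ratio signs gated on significance", {
  q <- assign_quadrant(1.4, 1.3, 0.03, 0.04)
  expect_equal(q$quadrant, "1"); expect_equal(q$class, "both")
  q3 <- assign_quadrant(0.6, 0.6, 0.02, 0.02)
  expect_equal(q3$quadrant, "3")
  qn <- assign_quadrant(1.0, 1.0, 0.9, 0.9)
  expect_equal(qn$quadrant, "null"); expect_equal(qn$class, "none")
  # chase-only effect -> quadrant 2; pulse-only -> quadrant 4
  expect_equal(assign_quadrant(1.02, 0.5, 0.6, 0.01)$quadrant, "2")
  expect_equal(assign_quadrant(1.5, 1.01, 0.02, 0.7)$quadrant, "4")
  # significance class is orthogonal to the quadrant
  expect_equal(assign_quadrant(1.02, 0.5, 0.6, 0.01)$class, "chase-only")
})

test_that("quadrants plus null partition all tested genes", {
  genes <- paste0("g", 1:40)
  eff <- data.frame(gene = genes[1:20],
                    pulse_fold = rep(c(1.6, 0.6, 1.6, 0.6, 1), 4),
                    chase_fold = rep(c(1.6, 0.6, 0.6, 1.6, 0.5), 4))
  pl <- generate_secondary_plate(genes, eff, seed = 12)
  rec <- analyze_secondary_plate(pl)
  expect_equal(nrow(rec), 40)
  expect_true(all(rec$quadrant %in% c("1", "2", "3", "4", "null")))
  expect_false(any(duplicated(rec$gene)))
  expect_true(all((rec$quadrant == "null") == (rec$class == "none")))
})

test_that("planted folds >= 1.5x are recovered into their true quadrants", {
  genes <- paste0("g", 1:60)
  eff <- data.frame(gene = genes,
                    pulse_fold = rep(c(1.5, 0.5, 1.5, 1.0), 15),
                    chase_fold = rep(c(1.5, 0.5, 0.5, 0.5), 15))
  pl <- generate_secondary_plate(genes, eff, cv = 0.08, seed = 13)
  rec <- analyze_secondary_plate(pl)
  truth <- pl$truth
  agree <- rec$quadrant[match(truth$gene, rec$gene)] == truth$quadrant
  expect_gte(mean(agree), 0.95)
})

test_that("the exact sign test matches enumeration and the printed value", {
  expect_equal(binomial_sign_test(21, 22), 23 / 2^22)
  expect_equal(signif(binomial_sign_test(21, 22), 1), 5e-6)
  expect_equal(binomial_sign_test(0, 10), 1)
  expect_equal(binomial_sign_test(22, 22), 2^-22)
  for (n in c(5, 9, 12)) {
    for (k in c(0, 2, n)) {
      expect_equal(binomial_sign_test(k, n), binom_brute(k, n),
                   info = paste(k, n))
    }
  }
})

test_that("pathway cross-tabulation separates concordant and opposing genes", {
  a <- data.frame(gene = c("g1", "g2", "g3", "g4"),
                  pulse_ratio = c(0.5, 1.5, 0.5, 1.0),
                  quadrant = c("3", "1", "3", "null"))
  b <- data.frame(gene = c("g1", "g2", "g3", "g5"),
                  pulse_ratio = c(0.6, 1.4, 1.6, 0.5),
                  quadrant = c("3", "1", "1", "3"))
  ct <- crosstab_pathways(a, b)
  expect_equal(ct$both_down, "g1")
  expect_equal(ct$both_up, "g2")
  expect_equal(ct$opposing, "g3")
  expect_setequal(ct$single_pathway, c("g4", "g5"))
})
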