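test_that("affine normalization centres, scales, and is idempotent", {
  x <- affine_normalize(c(1, 2, 3))
  expect_equal(x, c(-1, 0, 1))
  expect_equal(mean(x), 0)
  expect_equal(sd(x), 1)
  expect_equal(affine_normalize(x), x, tolerance = 1e-12)
  expect_error(affine_normalize(c(5, 5, 5)), "degenerate")
  expect_error(affine_normalize(3), "degenerate")
})

test_that("KS statistic matches its brute-force oracle and ks.test", {
  expect_equal(ks_statistic(c(1, 2, 3, 4), c(1, 2, 3, 4)), 0)
  expect_equal(ks_statistic(c(0, 1), c(2, 3)), 1)
  expect_equal(ks_statistic(c(1, 3), c(2, 4)), 0.5)
  set.seed(41)
  for (i in 1:30) {
    a <- round(rnorm(sample(1:20, 1)), 1)  # rounding forces ties
    b <- round(rnorm(sample(1:20, 1), sd = 2), 1)
    d <- ks_statistic(a, b)
    expect_equal(d, ks_brute(a, b), info = paste("case", i))
    expect_equal(d, ks_statistic(b, a))
    expect_gte(d, 0); expect_lte(d, 1)
    # invariance under a strictly increasing transform
    expect_equal(ks_statistic(exp(a), exp(b)), d)
  }
})

test_that("negative-well splits are disjoint, exhaustive and seeded", {
  wells <- sprintf("w%02d", 1:30)
  s <- split_negatives(wells, 0.5, seed = 5)
  expect_length(s$reference, 15)
  expect_length(s$evaluation, 15)
  expect_setequal(c(s$reference, s$evaluation), wells)
  expect_identical(s, split_negatives(wells, 0.5, seed = 5))
  expect_error(split_negatives(wells[1:3]), "too few")
  expect_warning(split_negatives(wells, 1.0, seed = 1), "FP estimation")
})

test_that("null calibration scales with cell count and rejects degeneracy", {
  draw <- function(n_wells, n_cells, seed) {
    set.seed(seed)
    stats::setNames(lapply(seq_len(n_wells), function(i) rnorm(n_cells)),
                    paste0("w", seq_len(n_wells)))
  }
  cal200 <- calibrate_null(draw(12, 200, 1))
  cal50 <- calibrate_null(draw(12, 50, 2))
  # KS null scale ~ 1/sqrt(n): more cells, smaller mean null statistic
  expect_lt(cal200$mu_D, cal50$mu_D)
  expect_gt(cal200$sigma_D, 0)
  expect_error(calibrate_null(draw(3, 100, 3)), ">= 5")
  same <- stats::setNames(rep(list(c(1, 2, 3, 4, 5)), 6), paste0("w", 1:6))
  expect_error(calibrate_null(same, shape_mode = FALSE), "sigma_D")
})

test_that("Z-scores are centred under the null and detect shape changes", {
  set.seed(7)
  ref <- stats::setNames(lapply(1:12, function(i) rlnorm(200, 0, 0.6)),
                         paste0("w", 1:12))
  cal <- calibrate_null(ref)
  znull <- replicate(400, zscore_well(rlnorm(200, 0, 0.6), cal))
  expect_lt(abs(mean(znull)), 0.15)
  # a bimodal mixture of the same baseline family is flagged
  zmix <- replicate(50, {
    x <- rlnorm(200, 0, 0.6)
    x[1:100] <- x[1:100] + 4
    zscore_well(x, cal)
  })
  expect_gt(median(zmix), 3)
  # low-cell wells yield NA with a reason, not an error
  z <- zscore_well(rlnorm(10), cal, min_cells = 50)
  expect_true(is.na(z))
  expect_equal(attr(z, "reason"), "low_cell")
})

test_that("pure location shifts register only with shape_mode off", {
  eff <- data.frame(gene = "g1", feature = "Fint3", kind = "shift",
                    size = 3, mix_fraction = 0.5)
  cfg <- screen_config(n_genes = 8, n_replicates = 3, effect_table = eff,
                       cells_per_well = list(mean = 150, dispersion = 10),
                       seed = 9)
  scr <- generate_primary_screen(cfg)
  zon <- zscore_matrix(zscore_screen(scr, seed = 3))
  zoff <- zscore_matrix(zscore_screen(scr, shape_mode = FALSE, seed = 3))
  expect_lt(abs(median(zon["g1", "Fint3", ])), 1)
  expect_gt(median(zoff["g1", "Fint3", ]), 3)
})

test_that("FP/TP curves behave at the extremes and under the 2/3 rule", {
  cfg <- screen_config(n_genes = 10, n_replicates = 3,
                       cells_per_well = list(mean = 80, dispersion = 10),
                       seed = 13)
  z <- zscore_screen(generate_primary_screen(cfg), min_cells = 30, seed = 2)
  curves <- evaluate_fp_tp(z, thresholds = c(-100, 3, 100))
  expect_equal(curves$FP[1], 1)
  expect_equal(curves$TP[1], 1)
  expect_equal(curves$FP[3], 0)
  # FP3 closed form: f = 0.1 -> 0.028
  f <- 0.1
  expect_equal(3 * f^2 * (1 - f) + f^3, 0.028)
  expect_true(all(curves$FP3 <= curves$FP))
  # positives (strong planted skew) separate from negatives at t = 3
  expect_gt(curves$TP[2], curves$FP[2])
})
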