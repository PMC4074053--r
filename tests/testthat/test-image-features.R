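# brute-force grayscale opening on small arrays: erosion then dilation
# over an explicit neighbourhood. The footprint is taken from the disk
# brush the implementation declares (rasterizations of a digital disk are
# not unique), so this checks the min/max mechanics independently.
opening_brute <- function(img, radius) {
  b <- EBImage::makeBrush(2 * radius + 1, "disc")
  idx <- which(b > 0, arr.ind = TRUE)
  offs <- data.frame(dx = idx[, 1] - radius - 1, dy = idx[, 2] - radius - 1)
  nr <- nrow(img); nc <- ncol(img)
  stat <- function(m, f) {
    out <- matrix(NA_real_, nr, nc)
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      x <- i + offs$dx; y <- j + offs$dy
      ok <- x >= 1 & x <= nr & y >= 1 & y <= nc
      out[i, j] <- f(m[cbind(x[ok], y[ok])])
    }
    out
  }
  stat(stat(img, min), max)
}

test_that("top-hat subtraction matches brute-force grayscale opening", {
  # constant image -> all zero
  expect_true(all(tophat_subtract(matrix(7, 20, 20), 3) == 0))
  # isolated bright pixel survives untouched
  img <- matrix(0, 32, 32); img[16, 16] <- 100
  th <- tophat_subtract(img, 5)
  expect_equal(th[16, 16], 100)
  expect_equal(sum(th), 100)
  # wide uniform disk is removed entirely by a small top-hat
  disk <- matrix(0, 64, 64)
  disk[(row(disk) - 32)^2 + (col(disk) - 32)^2 <= 20^2] <- 50
  td <- tophat_subtract(disk, 5)
  interior <- (row(disk) - 32)^2 + (col(disk) - 32)^2 <= 14^2
  expect_true(all(td[interior] == 0))
  # random image equals the brute-force oracle away from the border
  # (the library pads the border; the oracle clips the neighbourhood)
  set.seed(81)
  rnd <- matrix(runif(24 * 24, 0, 1000), 24, 24)
  core <- 7:18
  expect_equal(tophat_subtract(rnd, 3)[core, core],
               pmax(rnd - opening_brute(rnd, 3), 0)[core, core],
               tolerance = 1e-6)
  # oversized disk: whole image treated as background-free
  expect_warning(th2 <- tophat_subtract(matrix(1:16, 4, 4), 10), "exceeds")
  expect_equal(th2, matrix(1:16, 4, 4) - 1)
  expect_error(tophat_subtract(rnd, 0), "radius")
})

test_that("radius ordering holds: larger disks remove less background", {
  set.seed(83)
  img <- matrix(rgamma(40 * 40, 2, 0.01), 40, 40)
  t1 <- mean(tophat_subtract(img, 16))
  t2 <- mean(tophat_subtract(img, 8))
  t3 <- mean(tophat_subtract(img, 3))
  expect_gte(t1, t2); expect_gte(t2, t3)
})

test_that("endosome detection counts components with 8-connectivity", {
  img <- matrix(0, 40, 40)
  mask <- matrix(TRUE, 40, 40)
  # two diagonal-touching pixels form one component
  img[10, 10] <- 100; img[11, 11] <- 100
  # an isolated 2x2 blob
  img[30:31, 30:31] <- 100
  sp <- detect_endosomes(img, mask, threshold = 50, min_area = 2)
  expect_equal(nrow(sp), 2)
  expect_setequal(sp$area, c(2, 4))
  # threshold above the maximum -> no spots
  expect_equal(nrow(detect_endosomes(img, mask, threshold = 1000)), 0)
  # empty mask -> empty spot set
  expect_equal(nrow(detect_endosomes(img, mask & FALSE, threshold = 50)), 0)
  # overlapping planted spots merge into one component (documented)
  img2 <- matrix(0, 40, 40); img2[20, 18:22] <- 100
  expect_equal(nrow(detect_endosomes(img2, mask, threshold = 50)), 1)
})

test_that("a rasterized disk scores near-perfect circularity", {
  mask <- matrix(FALSE, 32, 32)
  mask[(row(mask) - 16)^2 + (col(mask) - 16)^2 <= 10^2] <- TRUE
  g <- endoscreen:::.mask_geometry(mask)
  expect_gte(g$circularity, 0.95)
  expect_lte(g$circularity, 1.0)
})

test_that("feature extraction recovers the planted ground truth", {
  fld <- suppressWarnings(generate_images(min_separation = 8, seed = 91))
  feats <- extract_well_features(fld$images, fld$cell_labels, fld$nuc_labels)
  planted_f <- table(factor(
    fld$truth$spots$cell[fld$truth$spots$channel == "fluid"],
    levels = feats$cell_id))
  expect_equal(feats$Fnum, as.integer(planted_f))
  # intensity features non-negative, fractions within [0, 1], ordering
  expect_true(all(feats$Fint1 >= feats$Fint2 - 1e-9))
  expect_true(all(feats$Fint2 >= feats$Fint3 - 1e-9))
  frac <- c("Fint4", "Tint4", "Fmph2", "Tmph2", "Fclc", "Tclc")
  for (f in frac) expect_true(all(is.na(feats[[f]]) |
                                    (feats[[f]] >= 0 & feats[[f]] <= 1)),
                              info = f)
  expect_true(all(feats$Okt > 0))
  expect_equal(feats$Rto1, feats$Tint1 / feats$Okt)
  # determinism of the generator
  fld2 <- suppressWarnings(generate_images(min_separation = 8, seed = 91))
  expect_identical(fld$images, fld2$images)
})

test_that("spot count recovery is exact across many separated fixtures", {
  fails <- 0
  for (s in 1:20) {
    fld <- suppressWarnings(generate_images(
      dim = c(128, 128), n_cells = 4, cell_radius = 22,
      spots = list(fluid = list(n = 4, amplitude = 4000, sigma = 1.5)),
      min_separation = 8, seed = 100 + s))
    # radius-64 top-hat on a 128-px field warns that the disk spans the
    # image; that path is itself under test above
    feats <- suppressWarnings(
      extract_well_features(fld$images, fld$cell_labels, fld$nuc_labels))
    planted <- table(factor(fld$truth$spots$cell, levels = feats$cell_id))
    fails <- fails + sum(feats$Fnum != as.integer(planted))
  }
  expect_equal(fails, 0)
})

test_that("colocalized spots give full colocalization fractions", {
  fld <- suppressWarnings(generate_images(
    n_cells = 4, spots = list(fluid = list(n = 3, amplitude = 4000,
                                           sigma = 1.5)),
    min_separation = 10, seed = 77))
  # plant the tf channel identical to fluid: every fluid spot sits in a
  # tf spot and vice versa
  fld$images$tf <- fld$images$fluid
  feats <- extract_well_features(fld$images, fld$cell_labels,
                                 fld$nuc_labels)
  expect_true(all(feats$Fclc == 1))
  expect_true(all(feats$Tclc == 1))
})

test_that("zero-signal cells yield zero intensity features and no spots", {
  fld <- suppressWarnings(generate_images(
    n_cells = 4,
    spots = list(fluid = list(n = 0, amplitude = 0, sigma = 1.5)),
    background = list(level = 0, gradient = 0, noise = 0),
    seed = 55))
  feats <- extract_well_features(fld$images, fld$cell_labels,
                                 fld$nuc_labels)
  expect_true(all(feats$Fint1 == 0))
  expect_true(all(feats$Fint4 == 0))
  expect_true(all(feats$Fnum == 0))
  expect_true(all(is.na(feats$Fmph1)))
})
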