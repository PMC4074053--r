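# Distribution-shape Z-scores.
#
# Each test well's single-cell feature distribution is compared to the
# pooled in-slide negative controls with the two-sample Kolmogorov-Smirnov
# sup-statistic D. D is standardized into a Z-score against a null
# distribution of D obtained by leave-one-out comparisons among a reference
# subset of the negative wells of the same slide; the held-out negative
# wells estimate the false-positive rate of the score. With `shape_mode`
# every per-well sample is affine-normalized (mean 0, SD 1) first, so only
# changes in distribution *shape* register and well-level location/scale
# artifacts cancel.

#' Affine-normalize a per-well sample
#'
#' Subtracts the sample mean and divides by the sample standard deviation
#' (the `n-1` denominator convention of [stats::sd()]), preserving order.
#'
#' @param x Numeric vector of per-cell values (one feature, one well).
#' @return Numeric vector with mean 0 and SD 1.
#' @export
#' @examples
#' affine_normalize(c(1, 2, 3))
affine_normalize <- function(x) {
  if (length(x) < 2) stopf("degenerate sample: need at least 2 values")
  s <- sd(x)
  if (!is.finite(s) || s == 0) stopf("degenerate sample: zero SD")
  (x - mean(x)) / s
}

#' Two-sample Kolmogorov-Smirnov statistic
#'
#' The maximum vertical deviation between the two empirical cumulative
#' distribution functions, evaluated over the pooled values. Symmetric in
#' its arguments, lies in \[0, 1\], and is invariant under any strictly
#' increasing transform applied to both samples. Ties are handled exactly.
#'
#' @param a,b Numeric vectors (finite, length >= 1).
#' @return The statistic D.
#' @export
#' @examples
#' ks_statistic(c(1, 3), c(2, 4))  # 0.5
ks_statistic <- function(a, b) {
  if (!length(a) || !length(b)) stopf("both samples must be non-empty")
  if (anyNA(a) || anyNA(b) || any(!is.finite(a)) || any(!is.finite(b)))
    stopf("samples must be finite")
  cpp_ks_sorted(sort(a), sort(b))
}

#' Split negative-control wells into reference and evaluation sets
#'
#' Only the reference subset calibrates the Z-score null; the held-out
#' evaluation subset measures the score's false-positive behaviour.
#'
#' @param wells Character vector of negative well ids for one slide.
#' @param fraction_reference Fraction assigned to the reference set.
#' @param seed Integer seed (split is deterministic per seed).
#' @return List with `reference` and `evaluation` well-id vectors.
#' @export
split_negatives <- function(wells, fraction_reference = 0.5, seed = 1L) {
  if (length(wells) < 4)
    stopf("too few negative wells (%d); need >= 4", length(wells))
  n_ref <- round(length(wells) * fraction_reference)
  n_ref <- max(min(n_ref, length(wells)), 2L)
  ref <- with_seed(seed, sample(wells, n_ref))
  ev <- setdiff(wells, ref)
  if (!length(ev))
    warnf("evaluation set empty (fraction_reference = %g): FP estimation disabled",
          fraction_reference)
  list(reference = ref, evaluation = ev)
}

#' Calibrate the null distribution of the KS statistic
#'
#' For one slide and one feature, computes leave-one-out KS statistics of
#' each reference negative well against the pool of the remaining reference
#' wells; their mean and SD define the Z-score scaling.
#'
#' @param samples Named list of numeric vectors, one per reference negative
#'   well.
#' @param shape_mode If `TRUE` (default), affine-normalize every sample
#'   before pooling/comparison so only shape differences register.
#' @return Object of class `null_calibration`: list with `mu_D`, `sigma_D`,
#'   `n_null`, `reference` (the normalized (or raw) per-well samples) and
#'   `pool` (sorted pooled reference values).
#' @export
calibrate_null <- function(samples, shape_mode = TRUE) {
  if (length(samples) < 5)
    stopf("need >= 5 reference negative wells, got %d", length(samples))
  if (shape_mode) samples <- lapply(samples, affine_normalize)
  sorted <- lapply(samples, sort)
  d <- vapply(seq_along(sorted), function(i) {
    pool <- sort(unlist(sorted[-i], use.names = FALSE))
    cpp_ks_sorted(sorted[[i]], pool)
  }, numeric(1))
  mu <- mean(d); sg <- sd(d)
  if (!is.finite(sg) || sg == 0)
    stopf("degenerate null calibration: sigma_D = 0")
  structure(list(mu_D = mu, sigma_D = sg, n_null = length(d),
                 null_D = d, shape_mode = shape_mode,
                 reference = samples,
                 pool = sort(unlist(sorted, use.names = FALSE))),
            class = "null_calibration")
}

#' Shape-change Z-score of one well
#'
#' `Z = (D(test, pooled reference) - mu_D) / sigma_D` with `mu_D`,
#' `sigma_D` from [calibrate_null()]. Wells with fewer than `min_cells`
#' cells return `NA` with a reason attribute rather than an error.
#'
#' @param x Numeric vector of per-cell values for the test well.
#' @param calibration A [calibrate_null()] result.
#' @param min_cells Minimum cells per well for a well to be scored.
#' @return Z (scalar), or `NA` with attribute `reason = "low_cell"`.
#' @export
zscore_well <- function(x, calibration, min_cells = 50) {
  stopifnot(inherits(calibration, "null_calibration"))
  if (length(x) < min_cells)
    return(structure(NA_real_, reason = "low_cell"))
  if (calibration$shape_mode) {
    s <- sd(x)
    if (!is.finite(s) || s == 0) return(structure(NA_real_, reason = "degenerate"))
    x <- affine_normalize(x)
  }
  d <- cpp_ks_sorted(sort(x), calibration$pool)
  (d - calibration$mu_D) / calibration$sigma_D
}

#' Z-score an entire synthetic or measured screen
#'
#' Runs the slide-local calibration and scoring over every slide, feature
#' and well of a screen: per slide the negative wells are split into
#' reference and evaluation sets (one split per slide, shared by all
#' features), the null is calibrated per feature from the reference wells,
#' and every test, positive and evaluation-negative well is scored.
#'
#' @param screen A `primary_screen` (from [generate_primary_screen()]) or a
#'   list with `cells` and `layout` data frames in the same schema (e.g.
#'   from [read_well_tables()]).
#' @param features Features to score (default all 27).
#' @param shape_mode Affine-normalize samples first (default `TRUE`).
#' @param min_cells Minimum cells for a well/feature to be scored
#'   (default 50).
#' @param fraction_reference Fraction of negative wells used for
#'   calibration (default 0.5).
#' @param seed Seed for the negative-well splits.
#' @return Object of class `screen_zscores`: list with `scores` (long data
#'   frame: slide, replicate, well_id, role, gene, feature, n_cells, D, Z),
#'   `calibration` (per slide x feature mu_D/sigma_D), and the scoring
#'   parameters.
#' @export
zscore_screen <- function(screen, features = feature_catalog(),
                          shape_mode = TRUE, min_cells = 50,
                          fraction_reference = 0.5, seed = 1L) {
  cells <- screen$cells
  layout <- screen$layout
  slides <- unique(layout$slide)
  res <- vector("list", length(slides))
  calib <- vector("list", length(slides))
  for (si in seq_along(slides)) {
    sl <- slides[si]
    lsl <- layout[layout$slide == sl, , drop = FALSE]
    csl <- cells[cells$slide == sl, , drop = FALSE]
    negs <- lsl$well_id[lsl$role == "negative"]
    split <- split_negatives(negs, fraction_reference,
                             seed = child_seed(seed, si))
    score_wells <- lsl$well_id[lsl$role != "negative" |
                                 lsl$well_id %in% split$evaluation]
    well_meta <- lsl[match(score_wells, lsl$well_id), , drop = FALSE]
    out_f <- vector("list", length(features))
    cal_f <- vector("list", length(features))
    wf <- factor(csl$well_id, levels = lsl$well_id)
    for (fi in seq_along(features)) {
      f <- features[fi]
      by_well <- split(csl[[f]], wf)
      ref_samples <- by_well[split$reference]
      ref_samples <- ref_samples[vapply(ref_samples, length, 1L) >= min_cells]
      cal <- tryCatch(calibrate_null(ref_samples, shape_mode = shape_mode),
                      error = function(e) NULL)
      if (is.null(cal)) {
        out_f[[fi]] <- data.frame(well_id = score_wells, feature = f,
                                  n_cells = NA_integer_, D = NA_real_,
                                  Z = NA_real_)
        next
      }
      cal_f[[fi]] <- data.frame(slide = sl, feature = f, mu_D = cal$mu_D,
                                sigma_D = cal$sigma_D, n_null = cal$n_null)
      zs <- vapply(score_wells, function(wid) {
        x <- by_well[[wid]]
        n <- length(x)
        z <- zscore_well(x, cal, min_cells = min_cells)
        c(n, as.numeric(z),
          if (is.na(z)) NA_real_ else z * cal$sigma_D + cal$mu_D)
      }, numeric(3))
      out_f[[fi]] <- data.frame(well_id = score_wells, feature = f,
                                n_cells = as.integer(zs[1, ]),
                                D = zs[3, ], Z = zs[2, ])
    }
    sc <- do.call(rbind, out_f)
    sc <- cbind(well_meta[match(sc$well_id, well_meta$well_id),
                          c("slide", "replicate", "role", "gene")], sc)
    rownames(sc) <- NULL
    res[[si]] <- sc
    calib[[si]] <- do.call(rbind, cal_f)
  }
  structure(list(scores = do.call(rbind, res),
                 calibration = do.call(rbind, calib),
                 shape_mode = shape_mode, min_cells = min_cells,
                 fraction_reference = fraction_reference, seed = seed),
            class = "screen_zscores")
}

#' @export
print.screen_zscores <- function(x, ...) {
  cat(sprintf("screen_zscores: %d scored well-features (%d wells), shape_mode=%s\n",
              nrow(x$scores), length(unique(x$scores$well_id)),
              x$shape_mode))
  invisible(x)
}

#' Gene x feature x replicate Z-score array
#'
#' Reshapes the long score table of [zscore_screen()] into the triplicate
#' Z-score array used by hit calling.
#'
#' @param z A `screen_zscores` object.
#' @return 3-d numeric array gene x feature x replicate (class
#'   `zscore_matrix`), `NA` for unscored wells.
#' @export
zscore_matrix <- function(z) {
  sc <- z$scores[z$scores$role == "test" & !is.na(z$scores$gene), ]
  genes <- sort(unique(sc$gene))
  feats <- unique(sc$feature)
  reps <- sort(unique(sc$replicate))
  arr <- array(NA_real_, dim = c(length(genes), length(feats), length(reps)),
               dimnames = list(gene = genes, feature = feats,
                               replicate = paste0("rep", reps)))
  idx <- cbind(match(sc$gene, genes), match(sc$feature, feats),
               match(sc$replicate, reps))
  arr[idx] <- sc$Z
  structure(arr, class = c("zscore_matrix", "array"))
}

#' False-positive and true-positive curves over a threshold grid
#'
#' `FP(t)` is the fraction of evaluation-negative wells with `Z >= t` (the
#' score's false-positive rate); `TP(t)` the fraction of positive-control
#' wells with `Z >= t`. Also reports the triplicate 2-of-3 rule rate
#' `FP3(t) = 3 f^2 (1-f) + f^3` with `f = FP(t)`.
#'
#' @param z A `screen_zscores` object.
#' @param thresholds Numeric vector of Z thresholds.
#' @return Data frame with columns `threshold`, `FP`, `FP3`, `TP` (`TP` is
#'   `NA` if no positive wells were scored), plus counts.
#' @export
evaluate_fp_tp <- function(z, thresholds = seq(0, 10, by = 0.5)) {
  sc <- z$scores
  negz <- sc$Z[sc$role == "negative" & !is.na(sc$Z)]
  posz <- sc$Z[sc$role == "positive" & !is.na(sc$Z)]
  if (length(negz) < 10)
    stopf("need >= 10 evaluation-negative Z values, got %d", length(negz))
  fp <- vapply(thresholds, function(t) mean(negz >= t), numeric(1))
  tp <- if (length(posz))
    vapply(thresholds, function(t) mean(posz >= t), numeric(1))
  else rep(NA_real_, length(thresholds))
  data.frame(threshold = thresholds, FP = fp,
             FP3 = 3 * fp^2 * (1 - fp) + fp^3, TP = tp,
             n_negative = length(negz), n_positive = length(posz))
}
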