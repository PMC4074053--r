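# Extraction of the 27 per-cell features from multi-channel images and
# segmentation masks. Intensity features are read off top-hat processed
# images at three disk radii per channel (fluid: 64/10/5 px, transferrin:
# 64/14/7 px, the wider small/medium disks accounting for the tubular
# morphology of transferrin endosomes); endosomes are connected components
# (8-connectivity) of the small-radius top-hat image above an automatic
# threshold, clipped to the cell mask.

.default_radii <- list(fluid = c(64, 10, 5), tf = c(64, 14, 7))

#' Top-hat background subtraction
#'
#' Subtracts the grayscale morphological opening of the image by a disk of
#' the given radius, suppressing every structure wider than the disk while
#' retaining narrower peaks. The result is non-negative.
#'
#' @param img Numeric matrix of non-negative intensities.
#' @param radius Disk radius in pixels (>= 1).
#' @return Matrix of the same shape.
#' @export
tophat_subtract <- function(img, radius) {
  if (radius < 1) stopf("radius must be >= 1")
  side <- 2 * radius + 1
  if (side > min(dim(img))) {
    warnf("disk diameter %d exceeds image size; treating whole image as background-free",
          side)
    return(img - min(img))
  }
  brush <- EBImage::makeBrush(side, shape = "disc")
  mx <- max(img)
  if (mx <= 0) return(img * 0)
  # EBImage grayscale morphology expects intensities in [0, 1]; erosion and
  # dilation commute with positive rescaling
  opened <- EBImage::imageData(EBImage::opening(img / mx, brush)) * mx
  pmax(img - opened, 0)
}

# 8-connected labeling: EBImage::bwlabel is 4-connected, so labels that
# touch diagonally are merged with a union-find over label pairs.
.label8 <- function(bw) {
  lab <- EBImage::bwlabel(bw)
  lab <- EBImage::imageData(lab)
  n <- max(lab)
  if (n < 2) return(lab)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  nr <- nrow(lab); nc <- ncol(lab)
  # diagonal neighbour label pairs
  pairs <- rbind(
    cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),
    cbind(as.vector(lab[-1, -nc]), as.vector(lab[-nr, -1])))
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                   pairs[, 1] != pairs[, 2], , drop = FALSE]
  for (i in seq_len(nrow(pairs))) {
    a <- find(pairs[i, 1]); b <- find(pairs[i, 2])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  root <- vapply(seq_len(n), find, integer(1))
  relab <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

# Otsu threshold on a vector of (mask-restricted) intensities
.otsu <- function(x, levels = 256) {
  r <- range(x)
  if (diff(r) == 0) return(r[1])
  h <- tabulate(pmin(floor((x - r[1]) / diff(r) * levels) + 1, levels),
                nbins = levels)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(levels))
  mu_t <- mu[levels]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  k <- which.max(sigma_b)
  r[1] + k / levels * diff(r)
}

# chain-code perimeter with Vossepoel-Smeulders weights
.contour_perimeter <- function(oc) {
  if (nrow(oc) < 2) return(4 * 0.948)
  d <- rbind(diff(oc), oc[1, ] - oc[nrow(oc), ])
  steps <- abs(d[, 1]) + abs(d[, 2])
  0.948 * sum(steps == 1) + 1.340 * sum(steps == 2)
}

#' Detect endosomes in a top-hat processed channel
#'
#' Connected components (8-connectivity) of the small-radius top-hat image
#' above a threshold, clipped to the cell mask. The default threshold is
#' the Otsu split of the within-mask intensities, floored at 3x the robust
#' noise level (median absolute deviation); components smaller than
#' `min_area` pixels are discarded.
#'
#' @param img Top-hat processed numeric matrix (small radius).
#' @param mask Logical matrix, the cell mask.
#' @param threshold Absolute intensity threshold; `NULL` (default) for
#'   automatic.
#' @param min_area Minimum component area in pixels (default 2).
#' @return Data frame with one row per spot: `spot`, `area`, `perimeter`,
#'   `intensity` (integrated), `cx`, `cy` (centroid), `circularity`;
#'   attribute `labels` holds the label matrix.
#' @export
detect_endosomes <- function(img, mask, threshold = NULL, min_area = 2) {
  empty <- data.frame(spot = integer(), area = numeric(),
                      perimeter = numeric(), intensity = numeric(),
                      cx = numeric(), cy = numeric(),
                      circularity = numeric())
  if (!any(mask)) {
    attr(empty, "labels") <- matrix(0L, nrow(img), ncol(img))
    return(empty)
  }
  vals <- img[mask]
  if (is.null(threshold)) {
    noise <- mad(vals)
    threshold <- max(.otsu(vals), 3 * noise)
  }
  bw <- (img > threshold) & mask
  if (!any(bw)) {
    attr(empty, "labels") <- matrix(0L, nrow(img), ncol(img))
    return(empty)
  }
  lab <- .label8(bw)
  areas <- tabulate(lab[lab > 0])
  keep <- which(areas >= min_area)
  if (!length(keep)) {
    attr(empty, "labels") <- matrix(0L, nrow(img), ncol(img))
    return(empty)
  }
  relab <- integer(length(areas))
  relab[keep] <- seq_along(keep)
  out <- matrix(0L, nrow(lab), ncol(lab))
  out[lab > 0] <- relab[lab[lab > 0]]
  oc <- EBImage::ocontour(out)
  rows <- lapply(seq_along(keep), function(i) {
    px <- which(out == i)
    r <- (px - 1) %% nrow(out) + 1
    cc <- (px - 1) %/% nrow(out) + 1
    A <- length(px)
    P <- .contour_perimeter(oc[[i]])
    data.frame(spot = i, area = A, perimeter = P,
               intensity = sum(img[px]),
               cx = mean(r), cy = mean(cc),
               circularity = min(1, 4 * pi * A / P^2))
  })
  res <- do.call(rbind, rows)
  attr(res, "labels") <- out
  res
}

# mask geometry: area, circularity, centroid
.mask_geometry <- function(mask) {
  A <- sum(mask)
  if (A == 0) return(list(area = 0, circularity = NA_real_,
                          cx = NA_real_, cy = NA_real_))
  oc <- EBImage::ocontour(mask * 1L)
  P <- .contour_perimeter(oc[[1]])
  px <- which(mask)
  list(area = A, circularity = min(1, 4 * pi * A / P^2),
       cx = mean((px - 1) %% nrow(mask) + 1),
       cy = mean((px - 1) %/% nrow(mask) + 1))
}

.coloc_fraction <- function(spots_a, labels_b, mode = "centroid") {
  if (!nrow(spots_a)) return(NA_real_)
  if (mode == "centroid") {
    inside <- vapply(seq_len(nrow(spots_a)), function(i) {
      labels_b[round(spots_a$cx[i]), round(spots_a$cy[i])] > 0
    }, logical(1))
    mean(inside)
  } else {
    la <- attr(spots_a, "labels")
    overl <- vapply(seq_len(nrow(spots_a)), function(i) {
      any(labels_b[la == i] > 0)
    }, logical(1))
    mean(overl)
  }
}

#' Compute the 27 features for one cell
#'
#' @param channels Named list of numeric matrices with elements `nuclear`,
#'   `fluid`, `tf`, `surface` (raw intensities).
#' @param cell_mask,nuc_mask Logical matrices for this cell.
#' @param radii Per-channel top-hat radii, list with `fluid` and `tf`
#'   3-vectors (large, medium, small).
#' @param coloc Colocalization mode: `"centroid"` (spot centroid inside a
#'   partner spot) or `"pixel"` (any pixel overlap).
#' @param tophats Optional precomputed top-hat images (as produced
#'   internally by [extract_well_features()]), to avoid recomputation.
#' @return One-row data frame with the 27 feature columns.
#' @export
compute_cell_features <- function(channels, cell_mask, nuc_mask,
                                  radii = .default_radii,
                                  coloc = c("centroid", "pixel"),
                                  tophats = NULL) {
  coloc <- match.arg(coloc)
  if (!any(cell_mask) || !any(nuc_mask)) stopf("empty mask")
  stopifnot(all(vapply(channels, function(m)
    identical(dim(m), dim(cell_mask)), logical(1))))
  if (is.null(tophats)) {
    tophats <- list(
      fluid = lapply(radii$fluid, function(r) tophat_subtract(channels$fluid, r)),
      tf = lapply(radii$tf, function(r) tophat_subtract(channels$tf, r)),
      surface = tophat_subtract(channels$surface, radii$fluid[1]))
  }
  out <- list()
  chan_feats <- function(th, prefix) {
    v <- setNames(vapply(th, function(m) mean(m[cell_mask]), numeric(1)),
                  paste0(prefix, "int", 1:3))
    v[paste0(prefix, "int4")] <- mean(th[[3]][cell_mask] > 0)
    spots <- detect_endosomes(th[[3]], cell_mask)
    v[paste0(prefix, "num")] <- nrow(spots)
    if (nrow(spots)) {
      v[paste0(prefix, "mph1")] <- mean(spots$area)
      v[paste0(prefix, "mph2")] <- sum(spots$area) / sum(cell_mask)
      v[paste0(prefix, "mph3")] <- mean(spots$circularity)
    } else {
      v[paste0(prefix, "mph", 1:3)] <- NA_real_
    }
    list(v = v, spots = spots)
  }
  fl <- chan_feats(tophats$fluid, "F")
  tf <- chan_feats(tophats$tf, "T")
  okt <- mean(tophats$surface[cell_mask])
  rec <- c(fl$v, tf$v, Okt = okt)
  rec[paste0("Rto", 1:3)] <-
    if (okt > 0) unname(tf$v[paste0("Tint", 1:3)]) / okt else NA_real_
  rec["Fclc"] <- .coloc_fraction(fl$spots, attr(tf$spots, "labels"), coloc)
  rec["Tclc"] <- .coloc_fraction(tf$spots, attr(fl$spots, "labels"), coloc)
  ng <- .mask_geometry(nuc_mask)
  cg <- .mask_geometry(cell_mask)
  nucvals <- channels$nuclear[nuc_mask]
  rec["NucSize"] <- ng$area
  rec["NucCirc"] <- ng$circularity
  rec["NucFluct"] <- if (mean(nucvals) > 0) sd(nucvals) / mean(nucvals) else NA
  rec["NucDist"] <- sqrt((ng$cx - cg$cx)^2 + (ng$cy - cg$cy)^2)
  rec["CellSize"] <- cg$area
  as.data.frame(as.list(rec[feature_catalog()]))
}

#' Extract per-cell feature tables for a whole field of view
#'
#' Computes the top-hat stacks once per channel, then the 27 features for
#' every labeled cell.
#'
#' @param channels Named list of matrices (`nuclear`, `fluid`, `tf`,
#'   `surface`).
#' @param cell_labels,nuc_labels Integer label matrices (0 = background);
#'   nuclear label `i` must belong to cell label `i`.
#' @param ... Passed to [compute_cell_features()].
#' @return Data frame with `cell_id` plus the 27 feature columns.
#' @export
extract_well_features <- function(channels, cell_labels, nuc_labels, ...) {
  radii <- .default_radii
  tophats <- list(
    fluid = lapply(radii$fluid, function(r) tophat_subtract(channels$fluid, r)),
    tf = lapply(radii$tf, function(r) tophat_subtract(channels$tf, r)),
    surface = tophat_subtract(channels$surface, radii$fluid[1]))
  ids <- setdiff(sort(unique(as.vector(cell_labels))), 0)
  rows <- lapply(ids, function(i) {
    rec <- compute_cell_features(channels, cell_labels == i,
                                 nuc_labels == i, tophats = tophats, ...)
    cbind(cell_id = i, rec)
  })
  do.call(rbind, rows)
}

#' Naive nuclear-seeded segmentation (convenience fallback)
#'
#' Otsu-thresholds the nuclear channel into nuclei and grows cell regions
#' from them by Voronoi propagation on the combined intensity. Masks from
#' a dedicated segmentation pipeline should be preferred; this exists so
#' the feature extractor can run on images without external masks.
#'
#' @param nuclear Numeric matrix, nuclear channel.
#' @param cyto Optional numeric matrix guiding cell extent (defaults to a
#'   blurred nuclear channel).
#' @return List with `cell_labels` and `nuc_labels`.
#' @export
segment_cells <- function(nuclear, cyto = NULL) {
  thr <- .otsu(as.vector(nuclear))
  nuc <- .label8(nuclear > thr)
  if (is.null(cyto)) cyto <- EBImage::gblur(nuclear, sigma = 6)
  cells <- EBImage::propagate(EBImage::Image(cyto), EBImage::Image(nuc),
                              lambda = 1e-4)
  list(cell_labels = round(EBImage::imageData(cells)),
       nuc_labels = nuc)
}
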