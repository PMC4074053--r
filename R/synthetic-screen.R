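# Synthetic primary-screen generator.
#
# Emulates the structure of a printed cell-array screen: 10 x 30 wells per
# slide, 30 negative and 8 positive control wells, the remainder carrying
# one dsRNA (gene) each; every gene appears once per slide on three
# replicate slides; each well yields a per-cell table of the 27 features.

#' Configuration of a synthetic primary screen
#'
#' Assembles and validates the parameters of the generator. Defaults follow
#' the screen geometry of the assay platform: 10 x 30 wells per slide with
#' 30 negative and 8 positive controls, triplicate slides, and a
#' negative-binomial number of cells per well with mean 150 (about 100-150
#' cells are seeded per well).
#'
#' Baseline per-cell feature values are drawn from heavy-tailed, bounded
#' families chosen per feature class: log-normal for intensities, gamma for
#' counts and sizes, beta for fractions and circularities. Slide-positional
#' artifacts are multiplicative per-well biases (a linear row gradient, a
#' linear column gradient, and an edge factor) applied to the unbounded
#' features; bounded fraction features are left unperturbed, mirroring the
#' empirical robustness of geometric features.
#'
#' @param n_genes Number of test genes in the screen.
#' @param n_replicates Number of replicate slide sets (screen performed in
#'   triplicate).
#' @param n_rows,n_cols Well grid per slide (default 10 x 30 = 300 wells).
#' @param n_negative,n_positive Control wells per slide.
#' @param cells_per_well List with `mean` and `dispersion` (negative
#'   binomial size) of the per-well cell count.
#' @param artifact List with multiplicative bias magnitudes `row`, `col`,
#'   `edge` (default 0.15 each, i.e. up to +/-15 percent).
#' @param effect_table Data frame with columns `gene`, `feature`,
#'   `kind` (one of `"shift"`, `"scale"`, `"skew"`), `size`, and optionally
#'   `mix_fraction` (fraction of cells in the shifted subpopulation for
#'   `"skew"`; default 0.5). `size` is in units of the baseline SD for
#'   `shift`/`skew` and a multiplicative factor for `scale`.
#' @param positive_effect Effect specification applied to positive-control
#'   wells: list with `features`, `kind`, `size`, `mix_fraction`.
#' @param baseline Data frame with columns `feature`, `family`
#'   (`"lognormal"`, `"gamma"` or `"beta"`), `p1`, `p2` overriding the
#'   default per-feature baseline distributions.
#' @param seed Integer seed; the generator is a pure function of
#'   (config, seed).
#' @return An object of class `screen_config`.
#' @export
screen_config <- function(n_genes = 200,
                          n_replicates = 3,
                          n_rows = 10, n_cols = 30,
                          n_negative = 30, n_positive = 8,
                          cells_per_well = list(mean = 150, dispersion = 10),
                          artifact = list(row = 0.15, col = 0.15, edge = 0.15),
                          effect_table = NULL,
                          positive_effect = list(
                            features = c("Fint1", "Fint2", "Fint3",
                                         "Fmph1", "Fmph2", "Fnum"),
                            kind = "skew", size = 5, mix_fraction = 0.5),
                          baseline = NULL,
                          seed = 1L) {
  feats <- feature_catalog()
  if (cells_per_well$mean < 1)
    stopf("configuration error: cells_per_well mean must be >= 1")
  wells_per_slide <- n_rows * n_cols
  n_test <- wells_per_slide - n_negative - n_positive
  if (n_test <= 0)
    stopf("configuration error: controls exceed wells per slide")
  if (is.null(effect_table)) {
    effect_table <- data.frame(gene = character(), feature = character(),
                               kind = character(), size = numeric(),
                               mix_fraction = numeric())
  }
  if (nrow(effect_table)) {
    if (is.null(effect_table$mix_fraction)) effect_table$mix_fraction <- 0.5
    bad <- setdiff(unique(effect_table$feature), feats)
    if (length(bad))
      stopf("configuration error: unknown effect target feature(s): %s",
            paste(bad, collapse = ", "))
    if (!all(effect_table$kind %in% c("shift", "scale", "skew")))
      stopf("configuration error: effect kind must be shift, scale or skew")
  }
  base <- default_baseline()
  if (!is.null(baseline)) {
    rownames(base) <- base$feature
    base[baseline$feature, c("family", "p1", "p2")] <-
      baseline[, c("family", "p1", "p2")]
  }
  structure(list(
    n_genes = n_genes, n_replicates = n_replicates,
    n_rows = n_rows, n_cols = n_cols,
    n_negative = n_negative, n_positive = n_positive,
    cells_per_well = cells_per_well, artifact = artifact,
    effect_table = effect_table, positive_effect = positive_effect,
    baseline = base, seed = as.integer(seed)
  ), class = "screen_config")
}

#' @export
print.screen_config <- function(x, ...) {
  cat(sprintf(
    "screen_config: %d genes x %d replicates, %dx%d wells/slide (%d neg, %d pos)\n",
    x$n_genes, x$n_replicates, x$n_rows, x$n_cols, x$n_negative, x$n_positive))
  cat(sprintf("  cells/well ~ NB(mean=%g, size=%g); %d planted effects; seed %d\n",
              x$cells_per_well$mean, x$cells_per_well$dispersion,
              nrow(x$effect_table), x$seed))
  invisible(x)
}

# Default baseline distribution per feature: lognormal (meanlog, sdlog) for
# intensities, gamma (shape, scale) for counts/sizes, beta (a, b) for
# fractions. Parameters are stipulated, not fitted to real data.
default_baseline <- function() {
  feats <- feature_catalog()
  fam <- rep("lognormal", length(feats))
  p1 <- rep(log(200), length(feats))
  p2 <- rep(0.6, length(feats))
  names(fam) <- names(p1) <- names(p2) <- feats
  # decreasing means for increasing background subtraction
  p1[c("Fint1", "Tint1")] <- log(400)
  p1[c("Fint2", "Tint2")] <- log(250)
  p1[c("Fint3", "Tint3")] <- log(150)
  p1["Okt"] <- log(300)
  p1[c("Rto1", "Rto2", "Rto3")] <- log(1)
  p2[c("Rto1", "Rto2", "Rto3")] <- 0.5
  gamma_feats <- c("Fmph1", "Tmph1", "Fnum", "Tnum",
                   "NucSize", "NucDist", "CellSize", "NucFluct")
  fam[gamma_feats] <- "gamma"
  p1[gamma_feats] <- 4            # shape
  p2[gamma_feats] <- 5            # scale
  p1["Fnum"] <- 5; p2["Fnum"] <- 4
  p1["Tnum"] <- 5; p2["Tnum"] <- 4
  p1["NucSize"] <- 10; p2["NucSize"] <- 8
  p1["CellSize"] <- 12; p2["CellSize"] <- 40
  p1["NucDist"] <- 2; p2["NucDist"] <- 3
  p1["NucFluct"] <- 6; p2["NucFluct"] <- 0.05
  beta_feats <- .fraction_features()
  fam[beta_feats] <- "beta"
  p1[beta_feats] <- 4; p2[beta_feats] <- 2
  p1[c("Fclc", "Tclc")] <- 2; p2[c("Fclc", "Tclc")] <- 4
  data.frame(feature = feats, family = unname(fam),
             p1 = unname(p1), p2 = unname(p2))
}

# analytic mean/sd of a configured baseline family
baseline_moments <- function(family, p1, p2) {
  switch(family,
    lognormal = {
      m <- exp(p1 + p2^2 / 2)
      s <- sqrt((exp(p2^2) - 1)) * m
      c(mean = m, sd = s)
    },
    gamma = c(mean = p1 * p2, sd = sqrt(p1) * p2),
    beta = {
      m <- p1 / (p1 + p2)
      s <- sqrt(p1 * p2 / ((p1 + p2)^2 * (p1 + p2 + 1)))
      c(mean = m, sd = s)
    },
    stopf("unknown baseline family '%s'", family))
}

.draw_baseline <- function(n, family, p1, p2) {
  switch(family,
    lognormal = rlnorm(n, p1, p2),
    gamma = rgamma(n, shape = p1, scale = p2),
    beta = rbeta(n, p1, p2),
    stopf("unknown baseline family '%s'", family))
}

# apply one planted effect to a vector of baseline draws
.apply_effect <- function(x, kind, size, mix_fraction, sd_f, bounded) {
  y <- switch(kind,
    shift = x + size * sd_f,
    scale = x * size,
    skew = {
      n_shift <- round(length(x) * mix_fraction)
      if (n_shift > 0) {
        idx <- seq_len(n_shift)   # cells are exchangeable; first block
        x[idx] <- x[idx] + size * sd_f
      }
      x
    },
    stopf("unknown effect kind '%s'", kind))
  y <- pmax(y, 0)
  if (bounded) y <- pmin(y, 1)
  y
}

#' Plate layout for one replicate of a synthetic screen
#'
#' Distributes genes over slides (each slide holds
#' `n_rows * n_cols - n_negative - n_positive` test wells), and assigns
#' negative/positive control wells to seeded random grid positions.
#' Every gene appears exactly once per replicate.
#'
#' @param config A [screen_config()].
#' @param replicate Replicate index (1-based).
#' @return Data frame with one row per well: `slide`, `replicate`, `well_id`,
#'   `row`, `col` (0-based), `role`, `gene`.
#' @export
layout_replicate <- function(config, replicate = 1L) {
  wells <- config$n_rows * config$n_cols
  n_test <- wells - config$n_negative - config$n_positive
  genes <- paste0("g", seq_len(config$n_genes))
  n_slides <- ceiling(config$n_genes / n_test)
  with_seed(child_seed(config$seed, 1000L + replicate), {
    gene_order <- sample(genes)
    out <- vector("list", n_slides)
    for (s in seq_len(n_slides)) {
      slide_genes <- gene_order[((s - 1) * n_test + 1):min(s * n_test,
                                                          length(gene_order))]
      role <- rep("empty", wells)
      pos <- sample.int(wells, config$n_negative + config$n_positive +
                          length(slide_genes))
      role[pos[seq_len(config$n_negative)]] <- "negative"
      role[pos[config$n_negative + seq_len(config$n_positive)]] <- "positive"
      test_pos <- pos[config$n_negative + config$n_positive +
                        seq_along(slide_genes)]
      role[test_pos] <- "test"
      gene <- rep(NA_character_, wells)
      gene[test_pos] <- slide_genes
      out[[s]] <- data.frame(
        slide = sprintf("r%d_s%d", replicate, s),
        replicate = as.integer(replicate),
        well_id = sprintf("r%d_s%d_w%03d", replicate, s, seq_len(wells)),
        row = (seq_len(wells) - 1L) %% config$n_rows,
        col = (seq_len(wells) - 1L) %/% config$n_rows,
        role = role, gene = gene)
    }
    do.call(rbind, out)
  })
}

# per-well multiplicative artifact field for one slide
.artifact_field <- function(config, layout_slide, slide_seed) {
  a <- config$artifact
  nr <- config$n_rows; nc <- config$n_cols
  with_seed(slide_seed, {
    # random gradient direction per slide, linear across rows/columns
    row_dir <- sample(c(-1, 1), 1)
    col_dir <- sample(c(-1, 1), 1)
    row_f <- 1 + row_dir * a$row * (2 * layout_slide$row / (nr - 1) - 1)
    col_f <- 1 + col_dir * a$col * (2 * layout_slide$col / (nc - 1) - 1)
    edge <- layout_slide$row %in% c(0, nr - 1) |
      layout_slide$col %in% c(0, nc - 1)
    edge_f <- ifelse(edge, 1 + a$edge, 1)
    row_f * col_f * edge_f
  })
}

#' Generate a synthetic primary screen with known ground truth
#'
#' Draws per-cell feature tables for every well of every slide of every
#' replicate. Negative wells are baseline draws modulated only by the
#' slide-positional artifact field; test wells are additionally modulated
#' by their gene's planted effect; positive wells receive the configured
#' positive-control effect. Deterministic for a fixed config (which
#' includes the seed).
#'
#' @param config A [screen_config()].
#' @return Object of class `primary_screen`: list with `cells` (one row per
#'   cell: well metadata plus the 27 feature columns), `layout` (one row
#'   per well, including the artifact factor), and `truth` (list with
#'   `effect_table` = planted nonzero effects, `true_hits` = gene ->
#'   feature sets).
#' @export
#' @examples
#' cfg <- screen_config(n_genes = 20, n_replicates = 2,
#'                      cells_per_well = list(mean = 40, dispersion = 10),
#'                      seed = 7)
#' scr <- generate_primary_screen(cfg)
#' table(scr$layout$role)
generate_primary_screen <- function(config) {
  stopifnot(inherits(config, "screen_config"))
  feats <- feature_catalog()
  base <- config$baseline
  rownames(base) <- base$feature
  eff <- config$effect_table
  keep <- ifelse(eff$kind == "scale", eff$size != 1, eff$size != 0)
  eff <- eff[keep, , drop = FALSE]
  layouts <- lapply(seq_len(config$n_replicates),
                    function(r) layout_replicate(config, r))
  layout <- do.call(rbind, layouts)
  slides <- unique(layout$slide)
  cells_list <- vector("list", length(slides))
  layout$artifact <- NA_real_
  for (si in seq_along(slides)) {
    sl <- slides[si]
    lsl <- layout[layout$slide == sl, , drop = FALSE]
    sseed <- child_seed(config$seed, 5000L + si)
    art <- .artifact_field(config, lsl, sseed)
    layout$artifact[layout$slide == sl] <- art
    occupied <- lsl$role != "empty"
    lso <- lsl[occupied, , drop = FALSE]
    arto <- art[occupied]
    cells_list[[si]] <- with_seed(child_seed(config$seed, 9000L + si), {
      ncell <- rnbinom(nrow(lso), mu = config$cells_per_well$mean,
                       size = config$cells_per_well$dispersion)
      ncell <- pmax(ncell, 1L)
      widx <- rep(seq_len(nrow(lso)), ncell)
      tab <- data.frame(
        well_id = lso$well_id[widx], slide = lso$slide[widx],
        row = lso$row[widx], col = lso$col[widx],
        role = lso$role[widx], gene = lso$gene[widx],
        replicate = lso$replicate[widx],
        cell_id = sequence(ncell))
      total <- sum(ncell)
      off <- c(0L, cumsum(ncell))
      for (f in feats) {
        fam <- base[f, "family"]; p1 <- base[f, "p1"]; p2 <- base[f, "p2"]
        x <- .draw_baseline(total, fam, p1, p2)
        mom <- baseline_moments(fam, p1, p2)
        bounded <- f %in% .fraction_features()
        # planted effects, per well
        if (nrow(eff)) {
          eff_f <- eff[eff$feature == f, , drop = FALSE]
          if (nrow(eff_f)) {
            hit_wells <- which(lso$gene %in% eff_f$gene)
            for (wi in hit_wells) {
              e <- eff_f[match(lso$gene[wi], eff_f$gene), ]
              rng <- (off[wi] + 1L):off[wi + 1L]
              x[rng] <- .apply_effect(x[rng], e$kind, e$size,
                                      e$mix_fraction, mom["sd"], bounded)
            }
          }
        }
        pe <- config$positive_effect
        if (f %in% pe$features) {
          for (wi in which(lso$role == "positive")) {
            rng <- (off[wi] + 1L):off[wi + 1L]
            x[rng] <- .apply_effect(x[rng], pe$kind, pe$size,
                                    pe$mix_fraction %||% 0.5, mom["sd"],
                                    bounded)
          }
        }
        # positional artifact, multiplicative, unbounded features only
        if (!bounded) x <- x * arto[widx]
        if (f %in% c("Fnum", "Tnum")) x <- round(x)
        tab[[f]] <- x
      }
      tab
    })
  }
  cells <- do.call(rbind, cells_list)
  rownames(cells) <- NULL
  true_hits <- if (nrow(eff)) split(eff$feature, eff$gene) else list()
  structure(list(cells = cells,
                 layout = layout[layout$role != "empty", , drop = FALSE],
                 truth = list(effect_table = eff, true_hits = true_hits)),
            class = "primary_screen")
}

#' @export
print.primary_screen <- function(x, ...) {
  cat(sprintf("primary_screen: %d slides, %d wells, %d cells, %d genes\n",
              length(unique(x$layout$slide)), nrow(x$layout),
              nrow(x$cells), length(unique(stats::na.omit(x$layout$gene)))))
  invisible(x)
}

#' Effect table for nested gene groups
#'
#' Convenience constructor for planted hierarchical structure: each group
#' of genes perturbs one feature set, and the feature sets are nested (or
#' otherwise clade-like), so the induced binary characters support a known
#' tree. Used by the recovery analyses.
#'
#' @param feature_sets Named list of character vectors (feature subsets).
#' @param genes_per_set Number of genes planted per set.
#' @param kind,size,mix_fraction Effect parameters (see [screen_config()]).
#' @param prefix Gene-name prefix.
#' @return Data frame usable as `effect_table` in [screen_config()].
#' @export
nested_effect_table <- function(feature_sets, genes_per_set = 10,
                                kind = "skew", size = 4,
                                mix_fraction = 0.5, prefix = "g") {
  out <- list()
  g <- 0L
  for (nm in names(feature_sets)) {
    for (i in seq_len(genes_per_set)) {
      g <- g + 1L
      out[[length(out) + 1L]] <- data.frame(
        gene = sprintf("%s%d", prefix, g),
        feature = feature_sets[[nm]],
        kind = kind, size = size, mix_fraction = mix_fraction,
        set = nm)
    }
  }
  do.call(rbind, out)
}
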