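# Replicate-consistent hit calling on the triplicate Z-score array,
# permutation null curves, and binarization into 27-bit feature vectors.

#' Call hits with the 2-of-3 replicate rule
#'
#' A gene is a hit for a feature if at least `min_reps` of its replicate
#' Z-scores reach the threshold (inclusive `>=` by default, matching the
#' published `Z >= 3` rule; set `strict = TRUE` for `>`). Missing
#' replicates count as failures. Genes with fewer than 2 scored replicates
#' for a feature are flagged unevaluable for it.
#'
#' @param z A `zscore_matrix` (gene x feature x replicate array, see
#'   [zscore_matrix()]).
#' @param threshold Z threshold (default 3).
#' @param min_reps Replicates required at threshold (default 2 of 3).
#' @param strict Use strict `>` instead of `>=`.
#' @return Object of class `hit_matrix`: logical gene x feature matrix with
#'   attributes `threshold`, `min_reps`, `evaluable` (logical matrix, `TRUE`
#'   where >= 2 replicates were scored).
#' @export
#' @examples
#' z <- array(c(3.5, 3.1, 0.2), dim = c(1, 1, 3),
#'            dimnames = list("g1", "Fint1", paste0("rep", 1:3)))
#' call_hits(structure(z, class = c("zscore_matrix", "array")))[1, 1]
call_hits <- function(z, threshold = 3, min_reps = 2, strict = FALSE) {
  stopifnot(threshold > 0, min_reps %in% 1:3)
  pass <- if (strict) z > threshold else z >= threshold
  pass[is.na(pass)] <- FALSE
  n_pass <- apply(pass, c(1, 2), sum)
  n_scored <- apply(!is.na(z), c(1, 2), sum)
  hits <- n_pass >= min_reps
  structure(hits, class = "hit_matrix", threshold = threshold,
            min_reps = min_reps, strict = strict,
            evaluable = n_scored >= 2)
}

#' Observed versus gene-permuted hit counts over a threshold grid
#'
#' For each permutation, gene labels are shuffled within each replicate
#' (`scope = "replicate"`, default): every gene keeps its intact 27-feature
#' profile per replicate, so all marginal Z distributions and within-well
#' feature correlations are preserved and only the across-replicate
#' concordance that real hits produce is broken. Since the screen itself
#' assigns genes to wells by one independent permutation per replicate,
#' a null screen is exactly exchangeable with the permuted datasets and
#' the permutation spread is the correct yardstick for the observed count.
#' `scope = "feature"` shuffles independently per feature and replicate
#' instead (also breaking within-replicate feature coupling).
#'
#' @param z A `zscore_matrix`.
#' @param thresholds Z thresholds to scan.
#' @param n_perm Number of permutations (>= 10).
#' @param min_reps Replicate rule (default 2).
#' @param scope `"replicate"` (default) or `"feature"`; see above.
#' @param seed Integer seed.
#' @return Data frame per threshold: `observed` and `perm_mean`/`perm_sd`
#'   count hit (gene, feature) pairs — the statistic whose per-feature
#'   marginals the permutation preserves exactly — and `observed_genes`,
#'   `perm_genes_mean`, `perm_genes_sd` count distinct hit genes.
#' @export
permutation_hit_curve <- function(z, thresholds = 2:5, n_perm = 50,
                                  min_reps = 2,
                                  scope = c("replicate", "feature"),
                                  seed = 1L) {
  scope <- match.arg(scope)
  if (n_perm < 10) stopf("n_perm must be >= 10")
  count_hits <- function(zz, t) {
    pass <- zz >= t
    pass[is.na(pass)] <- FALSE
    n_pass <- apply(pass, c(1, 2), sum)
    hit <- n_pass >= min_reps
    c(pairs = sum(hit), genes = sum(rowSums(hit) > 0))
  }
  obs <- vapply(thresholds, function(t) count_hits(z, t), numeric(2))
  G <- dim(z)[1]
  perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(p) {
      zp <- z
      if (scope == "replicate") {
        for (r in seq_len(dim(z)[3]))
          zp[, , r] <- z[sample.int(G), , r]
      } else {
        for (f in seq_len(dim(z)[2]))
          for (r in seq_len(dim(z)[3]))
            zp[, f, r] <- z[sample.int(G), f, r]
      }
      vapply(thresholds, function(t) count_hits(zp, t), numeric(2))
    }, matrix(0, 2, length(thresholds)))
  })
  # perm: 2 x thresholds x n_perm
  data.frame(threshold = thresholds,
             observed = obs["pairs", ],
             perm_mean = apply(perm[1, , , drop = FALSE], 2, mean),
             perm_sd = apply(perm[1, , , drop = FALSE], 2, sd),
             observed_genes = obs["genes", ],
             perm_genes_mean = apply(perm[2, , , drop = FALSE], 2, mean),
             perm_genes_sd = apply(perm[2, , , drop = FALSE], 2, sd))
}

#' Binarize a hit matrix into per-gene feature vectors
#'
#' One 27-bit feature vector per evaluable gene; genes with an all-zero
#' vector are excluded from the hit set (`is_hit = FALSE`).
#'
#' @param hits A `hit_matrix` from [call_hits()].
#' @return Data frame with `gene`, one logical column per feature,
#'   `n_features_hit`, and `is_hit`.
#' @export
binarize <- function(hits) {
  stopifnot(inherits(hits, "hit_matrix"))
  m <- unclass(hits)
  df <- data.frame(gene = rownames(m), m, check.names = FALSE,
                   row.names = NULL)
  df$n_features_hit <- rowSums(m)
  df$is_hit <- df$n_features_hit > 0
  df
}

#' Summarize a hit set by phenotype category
#'
#' Counts unique hit genes overall and per feature category (fluid-phase,
#' transferrin, nuclear morphology, cell size). Duplicated technical
#' control entries are deduplicated by unique identifier here only (they
#' stay distinct through scoring and hit calling): an entry named
#' `"geneX#2"` counts as `"geneX"`.
#'
#' @param hits A `hit_matrix`.
#' @return List with `n_hits` (unique hit identifiers) and `by_category`
#'   counts.
#' @export
summarize_hits <- function(hits) {
  fv <- binarize(hits)
  uid <- sub("#.*$", "", fv$gene)
  cats <- .feature_categories()
  feat_cols <- intersect(colnames(hits), feature_catalog())
  by_cat <- vapply(cats, function(fs) {
    fs <- intersect(fs, feat_cols)
    sel <- rowSums(fv[, fs, drop = FALSE]) > 0
    length(unique(uid[sel]))
  }, numeric(1))
  list(n_hits = length(unique(uid[fv$is_hit])), by_category = by_cat)
}
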