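# Secondary pulse/chase classification assay: each gene measured in
# triplicate next to 3 local positive and 6 local negative control wells;
# per-gene fold-changes are taken relative to the local negatives, tested
# with a two-sample t-test, and significant genes are placed into
# quadrants by the direction of their pulse and chase effects.

#' Generate a synthetic secondary classification plate
#'
#' Lays out one local group per gene (3 test replicates, 3 local
#' positives, 6 local negatives) and draws per-well mean pulse and chase
#' intensities log-normally around the negative-control baseline times the
#' gene's configured fold-changes. The ground-truth quadrant implied by
#' the folds is recorded.
#'
#' @param genes Character vector of tested genes.
#' @param effect_table Data frame with columns `gene`, `pulse_fold`,
#'   `chase_fold` (genes absent default to folds of 1).
#' @param cv Within-plate coefficient of variation of well means
#'   (default 0.08).
#' @param baseline_pulse,baseline_chase Negative-control mean intensities.
#' @param positive_fold Fold-change of the local positive controls
#'   (applied to both channels).
#' @param layout Local-group layout: list with `n_test`, `n_positive`,
#'   `n_negative` wells per gene group. The assay design requires a test
#'   triplet with 3 local positives and 6 local negatives; other counts
#'   raise an error.
#' @param seed Integer seed.
#' @return Object of class `secondary_plate`: list with `wells` (data
#'   frame: well_id, group, gene, role, replicate, pulse, chase) and
#'   `truth` (gene, pulse_fold, chase_fold, quadrant).
#' @export
generate_secondary_plate <- function(genes, effect_table = NULL, cv = 0.08,
                                     baseline_pulse = 1000,
                                     baseline_chase = 800,
                                     positive_fold = 0.3,
                                     layout = list(n_test = 3, n_positive = 3,
                                                   n_negative = 6),
                                     seed = 1L) {
  if (layout$n_test != 3 || layout$n_positive != 3 || layout$n_negative != 6)
    stopf("layout violates local-control counts (need 3 test + 3 positive + 6 negative wells per group)")
  if (is.null(effect_table))
    effect_table <- data.frame(gene = character(), pulse_fold = numeric(),
                               chase_fold = numeric())
  pf <- setNames(rep(1, length(genes)), genes)
  cf <- pf
  idx <- match(effect_table$gene, genes)
  pf[idx[!is.na(idx)]] <- effect_table$pulse_fold[!is.na(idx)]
  cf[idx[!is.na(idx)]] <- effect_table$chase_fold[!is.na(idx)]
  sdlog <- sqrt(log(1 + cv^2))
  wells <- with_seed(seed, {
    out <- vector("list", length(genes))
    for (i in seq_along(genes)) {
      role <- c(rep("test", 3), rep("positive", 3), rep("negative", 6))
      fold_p <- c(rep(pf[i], 3), rep(positive_fold, 3), rep(1, 6))
      fold_c <- c(rep(cf[i], 3), rep(positive_fold, 3), rep(1, 6))
      out[[i]] <- data.frame(
        well_id = sprintf("%s_w%02d", genes[i], seq_along(role)),
        group = genes[i],
        gene = ifelse(role == "test", genes[i], NA_character_),
        role = role, replicate = c(1:3, 1:3, 1:6),
        pulse = rlnorm(12, log(baseline_pulse * fold_p) - sdlog^2 / 2, sdlog),
        chase = rlnorm(12, log(baseline_chase * fold_c) - sdlog^2 / 2, sdlog))
    }
    do.call(rbind, out)
  })
  dir_p <- ifelse(pf > 1, 1L, ifelse(pf < 1, -1L, 0L))
  dir_c <- ifelse(cf > 1, 1L, ifelse(cf < 1, -1L, 0L))
  truth <- data.frame(gene = genes, pulse_fold = unname(pf),
                      chase_fold = unname(cf),
                      quadrant = .quadrant_from_dirs(dir_p, dir_c))
  structure(list(wells = wells, truth = truth), class = "secondary_plate")
}

# quadrant from dichotomized axis directions (-1, 0, +1):
# 1 = pulse and chase both up; 3 = both down; 2 = chase-driven patterns
# (chase effect with pulse unchanged or opposing, i.e. late-acting);
# 4 = pulse-driven patterns; "null" when neither axis moves.
.quadrant_from_dirs <- function(dir_p, dir_c) {
  q <- rep("null", length(dir_p))
  q[dir_p > 0 & dir_c > 0] <- "1"
  q[dir_p < 0 & dir_c < 0] <- "3"
  q[dir_c != 0 & dir_p <= 0 & !(dir_p < 0 & dir_c < 0) &
      !(dir_p > 0 & dir_c > 0)] <- "2"
  q[dir_p != 0 & (dir_c == 0 | (dir_p > 0 & dir_c < 0))] <- "4"
  q
}

#' Normalize test wells to their local negative controls
#'
#' Fold ratio of the mean of the test replicate means to the mean of the
#' local negative well means; per-replicate ratios are retained.
#'
#' @param test Numeric vector of test replicate means (length >= 1).
#' @param negatives Numeric vector of local negative well means
#'   (length >= 2).
#' @return List with `ratio` and `replicate_ratios`.
#' @export
#' @examples
#' normalize_to_local_controls(c(10, 12, 14), rep(8, 6))$ratio  # 1.5
normalize_to_local_controls <- function(test, negatives) {
  if (length(negatives) < 2) stopf("need >= 2 local negative wells")
  m <- mean(negatives)
  if (!is.finite(m) || m == 0) stopf("zero local negative mean")
  list(ratio = mean(test) / m, replicate_ratios = test / m)
}

#' Two-sample test of a gene against its local negatives
#'
#' Two-sided location test of the test replicate values against the local
#' negative values; Welch's unequal-variance t-test by default, pooled
#' variance behind a flag. Degenerate inputs (both groups constant and
#' equal) return p = 1.
#'
#' @param test Numeric vector (length >= 2).
#' @param negatives Numeric vector (length >= 2).
#' @param pooled Use the pooled-variance form.
#' @return Two-sided p-value.
#' @export
test_gene <- function(test, negatives, pooled = FALSE) {
  if (length(test) < 2 || length(negatives) < 2)
    stopf("need >= 2 values per group")
  if (var(test) == 0 && var(negatives) == 0) {
    return(if (mean(test) == mean(negatives)) 1 else .Machine$double.xmin)
  }
  t.test(test, negatives, var.equal = pooled)$p.value
}

#' Assign a gene to a pulse/chase quadrant
#'
#' Axes are dichotomized at a fold ratio of 1 and gated on significance at
#' `alpha` (a gene enters a quadrant only if at least one axis is
#' significant): both axes up is quadrant 1, both down quadrant 3,
#' chase-driven patterns (significant chase with pulse unchanged or
#' down-while-chase-up) quadrant 2, pulse-driven patterns quadrant 4. The
#' significance class records which axes pass, orthogonally to the
#' quadrant.
#'
#' @param pulse_ratio,chase_ratio Fold ratios (> 0).
#' @param p_pulse,p_chase Per-axis p-values.
#' @param alpha Significance cut (default 0.10).
#' @return List with `quadrant` (`"1"`, `"2"`, `"3"`, `"4"` or `"null"`)
#'   and `class` (`"pulse-only"`, `"chase-only"`, `"both"`, `"none"`).
#' @export
assign_quadrant <- function(pulse_ratio, chase_ratio, p_pulse, p_chase,
                            alpha = 0.10) {
  stopifnot(pulse_ratio > 0, chase_ratio > 0)
  sig_p <- is.finite(p_pulse) && p_pulse < alpha
  sig_c <- is.finite(p_chase) && p_chase < alpha
  cls <- if (sig_p && sig_c) "both" else if (sig_p) "pulse-only"
         else if (sig_c) "chase-only" else "none"
  if (!sig_p && !sig_c)
    return(list(quadrant = "null", class = "none"))
  dir_p <- if (sig_p) sign(pulse_ratio - 1) else 0
  dir_c <- if (sig_c) sign(chase_ratio - 1) else 0
  list(quadrant = .quadrant_from_dirs(dir_p, dir_c), class = cls)
}

#' Analyze a secondary plate into per-gene records
#'
#' Runs local-control normalization, per-axis significance testing and
#' quadrant assignment for every gene of a secondary plate.
#'
#' @param plate A `secondary_plate` (or a compatible list with a `wells`
#'   data frame).
#' @param alpha Significance cut (default 0.10).
#' @param pooled Pooled-variance t-test flag (see [test_gene()]).
#' @return Data frame of class `secondary_records`: gene, pulse_ratio,
#'   chase_ratio, p_pulse, p_chase, quadrant, class.
#' @export
analyze_secondary_plate <- function(plate, alpha = 0.10, pooled = FALSE) {
  w <- plate$wells
  genes <- unique(w$group)
  out <- lapply(genes, function(g) {
    wg <- w[w$group == g, ]
    te <- wg[wg$role == "test", ]
    ne <- wg[wg$role == "negative", ]
    np <- normalize_to_local_controls(te$pulse, ne$pulse)
    nc <- normalize_to_local_controls(te$chase, ne$chase)
    pp <- test_gene(te$pulse, ne$pulse, pooled = pooled)
    pc <- test_gene(te$chase, ne$chase, pooled = pooled)
    q <- assign_quadrant(np$ratio, nc$ratio, pp, pc, alpha = alpha)
    data.frame(gene = g, pulse_ratio = np$ratio, chase_ratio = nc$ratio,
               p_pulse = pp, p_chase = pc, quadrant = q$quadrant,
               class = q$class)
  })
  res <- do.call(rbind, out)
  class(res) <- c("secondary_records", "data.frame")
  res
}

#' Exact binomial sign test (upper tail)
#'
#' `P(X >= k)` for `X ~ Binomial(n, p0)`; the summary statistic used to
#' show that per-feature secondary confirmation rates beat chance for
#' nearly all features.
#'
#' @param k Number of successes.
#' @param n Number of trials.
#' @param p0 Null success probability (default 0.5).
#' @return Upper-tail probability.
#' @export
#' @examples
#' binomial_sign_test(21, 22)  # 23 / 2^22
binomial_sign_test <- function(k, n, p0 = 0.5) {
  stopifnot(k >= 0, k <= n)
  if (k == 0) return(1)
  pbinom(k - 1, n, p0, lower.tail = FALSE)
}

#' Cross-tabulate pathway effects between two classification assays
#'
#' Deterministic set algebra on per-gene effect directions from two assays
#' (e.g. fluid-phase/CG versus transferrin/CD): genes down in both, up in
#' both, with opposing effects, or measured with an effect in only one
#' assay.
#'
#' @param a,b `secondary_records` data frames (or any data frame with
#'   `gene`, `pulse_ratio`, `quadrant`).
#' @return List of character vectors: `both_down`, `both_up`, `opposing`,
#'   `single_pathway`.
#' @export
crosstab_pathways <- function(a, b) {
  dir_of <- function(r) {
    d <- ifelse(r$quadrant == "null", 0, sign(r$pulse_ratio - 1))
    setNames(d, r$gene)
  }
  da <- dir_of(a); db <- dir_of(b)
  common <- intersect(names(da), names(db))
  ca <- da[common]; cb <- db[common]
  list(both_down = common[ca < 0 & cb < 0],
       both_up = common[ca > 0 & cb > 0],
       opposing = common[ca * cb < 0],
       single_pathway = c(common[xor(ca == 0, cb == 0)],
                          setdiff(names(da), common),
                          setdiff(names(db), common)))
}
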