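# Enrichment statistics for tree nodes: hypergeometric tests against
# annotation or external-screen gene lists, and a permutation test for
# within-node protein-protein interaction density.

#' Filter an interaction edge list by confidence
#'
#' Keeps edges with confidence greater than or equal to `min_conf`
#' (inclusive, matching the published STRING-score cut of >= 0.400).
#'
#' @param edges Data frame with columns `a`, `b`, `confidence`.
#' @param min_conf Minimum confidence (default 0.400).
#' @return Filtered edge list.
#' @export
filter_edges <- function(edges, min_conf = 0.400) {
  edges[edges$confidence >= min_conf, , drop = FALSE]
}

# canonicalize an undirected edge list: drop self-edges, merge duplicates
# (keeping the maximum confidence)
.canonical_edges <- function(edges) {
  a <- pmin(edges$a, edges$b)
  b <- pmax(edges$a, edges$b)
  keep <- a != b
  e <- data.frame(a = a[keep], b = b[keep],
                  confidence = edges$confidence[keep])
  e <- e[order(e$a, e$b, -e$confidence), ]
  e[!duplicated(e[, c("a", "b")]), ]
}

#' Upper-tail hypergeometric enrichment test
#'
#' Probability of drawing at least the observed number of annotated genes
#' if a study-set-sized list were drawn at random from the universe:
#' `P(X >= k)` for `X ~ Hypergeometric(N = |universe|, K = |annotated|,
#' n = |study|)`.
#'
#' @param study,annotated Character vectors, both subsets of `universe`.
#' @param universe Character vector, the population.
#' @return Raw upper-tail p-value.
#' @export
#' @examples
#' hypergeom_test(letters[1:5], letters[1:5], letters[1:20])
hypergeom_test <- function(study, annotated, universe) {
  study <- unique(study); annotated <- unique(annotated)
  if (!all(study %in% universe)) stopf("study set is not within the universe")
  annotated <- intersect(annotated, universe)
  k <- length(intersect(study, annotated))
  phyper(k - 1, length(annotated), length(universe) - length(annotated),
         length(study), lower.tail = FALSE)
}

#' Multiple-testing correction
#'
#' Benjamini-Hochberg by default (Bonferroni and the other
#' [stats::p.adjust()] methods available); corrected values are monotone
#' and never below the raw p-values.
#'
#' @param p Numeric vector of raw p-values in (0, 1].
#' @param method Correction method (default `"BH"`).
#' @return Corrected p-values.
#' @export
correct_pvalues <- function(p, method = c("BH", "bonferroni", "holm", "BY")) {
  method <- match.arg(method)
  p.adjust(p, method = method)
}

#' Permutation test for within-node interaction enrichment
#'
#' The observed statistic per node is the number of (confidence-filtered)
#' edges with both endpoints inside the node's gene set. Permuted
#' interaction datasets are constructed keeping the total number of
#' interactions constant: by default edges are rewired by drawing endpoint
#' pairs uniformly from the network's gene universe (no self-edges or
#' duplicates); a degree-preserving double-edge-swap variant is available
#' for sensitivity analysis. The empirical p-value per node is
#' `(1 + #\{perm >= observed\}) / (n_perm + 1)`, BH-corrected across nodes.
#'
#' @param nodes Named list of character vectors (gene set per node).
#' @param edges Edge list data frame (`a`, `b`, `confidence`), already or
#'   not yet confidence-filtered.
#' @param n_perm Number of permuted datasets (default 10000; >= 100).
#' @param min_conf Confidence filter applied first (default 0.400).
#' @param scheme `"uniform"` endpoint rewiring (default) or
#'   `"degree_preserving"` double-edge swaps.
#' @param seed Integer seed.
#' @return Data frame: `node`, `n_genes`, `observed`, `perm_mean`, `p`,
#'   `p_adj`.
#' @export
interaction_enrichment <- function(nodes, edges, n_perm = 10000,
                                   min_conf = 0.400,
                                   scheme = c("uniform", "degree_preserving"),
                                   seed = 1L) {
  scheme <- match.arg(scheme)
  if (n_perm < 100) stopf("n_perm must be >= 100")
  e <- .canonical_edges(filter_edges(edges, min_conf))
  genes <- sort(unique(c(e$a, e$b)))
  N <- length(genes)
  M <- nrow(e)
  memb <- vapply(nodes, function(g) genes %in% g, logical(N))
  ai <- match(e$a, genes); bi <- match(e$b, genes)
  count_within <- function(ai, bi) colSums(memb[ai, , drop = FALSE] &
                                             memb[bi, , drop = FALSE])
  obs <- count_within(ai, bi)
  npairs <- N * (N - 1) / 2
  ge <- vapply(nodes, function(g) length(g), integer(1))
  perm_ge <- matrix(0, n_perm, length(nodes))
  with_seed(seed, {
    for (p in seq_len(n_perm)) {
      if (scheme == "uniform") {
        id <- sample(npairs, M) - 1
        # decode unordered pair index: row-major upper triangle
        pa <- floor((2 * N - 1 - sqrt((2 * N - 1)^2 - 8 * id)) / 2)
        pb <- id - pa * N + pa * (pa + 1) / 2 + pa + 1
        perm_ge[p, ] <- count_within(pa + 1, pb + 1)
      } else {
        pa <- ai; pb <- bi
        for (s in seq_len(2 * M)) {
          ij <- sample.int(M, 2)
          # swap partners; reject if it creates a self-edge
          na1 <- pa[ij[1]]; nb1 <- pb[ij[2]]
          na2 <- pa[ij[2]]; nb2 <- pb[ij[1]]
          if (na1 != nb1 && na2 != nb2) {
            pb[ij[1]] <- nb1; pb[ij[2]] <- nb2
          }
        }
        perm_ge[p, ] <- count_within(pa, pb)
      }
    }
  })
  pv <- vapply(seq_along(nodes), function(i) {
    if (ge[i] < 2) return(1)
    (1 + sum(perm_ge[, i] >= obs[i])) / (n_perm + 1)
  }, numeric(1))
  data.frame(node = names(nodes), n_genes = ge, observed = obs,
             perm_mean = colMeans(perm_ge), p = pv,
             p_adj = correct_pvalues(pv), row.names = NULL)
}

#' Overlap of node gene sets with external screen hit lists
#'
#' Overlap is quantified as the fraction of the node's genes also present
#' in the external list, with an upper-tail hypergeometric p-value against
#' the shared universe.
#'
#' @param nodes Named list of gene sets.
#' @param lists Named list of external hit lists (character vectors).
#' @param universe Population gene set; lists are intersected with it. If
#'   more than half of a list is outside the universe the identifier
#'   spaces are considered mismatched and an error is raised.
#' @return Data frame: `node`, `list`, `overlap`, `fraction`, `p`.
#' @export
screen_overlap <- function(nodes, lists, universe) {
  rows <- list()
  for (ln in names(lists)) {
    l <- unique(lists[[ln]])
    if (length(l) && mean(l %in% universe) < 0.5)
      stopf("identifier-space mismatch: >50%% of list '%s' unmapped", ln)
    l <- intersect(l, universe)
    for (nn in names(nodes)) {
      g <- intersect(unique(nodes[[nn]]), universe)
      ov <- length(intersect(g, l))
      rows[[length(rows) + 1]] <- data.frame(
        node = nn, list = ln, overlap = ov,
        fraction = if (length(g)) ov / length(g) else NA_real_,
        p = if (length(g)) hypergeom_test(g, l, universe) else NA_real_)
    }
  }
  do.call(rbind, rows)
}
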