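# Synthetic annotation maps and interaction networks with planted
# structure, for exercising the enrichment and GO pull-up stages against
# known ground truth.

#' Generate a synthetic gene-to-term annotation map
#'
#' Planted terms annotate exactly the given gene sets; background terms
#' annotate genes drawn uniformly at random from the universe.
#'
#' @param universe Character vector of genes (non-empty).
#' @param n_terms Number of background terms.
#' @param planted Named list term -> gene set (subsets of the universe).
#' @param genes_per_term Mean genes per background term (Poisson-ish:
#'   uniform between half and twice this value).
#' @param seed Integer seed.
#' @return An [annotation_map()].
#' @export
generate_annotations <- function(universe, n_terms = 20, planted = list(),
                                 genes_per_term = 15, seed = 1L) {
  if (!length(universe)) stopf("empty gene universe")
  for (t in names(planted)) {
    if (!all(planted[[t]] %in% universe))
      stopf("planted gene outside universe in term '%s'", t)
  }
  tabs <- list()
  for (t in names(planted))
    tabs[[length(tabs) + 1]] <- data.frame(gene = planted[[t]], term = t)
  with_seed(seed, {
    for (i in seq_len(n_terms)) {
      n <- sample(max(1, round(genes_per_term / 2)):
                    round(genes_per_term * 2), 1)
      n <- min(n, length(universe))
      tabs[[length(tabs) + 1]] <- data.frame(
        gene = sample(universe, n), term = sprintf("bg_term_%03d", i))
    }
  })
  annotation_map(do.call(rbind, tabs))
}

#' Generate a synthetic weighted interaction network
#'
#' Planted modules are fully connected with high-confidence edges;
#' background edges connect uniformly random gene pairs. Duplicate
#' undirected edges are merged (maximum confidence wins).
#'
#' @param universe Character vector of genes.
#' @param modules Named list of gene sets to fully connect (subsets of the
#'   universe).
#' @param n_background Number of background edges.
#' @param module_conf Confidence of module edges (default 0.9).
#' @param conf_range Background confidences drawn uniformly in this range.
#' @param seed Integer seed.
#' @return Edge-list data frame (`a`, `b`, `confidence`).
#' @export
generate_interaction_network <- function(universe, modules = list(),
                                         n_background = 500,
                                         module_conf = 0.9,
                                         conf_range = c(0.15, 0.95),
                                         seed = 1L) {
  for (m in names(modules)) {
    if (!all(modules[[m]] %in% universe))
      stopf("module gene outside universe in '%s'", m)
  }
  edges <- list()
  for (m in modules) {
    if (length(m) >= 2) {
      pr <- t(combn(m, 2))
      edges[[length(edges) + 1]] <- data.frame(
        a = pr[, 1], b = pr[, 2], confidence = module_conf)
    }
  }
  N <- length(universe)
  edges[[length(edges) + 1]] <- with_seed(seed, {
    id <- sample(N * (N - 1) / 2, min(n_background, N * (N - 1) / 2)) - 1
    pa <- floor((2 * N - 1 - sqrt((2 * N - 1)^2 - 8 * id)) / 2)
    pb <- id - pa * N + pa * (pa + 1) / 2 + pa + 1
    data.frame(a = universe[pa + 1], b = universe[pb + 1],
               confidence = runif(length(id), conf_range[1], conf_range[2]))
  })
  .canonical_edges(do.call(rbind, edges))
}
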