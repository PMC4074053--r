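# GO-guided view of the feature tree: leaves are populated with the GO
# cellular-component annotations of their hit genes, and a term shared by
# connected leaves rises to the highest node through which all of its
# occurrences are connected. A fixed list of generic terms is forced to
# the root.

#' Default generic cellular-component terms forced to the tree root
#' @return Character vector.
#' @export
generic_go_terms <- function() {
  c("cytoplasm", "nucleus", "membrane", "intracellular",
    "extracellular region", "plasma membrane")
}

#' Build an annotation map from a gene-to-term table
#'
#' @param tab Data frame with columns `gene` and `term` (one row per
#'   annotation), e.g. from [read_annotations()].
#' @return Object of class `annotation_map`: list with `gene2term` and
#'   `term2gene` (named lists of character vectors, mutually consistent).
#' @export
annotation_map <- function(tab) {
  stopifnot(all(c("gene", "term") %in% colnames(tab)))
  tab <- unique(tab[, c("gene", "term")])
  structure(list(gene2term = split(tab$term, tab$gene),
                 term2gene = split(tab$gene, tab$term)),
            class = "annotation_map")
}

#' Populate tree leaves with the GO terms of their hit genes
#'
#' A term is present at a feature leaf if at least one hit gene for that
#' feature carries the term (set semantics). Unannotated genes contribute
#' nothing; their count is reported as an attribute.
#'
#' @param hits A `hit_matrix` from [call_hits()].
#' @param ann An [annotation_map()].
#' @return Named list leaf (feature) -> character vector of terms, with
#'   attribute `n_unannotated`.
#' @export
annotate_leaves <- function(hits, ann) {
  stopifnot(inherits(ann, "annotation_map"))
  m <- unclass(hits)
  genes <- rownames(m)
  unann <- sum(!(genes[rowSums(m) > 0] %in% names(ann$gene2term)))
  out <- lapply(colnames(m), function(f) {
    g <- genes[m[, f]]
    sort(unique(unlist(ann$gene2term[intersect(g, names(ann$gene2term))],
                       use.names = FALSE)))
  })
  names(out) <- colnames(m)
  attr(out, "n_unannotated") <- unann
  out
}

#' Pull shared annotations up the rooted tree
#'
#' Each term is placed at its home node(s): the highest node(s) whose
#' entire subtree carries the term, i.e. a term occurring at all leaves of
#' one clade rises to that clade's root (lowest-common-ancestor
#' semantics), a term at a single leaf stays there, and occurrences in
#' unconnected clades keep separate homes. Generic terms are forced to the
#' root regardless of occurrence.
#'
#' @param tree A rooted `phylo` or a `feature_tree` (its rooted tree is
#'   used).
#' @param leaf_terms Named list leaf -> terms from [annotate_leaves()].
#' @param generic_terms Terms forced to the root (default
#'   [generic_go_terms()]).
#' @return Data frame with columns `term`, `node` (tip label or internal
#'   node label), `n_leaves` (leaves covered by that home).
#' @export
pull_up <- function(tree, leaf_terms, generic_terms = generic_go_terms()) {
  phy <- if (inherits(tree, "feature_tree")) tree$tree else tree
  ntip <- length(phy$tip.label)
  nn <- ntip + phy$Nnode
  if (is.null(phy$node.label))
    phy$node.label <- paste0("node", seq_len(phy$Nnode))
  node_id <- c(phy$tip.label, phy$node.label)
  terms <- sort(unique(unlist(leaf_terms, use.names = FALSE)))
  po <- ape::reorder.phylo(phy, "postorder")$edge
  kids <- split(po[, 2], po[, 1])
  n_desc <- c(rep(1L, ntip), rep(0L, nn - ntip))
  out <- list()
  for (t in terms) {
    present <- phy$tip.label %in%
      phy$tip.label[vapply(leaf_terms[phy$tip.label], function(x) t %in% x,
                           logical(1))]
    if (t %in% generic_terms) {
      out[[length(out) + 1]] <- data.frame(term = t,
                                           node = node_id[ntip + 1L],
                                           n_leaves = sum(present))
      next
    }
    # full[v]: every leaf under v carries t
    full <- c(present, rep(NA, nn - ntip))
    cover <- c(as.integer(present), rep(0L, nn - ntip))
    for (i in seq_len(nrow(po))) {
      p <- po[i, 1]; c <- po[i, 2]
      full[p] <- if (is.na(full[p])) full[c] else full[p] & full[c]
      cover[p] <- cover[p] + cover[c]
    }
    # homes: full nodes whose parent is not full (root counts if full)
    parent <- rep(NA_integer_, nn)
    parent[po[, 2]] <- po[, 1]
    pfull <- full[ifelse(is.na(parent), 1L, parent)]
    homes <- which(full & (is.na(parent) | !pfull))
    if (length(homes))
      out[[length(out) + 1]] <- data.frame(
        term = t, node = node_id[homes],
        n_leaves = vapply(homes, function(v) {
          if (v <= ntip) 1L else .subtree_size(v, kids)
        }, integer(1)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

.subtree_size <- function(v, kids) {
  k <- kids[[as.character(v)]]
  if (is.null(k)) return(1L)
  sum(vapply(k, .subtree_size, integer(1), kids = kids))
}

#' Term enrichment of a node's gene set
#'
#' Upper-tail hypergeometric enrichment of every annotated term within one
#' node's gene set, BH-corrected across terms. Thin wrapper over
#' [hypergeom_test()].
#'
#' @param node_genes Character vector of the node's genes.
#' @param ann An [annotation_map()].
#' @param universe Character vector, the population gene set.
#' @param correction Multiple-testing method (see [correct_pvalues()]).
#' @return Data frame: `term`, `observed`, `annotated`, `p`, `p_adj`,
#'   sorted by `p`.
#' @export
node_term_enrichment <- function(node_genes, ann, universe,
                                 correction = "BH") {
  if (!length(node_genes))
    return(data.frame(term = character(), observed = integer(),
                      annotated = integer(), p = numeric(),
                      p_adj = numeric()))
  res <- lapply(names(ann$term2gene), function(t) {
    tg <- intersect(ann$term2gene[[t]], universe)
    data.frame(term = t,
               observed = length(intersect(node_genes, tg)),
               annotated = length(tg),
               p = hypergeom_test(node_genes, tg, universe))
  })
  res <- do.call(rbind, res)
  res$p_adj <- correct_pvalues(res$p, method = correction)
  res[order(res$p), ]
}
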