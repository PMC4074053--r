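# Independent brute-force oracles. These deliberately share no code with
# the package implementations they check.

# two-sample KS: evaluate both ECDFs at every pooled point
ks_brute <- function(a, b) {
  pool <- sort(unique(c(a, b)))
  max(abs(vapply(pool, function(v) mean(a <= v) - mean(b <= v), numeric(1))))
}

# minimum event counts of binary characters on a tree, by exhaustive
# enumeration of internal-node labelings. Unrooted convention (default):
# one extra origin event when no node can be in state 0. Rooted
# convention (`rooted = TRUE`): one extra origin gain when the root node
# itself is in state 1.
parsimony_brute <- function(tree, X, rooted = FALSE) {
  ntip <- length(tree$tip.label)
  X <- X[tree$tip.label, , drop = FALSE]
  m <- tree$Nnode
  E <- tree$edge
  total <- 0
  for (k in seq_len(ncol(X))) {
    best <- Inf
    for (code in 0:(2^m - 1)) {
      internal <- as.integer(intToBits(code))[seq_len(m)]
      s <- c(X[, k], internal)
      changes <- sum(s[E[, 1]] != s[E[, 2]])
      origin <- if (rooted) unname(s[ntip + 1]) else as.integer(all(s == 1))
      cost <- unname(changes + origin)
      if (cost < best) best <- cost
    }
    total <- total + best
  }
  total
}

# P(X >= k) for the hypergeometric by enumeration of all study draws
hyper_brute <- function(universe, annotated, n_study, k) {
  draws <- combn(universe, n_study)
  mean(apply(draws, 2, function(d) sum(d %in% annotated) >= k))
}

# P(X >= k) for the binomial by enumeration of all 2^n outcomes
binom_brute <- function(k, n, p = 0.5) {
  if (p != 0.5) stop("oracle assumes fair trials")
  outcomes <- expand.grid(rep(list(0:1), n))
  mean(rowSums(outcomes) >= k)
}

# all unrooted topologies on 5 or fewer taxa, as ape trees
all_topologies <- function(taxa) {
  stopifnot(length(taxa) <= 6)
  phangorn::allTrees(length(taxa), rooted = FALSE, tip.label = taxa)
}

# small nested-hierarchy effect design shared by recovery tests
nested_design <- function(genes_per_set = 10, size = 4) {
  feats <- feature_catalog()
  grp <- split(feats, rep(1:6, c(5, 5, 5, 4, 4, 4)))
  sets <- c(stats::setNames(grp, paste0("G", 1:6)),
            list(M1 = c(grp[[1]], grp[[2]]),
                 M2 = c(grp[[3]], grp[[4]]),
                 M3 = c(grp[[5]], grp[[6]]),
                 T1 = unlist(grp[1:4], use.names = FALSE)))
  list(sets = sets,
       effects = nested_effect_table(sets, genes_per_set = genes_per_set,
                                     size = size))
}

# leaf sets under every internal node of an (unrooted) phylo
node_leaf_sets <- function(tree) {
  ntip <- length(tree$tip.label)
  po <- ape::reorder.phylo(tree, "postorder")$edge
  desc <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) desc[[i]] <- tree$tip.label[i]
  for (i in seq_len(nrow(po)))
    desc[[po[i, 1]]] <- c(desc[[po[i, 1]]], desc[[po[i, 2]]])
  lapply((ntip + 1):(ntip + tree$Nnode),
         function(v) sort(unlist(desc[[v]])))
}

# does the consensus contain the unrooted split set|complement, and with
# what support
split_support <- function(consensus, support, set, all_taxa) {
  s <- sort(set)
  comp <- sort(setdiff(all_taxa, s))
  ns <- node_leaf_sets(consensus)
  hit <- which(vapply(ns, function(x) identical(x, s) || identical(x, comp),
                      logical(1)))
  if (!length(hit)) return(NA_real_)
  max(support[hit])
}
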