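# Maximum-parsimony organization of the measured features.
#
# The 27 features play the role of "species" and the binary hit profiles of
# the genes are the "characters": a gene's feature vector is one column of
# the character matrix. The best tree explains all observed profiles with
# the fewest gene gain/loss events. Character fit uses Fitch/Hartigan
# small parsimony (unordered binary states, unit cost, polytomies allowed)
# under a gain-rooting convention: every character is absent at the origin,
# so a character present in all taxa still costs one (root) gain.

#' Build the character matrix from feature vectors, dropping trivial ones
#'
#' Characters (genes) hitting fewer than two features are phylogenetically
#' uninformative; they are removed from the matrix and recorded separately
#' (they attach to their single leaf at reporting time).
#'
#' @param fv Feature-vector data frame from [binarize()], or a logical/0-1
#'   matrix with genes in rows and features in columns.
#' @return Object of class `character_matrix`: 0/1 integer matrix with
#'   features (taxa) in rows and genes (characters) in columns; attribute
#'   `singletons` holds a data frame (gene, feature) of the popcount-1
#'   characters.
#' @export
filter_nontrivial <- function(fv) {
  if (is.data.frame(fv)) {
    feats <- intersect(colnames(fv), feature_catalog())
    m <- as.matrix(fv[, feats, drop = FALSE]) * 1L
    rownames(m) <- fv$gene
  } else {
    m <- fv * 1L
  }
  pc <- rowSums(m)
  single <- which(pc == 1)
  singletons <- if (length(single)) {
    data.frame(gene = rownames(m)[single],
               feature = colnames(m)[max.col(m[single, , drop = FALSE])])
  } else {
    data.frame(gene = character(), feature = character())
  }
  keep <- m[pc >= 2, , drop = FALSE]
  if (!nrow(keep)) stopf("no informative characters")
  structure(t(keep), class = "character_matrix", singletons = singletons)
}

# collapse duplicate character patterns into weighted unique columns
.collapse_patterns <- function(X) {
  key <- apply(X, 2, paste0, collapse = "")
  u <- !duplicated(key)
  list(X = X[, u, drop = FALSE],
       w = as.numeric(table(key)[key[u]]))
}

.check_taxa <- function(tree, X) {
  if (!setequal(tree$tip.label, rownames(X)))
    stopf("tree leaves and matrix taxa differ")
  X[tree$tip.label, , drop = FALSE]
}

#' Parsimony score of a topology
#'
#' Minimum total number of character state changes (gains + losses) over
#' all characters, by the Fitch/Hartigan algorithm; a character present in
#' every taxon contributes one (root gain) event.
#'
#' @param tree An `ape::phylo` tree whose tips are the matrix taxa
#'   (polytomies allowed).
#' @param X Character matrix (taxa x characters 0/1), e.g. a
#'   [filter_nontrivial()] result.
#' @return Integer score.
#' @export
parsimony_score <- function(tree, X) {
  X <- .check_taxa(tree, X)
  storage.mode(X) <- "integer"
  cpp_fitch_score(tree$edge, length(tree$tip.label), X, rep(1, ncol(X)))
}

#' Heuristic maximum-parsimony tree search
#'
#' Random-order stepwise addition followed by nearest-neighbour-interchange
#' hill-climbing until no improvement, repeated from `n_restarts` shuffled
#' taxon orders; the minimum-score topology found is returned (ties keep
#' the first). Deterministic for a fixed seed.
#'
#' @param X Character matrix (taxa x characters).
#' @param n_restarts Number of shuffled-order restarts (default 25).
#' @param seed Integer seed.
#' @return List with `tree` (unrooted `phylo`) and `score`.
#' @export
search_tree <- function(X, n_restarts = 25, seed = 1L) {
  ntaxa <- nrow(X)
  if (ntaxa < 4) stopf("need >= 4 taxa")
  cp <- .collapse_patterns(X)
  Xi <- cp$X; storage.mode(Xi) <- "integer"
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      ord <- sample.int(ntaxa)
      res <- cpp_search(Xi, cp$w, ord)
      if (is.null(best) || res$score < best$score) best <- res
    }
  })
  tree <- .edges_to_phylo(best$edge, ntaxa, rownames(X))
  list(tree = tree, score = best$score)
}

# convert an undirected edge matrix (tips 1..ntip) into an ape phylo via a
# Newick string rooted at the first internal node
.edges_to_phylo <- function(edge, ntip, tip_labels) {
  nn <- max(edge)
  adj <- vector("list", nn)
  for (i in seq_len(nrow(edge))) {
    a <- edge[i, 1]; b <- edge[i, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  build <- function(v, parent) {
    if (v <= ntip) return(tip_labels[v])
    kids <- setdiff(adj[[v]], parent)
    paste0("(", paste(vapply(kids, build, "", parent = v), collapse = ","), ")")
  }
  ape::read.tree(text = paste0(build(ntip + 1L, 0L), ";"))
}

#' Jackknife majority-rule consensus tree
#'
#' Each replicate retains a random half of the characters (drawn without
#' replacement), a parsimony search is run on the reduced matrix, and the
#' majority-rule consensus of the replicate trees is returned with
#' per-branch support (the percentage of replicates containing each
#' bipartition). The consensus may contain polytomies.
#'
#' @param X Character matrix (taxa x characters).
#' @param n_reps Number of jackknife replicates (default 100).
#' @param drop_fraction Fraction of characters dropped per replicate
#'   (default 0.5; exactly `ceiling(G/2)` characters are retained).
#' @param majority Bipartition frequency required for inclusion (strictly
#'   greater than; default 0.5).
#' @param n_restarts Search restarts per replicate (default 25).
#' @param seed Integer seed.
#' @return List of class `jackknife_consensus`: `tree` (unrooted consensus
#'   `phylo` with node labels `"<support>"`), `support` (numeric, percent,
#'   per internal node), `replicate_scores`.
#' @export
jackknife_consensus <- function(X, n_reps = 100, drop_fraction = 0.5,
                                majority = 0.5, n_restarts = 25, seed = 1L) {
  if (n_reps < 2) stopf("n_reps must be >= 2")
  G <- ncol(X)
  n_keep <- ceiling(G * (1 - drop_fraction))
  trees <- vector("list", n_reps)
  scores <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    cols <- with_seed(child_seed(seed, 300L + r), sample.int(G, n_keep))
    res <- search_tree(X[, cols, drop = FALSE], n_restarts = n_restarts,
                       seed = child_seed(seed, 600L + r))
    trees[[r]] <- res$tree
    scores[r] <- res$score
  }
  class(trees) <- "multiPhylo"
  cons <- ape::consensus(trees, p = majority, rooted = FALSE)
  counts <- ape::prop.clades(cons, trees, rooted = FALSE)
  counts[is.na(counts)] <- n_reps
  support <- round(100 * counts / n_reps)
  cons$node.label <- as.character(support)
  structure(list(tree = cons, support = support,
                 replicate_scores = scores, n_reps = n_reps),
            class = "jackknife_consensus")
}

# ---- minimum-change ancestral assignment ---------------------------------

# Vectorized Sankoff DP over binary characters on a rooted (multifurcating)
# phylo. Among minimum-change labelings, losses (1->0 transitions) are
# minimized, i.e. gains are preferred; remaining ties keep the parent
# state, then state 0. Returns per-node states and per-root-choice costs.
.assign_states <- function(phy, X) {
  ntip <- length(phy$tip.label)
  nn <- ntip + phy$Nnode
  nchar <- ncol(X)
  INF <- 1e9
  C0 <- C1 <- L0 <- L1 <- matrix(0, nn, nchar)
  C0[seq_len(ntip), ] <- ifelse(X == 0, 0, INF)
  C1[seq_len(ntip), ] <- ifelse(X == 1, 0, INF)
  po <- ape::reorder.phylo(phy, "postorder")
  E <- po$edge
  # child contribution given parent state, with lexicographic
  # (cost, losses, keep-parent-state) tie-breaking
  pick_child <- function(p_state, c) {
    if (p_state == 0) {
      t0 <- C0[c, ]; t1 <- C1[c, ] + 1
      l0 <- L0[c, ]; l1 <- L1[c, ]
    } else {
      t1 <- C1[c, ]; t0 <- C0[c, ] + 1
      l1 <- L1[c, ]; l0 <- L0[c, ] + 1
    }
    if (p_state == 0) {
      take0 <- (t0 < t1) | (t0 == t1 & l0 <= l1)
    } else {
      take1 <- (t1 < t0) | (t1 == t0 & l1 <= l0)
      take0 <- !take1
    }
    list(cost = ifelse(take0, t0, t1), loss = ifelse(take0, l0, l1),
         state = ifelse(take0, 0L, 1L))
  }
  for (i in seq_len(nrow(E))) {
    p <- E[i, 1]; c <- E[i, 2]
    k0 <- pick_child(0, c); k1 <- pick_child(1, c)
    C0[p, ] <- C0[p, ] + k0$cost; L0[p, ] <- L0[p, ] + k0$loss
    C1[p, ] <- C1[p, ] + k1$cost; L1[p, ] <- L1[p, ] + k1$loss
  }
  root <- ntip + 1L
  # virtual origin edge: state 1 at the root is itself a gain
  r0 <- C0[root, ]; r1 <- C1[root, ] + 1
  root_state <- ifelse(r0 < r1, 0L,
                ifelse(r1 < r0, 1L,
                ifelse(L0[root, ] <= L1[root, ], 0L, 1L)))
  states <- matrix(NA_integer_, nn, nchar)
  states[root, ] <- root_state
  for (i in rev(seq_len(nrow(E)))) {
    p <- E[i, 1]; c <- E[i, 2]
    k0 <- pick_child(0, c); k1 <- pick_child(1, c)
    states[c, ] <- ifelse(states[p, ] == 0L, k0$state, k1$state)
  }
  list(states = states, ntip = ntip, edge = phy$edge)
}

#' Root a consensus tree and assign per-node gene gains and losses
#'
#' Reproduces the rooted event layer of the feature tree: a minimum-change
#' assignment of each character (gene) to the internal nodes is computed,
#' the internal node carrying the fewest characters in state 1 is taken as
#' the root, the tree is re-rooted there, and every character's state
#' transitions along the rooted edges are labeled gains (0 to 1) or losses
#' (1 to 0). Ambiguous minimum-change reconstructions are resolved
#' preferring gains (losses are interpreted as assay false negatives).
#'
#' @param tree Unrooted consensus `phylo` (e.g.
#'   `jackknife_consensus(...)$tree`) covering all feature leaves;
#'   polytomies allowed.
#' @param X Character matrix (taxa x characters 0/1). Columns with a single
#'   1 are allowed here and attach at their leaf.
#' @return Object of class `feature_tree`: list with `tree` (rooted
#'   `phylo`, node labels `node1..nodeN`), `support` (from the input node
#'   labels, if any), `events` (data frame: gene, node, event in
#'   gain/loss), `genes_added` (named list node -> genes gained),
#'   `node_states` (node x gene 0/1 matrix), and `summary` (list:
#'   total_events, gains, losses, multi_gain_characters).
#' @export
assign_characters <- function(tree, X) {
  X <- .check_taxa(tree, X)
  storage.mode(X) <- "integer"
  ntip <- length(tree$tip.label)
  # pass 1: arbitrary root, count state-1 characters per internal node
  a1 <- .assign_states(tree, X)
  pop <- rowSums(a1$states[(ntip + 1):nrow(a1$states), , drop = FALSE])
  ties <- which(pop == min(pop))
  if (length(ties) > 1)
    warnf("tie for least-populated internal node; using lowest node id")
  root_node <- ntip + ties[1]
  rooted <- if (root_node == ntip + 1L) tree else
    ape::root(tree, node = root_node, resolve.root = FALSE)
  # pass 2: final gain-biased assignment on the rooted tree
  a2 <- .assign_states(rooted, X[rooted$tip.label, , drop = FALSE])
  states <- a2$states
  nn <- nrow(states)
  node_id <- character(nn)
  node_id[seq_len(ntip)] <- rooted$tip.label
  node_id[(ntip + 1):nn] <- paste0("node", seq_len(nn - ntip))
  ev <- list()
  E <- rooted$edge
  genes <- colnames(X) %||% paste0("char", seq_len(ncol(X)))
  for (i in seq_len(nrow(E))) {
    p <- E[i, 1]; c <- E[i, 2]
    gain <- which(states[p, ] == 0L & states[c, ] == 1L)
    loss <- which(states[p, ] == 1L & states[c, ] == 0L)
    if (length(gain))
      ev[[length(ev) + 1]] <- data.frame(gene = genes[gain],
                                         node = node_id[c], event = "gain")
    if (length(loss))
      ev[[length(ev) + 1]] <- data.frame(gene = genes[loss],
                                         node = node_id[c], event = "loss")
  }
  root_gain <- which(states[ntip + 1L, ] == 1L)
  if (length(root_gain))
    ev[[length(ev) + 1]] <- data.frame(gene = genes[root_gain],
                                       node = node_id[ntip + 1L],
                                       event = "gain")
  events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(gene = character(), node = character(), event = character())
  gains <- events[events$event == "gain", , drop = FALSE]
  gain_counts <- table(gains$gene)
  summ <- list(total_events = nrow(events), gains = nrow(gains),
               losses = sum(events$event == "loss"),
               multi_gain_characters = sum(gain_counts >= 2))
  support <- suppressWarnings(as.numeric(tree$node.label))
  rooted$node.label <- node_id[(ntip + 1):nn]
  rownames(states) <- node_id
  colnames(states) <- genes
  structure(list(tree = rooted, support = support, events = events,
                 genes_added = split(gains$gene, gains$node),
                 node_states = states, summary = summ),
            class = "feature_tree")
}

#' @export
print.feature_tree <- function(x, ...) {
  cat(sprintf(
    "feature_tree: %d leaves, %d internal nodes; %d events (%d gains, %d losses)\n",
    length(x$tree$tip.label), x$tree$Nnode, x$summary$total_events,
    x$summary$gains, x$summary$losses))
  invisible(x)
}

#' Overlap between two node gene sets against a random-draw null
#'
#' Tests whether the genes gained at two nodes overlap more (or less) than
#' expected if both sets were drawn at random from the background of all
#' hit genes. Empirical p-values use `n_perm` same-size random draws with a
#' +1 pseudo-count; the exact hypergeometric tail probabilities are
#' reported alongside.
#'
#' @param set_a,set_b Character vectors of genes.
#' @param background Character vector, the background hit set.
#' @param n_perm Number of null draws.
#' @param seed Integer seed.
#' @return List: `observed` overlap, `expected`, `p_enrich`, `p_deplete`,
#'   `p_two_sided` (empirical), `p_enrich_hyper`, `p_deplete_hyper`.
#' @export
leaf_overlap_test <- function(set_a, set_b, background, n_perm = 1000,
                              seed = 1L) {
  set_a <- intersect(unique(set_a), background)
  set_b <- intersect(unique(set_b), background)
  obs <- length(intersect(set_a, set_b))
  N <- length(background); ka <- length(set_a); kb <- length(set_b)
  if (ka == 0 || kb == 0) {
    return(list(observed = obs, expected = 0, p_enrich = 1, p_deplete = 1,
                p_two_sided = 1, p_enrich_hyper = 1, p_deplete_hyper = 1))
  }
  null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      length(intersect(sample(background, ka), sample(background, kb)))
    }, numeric(1))
  })
  p_en <- (1 + sum(null >= obs)) / (n_perm + 1)
  p_de <- (1 + sum(null <= obs)) / (n_perm + 1)
  list(observed = obs, expected = ka * kb / N,
       p_enrich = p_en, p_deplete = p_de,
       p_two_sided = min(1, 2 * min(p_en, p_de)),
       p_enrich_hyper = phyper(obs - 1, ka, N - ka, kb, lower.tail = FALSE),
       p_deplete_hyper = phyper(obs, ka, N - ka, kb))
}
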