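# Shared fixtures and independent oracles.

# Random rooted binary tree with uniform branch lengths (not ultrametric).
random_tree <- function(n_tips) {
  tr <- ape::rtree(n_tips)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 1.5)
  tr
}

random_rates <- function(model) {
  stats::setNames(stats::runif(length(model$params), 0.05, 1.2), model$params)
}

# Exhaustive-enumeration log-likelihood: sums the joint probability over all
# k^Nnode internal-state assignments. Independent of the pruning code path
# (uses only transition_probabilities).
enum_loglik <- function(tree, states, Q, pi) {
  k <- nrow(Q)
  n_tip <- ape::Ntip(tree)
  P <- lapply(tree$edge.length, function(t) transition_probabilities(Q, t))
  combos <- as.matrix(expand.grid(rep(list(0:(k - 1)), tree$Nnode)))
  tot <- 0
  for (row in seq_len(nrow(combos))) {
    full <- c(states[tree$tip.label], combos[row, ])
    pr <- pi[full[n_tip + 1] + 1]
    for (e in seq_len(nrow(tree$edge)))
      pr <- pr * P[[e]][full[tree$edge[e, 1]] + 1, full[tree$edge[e, 2]] + 1]
    tot <- tot + pr
  }
  log(tot)
}

# Brute-force marginal posterior of one internal node: renormalized joint
# probabilities with that node clamped to each state in turn.
enum_node_posterior <- function(tree, states, Q, pi, node) {
  k <- nrow(Q)
  n_tip <- ape::Ntip(tree)
  P <- lapply(tree$edge.length, function(t) transition_probabilities(Q, t))
  combos <- as.matrix(expand.grid(rep(list(0:(k - 1)), tree$Nnode)))
  mass <- numeric(k)
  for (row in seq_len(nrow(combos))) {
    full <- c(states[tree$tip.label], combos[row, ])
    pr <- pi[full[n_tip + 1] + 1]
    for (e in seq_len(nrow(tree$edge)))
      pr <- pr * P[[e]][full[tree$edge[e, 1]] + 1, full[tree$edge[e, 2]] + 1]
    mass[full[node] + 1] <- mass[full[node] + 1] + pr
  }
  mass / sum(mass)
}

# Patristic distance matrix among tips, by tip label.
patristic <- function(tree) {
  d <- ape::cophenetic.phylo(tree)
  d[order(rownames(d)), order(colnames(d))]
}

# Newick strings for a 10-tree, 4-taxon posterior-style sample: 6 trees with
# the {A,B} clade, 4 with {A,C}.
mixed_sample <- function() {
  maj <- "((A:1,B:1):1,(C:1,D:1):1);"
  min <- "((A:1,C:1):1,(B:1,D:1):1);"
  ape::read.tree(text = c(rep(maj, 6), rep(min, 4)))
}

# canonical clade keys of a tree's internal nodes
internal_keys_of <- function(tree) {
  sub <- ape::subtrees(tree)
  vapply(sub, function(s) paste(sort(s$tip.label), collapse = "|"), "")
}

# topology equality for rooted trees, label-aware, edge lengths ignored
same_topology <- function(a, b) {
  isTRUE(ape::all.equal.phylo(a, b, use.edge.length = FALSE))
}

dep_rates <- function(...) {
  r <- stats::setNames(rep(0.15, 8), dependent_model()$params)
  dots <- c(...)
  r[names(dots)] <- dots
  r
}
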