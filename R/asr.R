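#' Marginal maximum-likelihood ancestral-state reconstruction
#'
#' Computes, for every node, the marginal posterior probability of each state
#' given all tip data under the supplied rate matrix (the "proportional
#' likelihoods"), by the standard inside-outside (down-pass / up-pass)
#' recursion with per-node rescaling. Tips with observed states get all mass
#' on the observed state; missing tips are reconstructed like internal
#' nodes.
#'
#' @inheritParams pruning_loglik
#' @return An `asr` object; its `$nodes` tibble has one row per node (ape
#'   node ids: tips `1..n`, root `n+1`) with columns `node`, `type`, `label`,
#'   one proportional-likelihood column `p_<state>` per state, and `ml_state`
#'   (0-based argmax).
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
#' Q <- build_q(mk2_model(), c(0.3, 0.3))
#' marginal_asr(tr, c(A = 0, B = 0, C = 1), Q)$nodes
#' @export
marginal_asr <- function(tree, states, Q, root = root_treatment("uniform")) {
  check_q(Q)
  root <- as_root_treatment(root)
  tree <- prepare_tree(tree)
  k <- nrow(Q)
  n_tip <- ape::Ntip(tree)
  n_node <- n_tip + tree$Nnode
  L <- tip_likelihoods(tree, states, k)

  po <- ape::reorder.phylo(tree, "postorder")
  Pm <- edge_pmat_list(Q, po$edge.length)

  # down pass: D[v, ] = P(tip data below v | state of v), rescaled per node
  D <- matrix(1, n_node, k)
  D[seq_len(n_tip), ] <- L
  for (e in seq_len(nrow(po$edge))) {
    par <- po$edge[e, 1]; chi <- po$edge[e, 2]
    d <- D[chi, ]
    m <- max(d)
    if (m <= 0) abort("tip data impossible under this model (zero likelihood)")
    D[par, ] <- D[par, ] * as.numeric(Pm[[e]] %*% (d / m))
  }
  root_id <- n_tip + 1L
  w <- root_weights(root, Q, D[root_id, ])

  # up pass: O[v, ] = P(data outside v's subtree, root weighting | state of v)
  O <- matrix(0, n_node, k)
  O[root_id, ] <- w
  pre <- rev(seq_len(nrow(po$edge)))  # parents before children
  children <- split(seq_len(nrow(po$edge)), po$edge[, 1])
  for (e in pre) {
    par <- po$edge[e, 1]; chi <- po$edge[e, 2]
    sibs <- setdiff(children[[as.character(par)]], e)
    contrib <- O[par, ]
    for (s in sibs) {
      ds <- D[po$edge[s, 2], ]
      contrib <- contrib * as.numeric(Pm[[s]] %*% (ds / max(ds)))
    }
    o <- as.numeric(crossprod(Pm[[e]], contrib))
    m <- max(o)
    O[chi, ] <- if (m > 0) o / m else o
  }

  marg <- O * D
  marg <- marg / rowSums(marg)
  colnames(marg) <- state_labels(k)
  nodes <- tibble::tibble(
    node = seq_len(n_node),
    type = rep(c("tip", "internal"), c(n_tip, tree$Nnode)),
    label = c(tree$tip.label, rep(NA_character_, tree$Nnode)))
  for (j in seq_len(k)) nodes[[paste0("p_", colnames(marg)[j])]] <- marg[, j]
  nodes$ml_state <- max.col(marg, ties.method = "first") - 1L
  structure(list(nodes = nodes, prob = marg, tree = tree, Q = Q, root = root,
                 k = k),
            class = "asr")
}

edge_pmat_list <- function(Q, lens) {
  u <- unique(lens)
  cache <- lapply(u, function(t) .pmat_cpp(unname(Q), t))
  cache[match(lens, u)]
}

#' @export
print.asr <- function(x, ...) {
  cat("Marginal ancestral-state reconstruction:", x$k, "states,",
      nrow(x$nodes), "nodes (root:", x$root$mode, "weights)\n")
  root_id <- ape::Ntip(x$tree) + 1L
  cat(" root proportional likelihoods:",
      paste(sprintf("%s=%.3f", colnames(x$prob), x$prob[root_id, ]),
            collapse = ", "), "\n")
  invisible(x)
}

#' Collapse a 4-state pair reconstruction to one trait
#'
#' Sums proportional likelihoods over the other trait's states, giving the
#' per-node marginal for a single trait from a joint reconstruction.
#'
#' @param recon An `asr` on the 4-state pair space.
#' @param trait 1 or 2.
#' @return A tibble with `node`, `type`, `label`, `p_0`, `p_1`, `ml_state`.
#' @export
collapse_trait <- function(recon, trait = 1) {
  stopifnot(inherits(recon, "asr"))
  if (recon$k != 4L) abort("`recon` must be a 4-state pair reconstruction")
  if (!trait %in% 1:2) abort("`trait` must be 1 or 2")
  p1 <- if (trait == 1) recon$prob[, "10"] + recon$prob[, "11"]
        else recon$prob[, "01"] + recon$prob[, "11"]
  out <- recon$nodes[c("node", "type", "label")]
  out$p_0 <- 1 - p1
  out$p_1 <- p1
  out$ml_state <- as.integer(p1 > 0.5)
  out
}

#' Count state transitions implied by a reconstruction
#'
#' Assigns each node a state and counts, per ordered state pair, the edges
#' whose endpoint assignments differ. Under the default `"argmax"` rule every
#' node takes its most probable state. Under the `"threshold"` rule an edge
#' is counted only when both endpoint assignments have proportional
#' likelihood at least `p` (with `p` in (0.5, 1]), a conservative "at least
#' this many transitions" reading.
#'
#' @param recon An `asr` object.
#' @param rule `"argmax"` or `"threshold"`.
#' @param p Confidence threshold for the threshold rule.
#' @return A tibble `from`, `to` (state labels), `count`, with the rule
#'   recorded in attribute `"rule"`.
#' @export
count_transitions <- function(recon, rule = c("argmax", "threshold"), p = NULL) {
  stopifnot(inherits(recon, "asr"))
  rule <- match.arg(rule)
  if (rule == "threshold") {
    if (is.null(p) || length(p) != 1L || p <= 0.5 || p > 1)
      abort("threshold rule requires `p` in (0.5, 1]")
  }
  assign <- recon$nodes$ml_state
  conf <- recon$prob[cbind(seq_len(nrow(recon$prob)), assign + 1L)]
  lab <- colnames(recon$prob)
  edge <- recon$tree$edge
  from <- assign[edge[, 1]]; to <- assign[edge[, 2]]
  use <- from != to
  if (rule == "threshold")
    use <- use & conf[edge[, 1]] >= p & conf[edge[, 2]] >= p
  grid <- expand.grid(from = seq_len(recon$k) - 1L, to = seq_len(recon$k) - 1L)
  grid <- grid[grid$from != grid$to, ]
  counts <- mapply(function(f, t) sum(use & from == f & to == t),
                   grid$from, grid$to)
  out <- tibble::tibble(from = lab[grid$from + 1L], to = lab[grid$to + 1L],
                        count = as.integer(counts))
  out <- dplyr::arrange(out, .data$from, .data$to)
  attr(out, "rule") <- if (rule == "argmax") "argmax" else paste0("threshold(", p, ")")
  out
}

#' Collapse pair-state transition counts to a single trait
#'
#' Aggregates a 4-state transition-count table to the 0->1 and 1->0 counts of
#' one trait (edges on which that trait's assigned state changed, regardless
#' of the other trait).
#'
#' @param counts A transition-count tibble from [count_transitions()] on a
#'   4-state reconstruction.
#' @param trait 1 or 2.
#' @return A tibble `from`, `to`, `count` over states 0/1.
#' @export
collapse_transition_counts <- function(counts, trait = 1) {
  if (!trait %in% 1:2) abort("`trait` must be 1 or 2")
  pos <- trait  # character position in the "xy" pair label
  f <- substr(counts$from, pos, pos)
  t <- substr(counts$to, pos, pos)
  keep <- f != t
  dplyr::summarise(
    dplyr::group_by(tibble::tibble(from = f[keep], to = t[keep],
                                   count = counts$count[keep]),
                    .data$from, .data$to),
    count = sum(.data$count), .groups = "drop")
}

#' Write a reconstruction's node table to TSV
#'
#' @param recon An `asr` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_asr_table <- function(recon, path) {
  utils::write.table(recon$nodes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
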