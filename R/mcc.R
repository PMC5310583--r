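#' Clade posterior frequencies in a tree sample
#'
#' Tabulates, over the post-burn-in trees, the relative frequency of every
#' clade (keyed by its canonical sorted tip-label set, so label order and
#' tree rotation are irrelevant). Tip singletons and the root clade are
#' included, with frequency 1 by construction.
#'
#' @param sample A `multiPhylo` (or list of `phylo`) over one taxon set.
#' @param burnin Number of leading trees to discard (default 0).
#' @return A tibble: `clade` (pipe-joined sorted tip labels), `size`,
#'   `frequency`.
#' @export
clade_frequencies <- function(sample, burnin = 0) {
  sample <- as_tree_sample(sample)
  n <- length(sample)
  if (burnin >= n) abort(paste0("burnin (", burnin, ") must be smaller than the ",
                                "sample size (", n, ")"))
  used <- sample[(burnin + 1L):n]
  tab <- table(unlist(lapply(used, tree_clade_keys)))
  tibble::tibble(
    clade = names(tab),
    size = lengths(strsplit(names(tab), "|", fixed = TRUE)),
    frequency = as.numeric(tab) / length(used)) |>
    dplyr::arrange(dplyr::desc(.data$frequency), .data$size, .data$clade)
}

as_tree_sample <- function(sample) {
  if (inherits(sample, "phylo")) sample <- list(sample)
  if (!length(sample)) abort("tree sample is empty")
  if (!all(vapply(sample, inherits, TRUE, "phylo")))
    abort("`sample` must contain 'phylo' trees")
  ref <- sort(sample[[1]]$tip.label)
  for (i in seq_along(sample))
    if (!identical(sort(sample[[i]]$tip.label), ref))
      abort("all trees in the sample must share one taxon set")
  sample
}

# All clades of a tree as canonical keys (sorted tip labels, pipe-joined),
# including tip singletons and the root clade.
tree_clade_keys <- function(tree) {
  n_tip <- ape::Ntip(tree)
  desc <- clade_members(tree)
  keys <- vapply(desc, function(tips)
    paste(sort(tree$tip.label[tips]), collapse = "|"), "")
  c(tree$tip.label, keys)
}

# tip sets per internal node (ape ids n_tip+1 ..)
clade_members <- function(tree) {
  n_tip <- ape::Ntip(tree)
  po <- ape::reorder.phylo(tree, "postorder")
  members <- c(as.list(seq_len(n_tip)), vector("list", tree$Nnode))
  for (e in seq_len(nrow(po$edge))) {
    par <- po$edge[e, 1]; chi <- po$edge[e, 2]
    members[[par]] <- c(members[[par]], members[[chi]])
  }
  members[(n_tip + 1L):(n_tip + tree$Nnode)]
}

#' Select the maximum clade credibility tree from a sample
#'
#' Scores every sampled tree by aggregating the posterior frequencies of its
#' internal clades — the default aggregate is the sum of clade frequencies;
#' `"log-product"` (the product of clade posteriors, as in TreeAnnotator) is
#' also available — and returns the sampled tree (never a consensus) with the
#' highest score, ties broken by the lowest tree index. Internal nodes of the
#' selected tree whose clade posterior is at least `pp_limit` are annotated;
#' `pp_limit` never affects which tree is selected.
#'
#' @inheritParams clade_frequencies
#' @param score `"sum"` or `"log-product"`.
#' @param pp_limit Posterior-probability annotation threshold (default 0.5).
#' @return An `mcc_result`: `tree` (the selected `phylo`, with `node.label`
#'   holding annotated posteriors and `node_pp` kept numerically), `index`
#'   (position in the post-burn-in sample), `scores` (per post-burn-in tree),
#'   `clade_table`, `node_pp`, `pp_limit`, `score_mode`.
#' @export
mcc_tree <- function(sample, burnin = 0, score = c("sum", "log-product"),
                     pp_limit = 0.5) {
  score <- match.arg(score)
  if (pp_limit < 0 || pp_limit > 1) abort("`pp_limit` must be in [0, 1]")
  sample <- as_tree_sample(sample)
  n <- length(sample)
  if (burnin >= n) abort("burnin must be smaller than the sample size")
  used <- sample[(burnin + 1L):n]
  freq_tbl <- clade_frequencies(used, burnin = 0)
  freq <- setNames(freq_tbl$frequency, freq_tbl$clade)
  tree_scores <- vapply(used, function(tr) {
    f <- freq[internal_clade_keys(tr)]
    if (score == "sum") sum(f) else sum(log(f))
  }, numeric(1))
  idx <- which.max(tree_scores)  # which.max takes the first (lowest index) tie
  best <- used[[idx]]
  pp <- unname(freq[internal_clade_keys(best)])
  best$node.label <- ifelse(pp >= pp_limit, format(pp, digits = 4), "")
  structure(list(tree = best, index = idx, scores = tree_scores,
                 clade_table = freq_tbl, node_pp = pp, pp_limit = pp_limit,
                 score_mode = score),
            class = "mcc_result")
}

internal_clade_keys <- function(tree) {
  vapply(clade_members(tree), function(tips)
    paste(sort(tree$tip.label[tips]), collapse = "|"), "")
}

#' @export
print.mcc_result <- function(x, ...) {
  cat("Maximum clade credibility tree (", x$score_mode, " score)\n", sep = "")
  cat(" selected tree index:", x$index, "of", length(x$scores),
      sprintf("(score %.4f)\n", x$scores[x$index]))
  cat(" internal clades with PP >=", x$pp_limit, ":",
      sum(x$node_pp >= x$pp_limit), "of", length(x$node_pp), "\n")
  invisible(x)
}

#' Write an MCC tree as NEXUS with posterior annotations
#'
#' Writes the selected tree in a NEXUS trees block with BEAST-style
#' `[&posterior=...]` comments on internal nodes whose posterior meets the
#' annotation limit, plus a companion clade table if requested.
#'
#' @param x An `mcc_result`.
#' @param path Output NEXUS path.
#' @param clade_table_path Optional TSV path for the clade-frequency table.
#' @return `path`, invisibly.
#' @export
write_mcc <- function(x, path, clade_table_path = NULL) {
  stopifnot(inherits(x, "mcc_result"))
  nwk <- annotated_newick(x$tree, x$node_pp, x$pp_limit)
  writeLines(c("#NEXUS", "begin trees;",
               paste0("\ttree MCC = [&R] ", nwk), "end;"), path)
  if (!is.null(clade_table_path))
    utils::write.table(x$clade_table, clade_table_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Newick with [&posterior=p] comments after internal-node closing parens.
annotated_newick <- function(tree, node_pp, pp_limit) {
  n_tip <- ape::Ntip(tree)
  children <- split(tree$edge[, 2], tree$edge[, 1])
  lens <- numeric(n_tip + tree$Nnode)
  lens[tree$edge[, 2]] <- tree$edge.length
  build <- function(node) {
    if (node <= n_tip)
      return(paste0(tree$tip.label[node], ":", format(lens[node], digits = 12)))
    pp <- node_pp[node - n_tip]
    ann <- if (is.finite(pp) && pp >= pp_limit)
      paste0("[&posterior=", format(pp, digits = 4), "]") else ""
    kids <- paste(vapply(children[[as.character(node)]], build, ""),
                  collapse = ",")
    suffix <- if (node == n_tip + 1L) "" else
      paste0(":", format(lens[node], digits = 12))
    paste0("(", kids, ")", ann, suffix)
  }
  paste0(build(n_tip + 1L), ";")
}
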