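#' Read a tree or a tree sample from file
#'
#' Reads one or more rooted trees from a Newick or NEXUS file (NEXUS translate
#' blocks are supported) and verifies that all trees share an identical tip
#' set, as required for posterior samples over a fixed taxon list.
#'
#' @param path Path to the tree file.
#' @param format `"auto"` (default; sniffed from the `#NEXUS` header and file
#'   extension), `"newick"` or `"nexus"`.
#' @return A `multiPhylo` object (even for a single tree).
#' @examples
#' f <- tempfile(fileext = ".nwk")
#' writeLines("((A:1,B:1):1,(C:1,D:1):1);", f)
#' trees <- read_trees(f)
#' length(trees)
#' @export
read_trees <- function(path, format = c("auto", "newick", "nexus")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("tree file not found: ", path))
  if (format == "auto") {
    first <- toupper(trimws(readLines(path, n = 1L, warn = FALSE)))
    format <- if (startsWith(first, "#NEXUS") ||
                  grepl("\\.(nex|nexus|trees)$", tolower(path))) "nexus"
              else "newick"
  }
  trees <- tryCatch(
    if (format == "nexus") ape::read.nexus(path) else ape::read.tree(path),
    error = function(e) abort(paste0("failed to parse ", format, " file '",
                                     path, "': ", conditionMessage(e))))
  if (is.null(trees)) abort(paste0("no trees could be parsed from '", path, "'"))
  if (inherits(trees, "phylo")) trees <- structure(list(trees), class = "multiPhylo")
  for (i in seq_along(trees)) {
    dup <- unique(trees[[i]]$tip.label[duplicated(trees[[i]]$tip.label)])
    if (length(dup))
      abort(paste0("tree ", i, " has duplicated tip labels: ",
                   paste(dup, collapse = ", ")))
  }
  ref <- sort(trees[[1]]$tip.label)
  for (i in seq_along(trees)[-1]) {
    lab <- sort(trees[[i]]$tip.label)
    if (!identical(ref, lab)) {
      sd <- union(setdiff(ref, lab), setdiff(lab, ref))
      abort(paste0("tree ", i, " has a different taxon set than tree 1; ",
                   "symmetric difference: ", paste(sd, collapse = ", ")))
    }
  }
  trees
}

#' Write a tree or tree sample to file
#'
#' @param trees A `phylo` or `multiPhylo` object.
#' @param path Output path.
#' @param format `"newick"` (one tree per line) or `"nexus"` (trees block with
#'   translate table).
#' @return `path`, invisibly.
#' @export
write_trees <- function(trees, path, format = c("newick", "nexus")) {
  format <- match.arg(format)
  if (format == "nexus") ape::write.nexus(trees, file = path, translate = TRUE)
  else ape::write.tree(trees, file = path)
  invisible(path)
}

#' Validate a phylogeny for likelihood work
#'
#' Checks that the tree is rooted, fully resolved (binary), has unique tip
#' labels and nonnegative branch lengths. Polytomies are rejected by default;
#' with `resolve_polytomies = TRUE` they are resolved randomly into
#' zero-length branches under `seed`.
#'
#' @param tree A `phylo` object.
#' @param resolve_polytomies Resolve polytomies randomly instead of erroring.
#' @param seed Seed for random polytomy resolution.
#' @return The validated (possibly resolved) `phylo`.
#' @export
validate_tree <- function(tree, resolve_polytomies = FALSE, seed = NULL) {
  if (!inherits(tree, "phylo")) abort("`tree` must be a 'phylo' object")
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup))
    abort(paste0("duplicated tip labels: ", paste(dup, collapse = ", ")))
  if (ape::Ntip(tree) >= 2 && !ape::is.rooted(tree))
    abort("tree must be rooted")
  if (ape::Ntip(tree) >= 3 && !ape::is.binary(tree)) {
    if (!resolve_polytomies)
      abort(paste0("tree contains polytomies; pass resolve_polytomies = TRUE ",
                   "to resolve them randomly with zero-length branches"))
    tree <- with_seed(seed, ape::multi2di(tree, random = TRUE))
    if (!is.null(tree$edge.length))
      tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0))
    abort("tree has negative branch lengths")
  tree
}

#' Set all branch lengths equal
#'
#' Replaces every branch length by a single value, the punctuational-style
#' transform in which each branch contributes one unit of expected change
#' regardless of its duration. The absolute value is absorbed into the rate
#' estimates, so the default of 1 is canonical.
#'
#' @param tree A `phylo` object.
#' @param value Positive branch length assigned to every edge.
#' @return The transformed `phylo` (topology unchanged).
#' @export
set_equal_branch_lengths <- function(tree, value = 1) {
  if (!inherits(tree, "phylo")) abort("`tree` must be a 'phylo' object")
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value) || value <= 0)
    abort("`value` must be a single positive number")
  tree$edge.length <- rep(value, nrow(tree$edge))
  tree
}

#' Check whether a tree is ultrametric
#'
#' @param tree A `phylo` with branch lengths.
#' @param tolerance Maximum allowed absolute deviation of any root-to-tip
#'   depth from the mean depth.
#' @return A logical scalar with attribute `"max_deviation"`, the largest
#'   absolute root-to-tip deviation from the mean depth.
#' @export
check_ultrametric <- function(tree, tolerance = 1e-8) {
  if (!inherits(tree, "phylo")) abort("`tree` must be a 'phylo' object")
  if (is.null(tree$edge.length)) abort("tree has no branch lengths")
  if (ape::Ntip(tree) < 2)
    return(structure(TRUE, max_deviation = 0))
  depth <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  dev <- max(abs(depth - mean(depth)))
  structure(dev <= tolerance, max_deviation = dev)
}

#' Prune a tree to a set of taxa
#'
#' Returns the induced subtree on the kept tips; suppressed degree-2 nodes
#' have their branch lengths summed, so patristic distances among kept tips
#' are preserved.
#'
#' @param tree A `phylo` object.
#' @param keep Character vector of tip labels to keep.
#' @param allow_single_tip Permit a one-tip result (default errors: a single
#'   tip carries no likelihood information).
#' @return A list with `tree` (the pruned `phylo`) and `dropped` (labels
#'   removed).
#' @export
prune_to_taxa <- function(tree, keep, allow_single_tip = FALSE) {
  if (!inherits(tree, "phylo")) abort("`tree` must be a 'phylo' object")
  keep <- intersect(tree$tip.label, keep)
  if (length(keep) == 0L) abort("no requested taxa are present in the tree")
  dropped <- setdiff(tree$tip.label, keep)
  if (length(keep) == 1L) {
    if (!allow_single_tip)
      abort("pruning would leave a single tip; set allow_single_tip = TRUE")
    len <- ape::node.depth.edgelength(tree)[match(keep, tree$tip.label)]
    one <- ape::read.tree(text = paste0("(", keep, ":", format(len, digits = 17), ");"))
    return(list(tree = one, dropped = dropped))
  }
  pruned <- if (length(dropped)) ape::keep.tip(tree, keep) else tree
  list(tree = pruned, dropped = dropped)
}
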