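#' Transition probabilities over a branch
#'
#' Computes `P(t) = exp(Q t)` by scaling-and-squaring on the generator;
#' roundoff-negative entries are clamped and rows renormalized so each row is
#' a probability distribution.
#'
#' @param Q A square rate matrix (zero row sums, nonnegative off-diagonals).
#' @param t Branch length (nonnegative).
#' @return A stochastic matrix of the same dimension as `Q`.
#' @examples
#' Q <- build_q(mk2_model(), c(q01 = 0.3, q10 = 0.3))
#' transition_probabilities(Q, 1)
#' @export
transition_probabilities <- function(Q, t) {
  check_q(Q)
  if (!is.numeric(t) || length(t) != 1L || !is.finite(t) || t < 0)
    abort("`t` must be a single nonnegative number")
  P <- .pmat_cpp(unname(Q), t)
  dimnames(P) <- dimnames(Q)
  P
}

check_q <- function(Q) {
  if (!is.matrix(Q) || nrow(Q) != ncol(Q) || !is.numeric(Q))
    abort("`Q` must be a square numeric matrix")
  off <- Q; diag(off) <- 0
  if (any(off < 0)) abort("`Q` off-diagonal entries must be nonnegative")
  if (any(abs(rowSums(Q)) > 1e-8 * max(1, max(abs(Q)))))
    abort("`Q` rows must sum to zero")
  invisible(Q)
}

#' Stationary distribution of a rate matrix
#'
#' Solves `pi Q = 0`, `sum(pi) = 1`.
#'
#' @param Q A rate matrix with a unique stationary distribution.
#' @return A probability vector.
#' @export
stationary_distribution <- function(Q) {
  check_q(Q)
  k <- nrow(Q)
  A <- rbind(t(Q), rep(1, k))
  pi <- qr.solve(A, c(rep(0, k), 1))
  pi[pi < 0] <- 0
  pi / sum(pi)
}

#' Root-state treatment for tree likelihoods
#'
#' How per-state likelihoods at the root are combined into the data
#' likelihood: `"uniform"` weights (1/k each, the common default for these
#' analyses), `"stationary"` (the chain's equilibrium under the fitted Q),
#' `"fitzjohn"` (weights proportional to the root partial likelihoods), or
#' `"fixed"` (all weight on one known state).
#'
#' @param mode One of `"uniform"`, `"stationary"`, `"fitzjohn"`, `"fixed"`.
#' @param state For `"fixed"`: the root state (0-based integer).
#' @return A `root_treatment` object.
#' @export
root_treatment <- function(mode = c("uniform", "stationary", "fitzjohn", "fixed"),
                           state = NULL) {
  mode <- match.arg(mode)
  if (mode == "fixed") {
    if (is.null(state) || length(state) != 1L || state < 0)
      abort("`state` (0-based) is required for mode = 'fixed'")
    state <- as.integer(state)
  }
  structure(list(mode = mode, state = state), class = "root_treatment")
}

as_root_treatment <- function(root) {
  if (inherits(root, "root_treatment")) root
  else if (is.character(root)) root_treatment(root)
  else abort("`root` must be a root_treatment or a mode string")
}

root_weights <- function(root, Q, root_partial) {
  k <- nrow(Q)
  switch(root$mode,
    uniform = rep(1 / k, k),
    stationary = stationary_distribution(Q),
    fitzjohn = {
      s <- sum(root_partial)
      if (s <= 0) rep(1 / k, k) else root_partial / s
    },
    fixed = {
      if (root$state >= k) abort("fixed root state outside state space")
      w <- rep(0, k); w[root$state + 1L] <- 1; w
    })
}

# Tip partial-likelihood matrix in the tree's tip order. `states` is either a
# named vector of 0-based states (NA = missing, treated as ambiguous) or a
# numeric matrix of per-state tip likelihoods with tip labels as rownames.
tip_likelihoods <- function(tree, states, k) {
  tips <- tree$tip.label
  if (is.matrix(states)) {
    if (ncol(states) != k) abort("tip likelihood matrix must have k columns")
    if (is.null(rownames(states)) || !all(tips %in% rownames(states)))
      abort("tip likelihood matrix must cover every tree tip by rowname")
    return(unname(states[tips, , drop = FALSE]))
  }
  if (is.null(names(states))) abort("`states` must be named by tip label")
  miss <- setdiff(tips, names(states))
  if (length(miss))
    abort(paste0("no state for tree tip(s): ",
                 paste(head(miss, 5), collapse = ", "),
                 if (length(miss) > 5) ", ..."))
  s <- states[tips]
  bad <- !is.na(s) & (s < 0 | s >= k | s != floor(s))
  if (any(bad))
    abort(paste0("states must be integers in 0..", k - 1, " or NA; offending tips: ",
                 paste(head(tips[bad], 5), collapse = ", ")))
  L <- matrix(0, length(tips), k)
  L[is.na(s), ] <- 1
  obs <- which(!is.na(s))
  L[cbind(obs, s[obs] + 1L)] <- 1
  L
}

#' Log-likelihood of tip data by Felsenstein pruning
#'
#' Exact log-likelihood of discrete tip states on a rooted binary tree under
#' a continuous-time Markov model with generator `Q`, computed by the
#' post-order pruning recursion with per-node rescaling (compiled core).
#'
#' @param tree A rooted, fully resolved `phylo` with branch lengths.
#' @param states Named vector of 0-based tip states (NA = missing), or a tip
#'   likelihood matrix (rows named by tip).
#' @param Q Rate matrix (e.g. from [build_q()]).
#' @param root A [root_treatment()] or mode string; default uniform weights.
#' @return The log-likelihood (scalar; `-Inf` for impossible data under a
#'   fixed root).
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
#' Q <- build_q(mk2_model(), c(q01 = 0.2, q10 = 0.4))
#' pruning_loglik(tr, c(A = 0, B = 0, C = 1), Q)
#' @export
pruning_loglik <- function(tree, states, Q, root = root_treatment("uniform")) {
  check_q(Q)
  root <- as_root_treatment(root)
  pr <- pruning_root_partial(tree, states, Q)
  w <- root_weights(root, Q, pr$root_partial)
  lik <- sum(w * pr$root_partial)
  if (lik <= 0) return(-Inf)
  log(lik) + pr$log_scaler
}

# Shared pruning entry: returns rescaled root partials + log scaler.
pruning_root_partial <- function(tree, states, Q) {
  tree <- prepare_tree(tree)
  k <- nrow(Q)
  L <- tip_likelihoods(tree, states, k)
  po <- ape::reorder.phylo(tree, "postorder")
  res <- .pruning_partials_cpp(po$edge, po$edge.length, ape::Ntip(po), L, unname(Q))
  if (isTRUE(res$loglik_impossible))
    return(list(root_partial = rep(0, k), log_scaler = -Inf))
  list(root_partial = as.numeric(res$root_partial), log_scaler = res$log_scaler)
}

prepare_tree <- function(tree) {
  if (!inherits(tree, "phylo")) abort("`tree` must be a 'phylo' object")
  if (is.null(tree$edge.length)) abort("tree has no branch lengths")
  if (any(tree$edge.length < 0)) abort("tree has negative branch lengths")
  if (ape::Ntip(tree) < 2) abort("tree must have at least 2 tips")
  if (!ape::is.binary(tree) || !ape::is.rooted(tree))
    abort("tree must be rooted and fully resolved; see validate_tree()")
  tree
}
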