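#' Rate models for binary-trait Markov chains
#'
#' A rate model describes the structure of the instantaneous rate matrix Q:
#' the state space, which off-diagonal entries are free parameters, which are
#' structural zeros, and which are tied together by equality constraints.
#'
#' States of a trait pair are ordered `(0,0), (0,1), (1,0), (1,1)` (trait 1
#' first), encoded 0..3. In the dependent model each of the 8 permitted
#' single-trait changes has its own rate `qij` (1-based state indices, e.g.
#' `q13` is trait 1 gain while trait 2 is 0); the two double-transition pairs
#' `(0,0)<->(1,1)` and `(0,1)<->(1,0)` are structural zeros, i.e. the traits
#' can only change one at a time. The independent model ties each trait's
#' gain and loss rates across the other trait's states, leaving 4 free rates.
#'
#' @return A `rate_model` object.
#' @name rate_models
NULL

new_rate_model <- function(name, k, params, index) {
  stopifnot(nrow(index) == k, ncol(index) == k,
            all(index %in% 0:length(params)), all(diag(index) == 0))
  structure(list(name = name, k = k, params = params, index = index),
            class = "rate_model")
}

#' @describeIn rate_models Two-state Mk model for a single binary trait, with
#'   free gain (`q01`) and loss (`q10`) rates.
#' @export
mk2_model <- function() {
  idx <- matrix(0L, 2, 2)
  idx[1, 2] <- 1L  # q01
  idx[2, 1] <- 2L  # q10
  new_rate_model("mk2", 2L, c("q01", "q10"), idx)
}

#' @describeIn rate_models Dependent model for a trait pair: 8 free rates,
#'   each trait's transition rates may depend on the other trait's state.
#' @export
dependent_model <- function() {
  idx <- matrix(0L, 4, 4)
  p <- c("q12", "q13", "q21", "q24", "q31", "q34", "q42", "q43")
  idx[1, 2] <- 1L; idx[1, 3] <- 2L
  idx[2, 1] <- 3L; idx[2, 4] <- 4L
  idx[3, 1] <- 5L; idx[3, 4] <- 6L
  idx[4, 2] <- 7L; idx[4, 3] <- 8L
  new_rate_model("dependent", 4L, p, idx)
}

#' @describeIn rate_models Independent model: the nested special case in
#'   which each trait's gain/loss rates are identical regardless of the other
#'   trait's state (`q13 = q24`, `q31 = q42`, `q12 = q34`, `q21 = q43`),
#'   leaving 4 free rates named `q01_1`, `q10_1` (trait 1) and `q01_2`,
#'   `q10_2` (trait 2).
#' @export
independent_model <- function() {
  idx <- matrix(0L, 4, 4)
  p <- c("q01_1", "q10_1", "q01_2", "q10_2")
  idx[1, 3] <- 1L; idx[2, 4] <- 1L  # trait 1 gain
  idx[3, 1] <- 2L; idx[4, 2] <- 2L  # trait 1 loss
  idx[1, 2] <- 3L; idx[3, 4] <- 3L  # trait 2 gain
  idx[2, 1] <- 4L; idx[4, 3] <- 4L  # trait 2 loss
  new_rate_model("independent", 4L, p, idx)
}

#' Constrain two rates of a model to be equal
#'
#' Produces a new model in which the two named free parameters are merged
#' into one, reducing the free-parameter count by one. Applying one such
#' constraint to the dependent model yields a 7-parameter restricted model
#' testable against the unrestricted model with a 1-df likelihood-ratio test.
#'
#' @param model A `rate_model`.
#' @param pair Character vector of two distinct free-parameter names.
#' @param name Optional name for the merged parameter (default
#'   `"a=b"`).
#' @return A `rate_model` with one fewer free parameter.
#' @export
constrain_equal <- function(model, pair, name = NULL) {
  stopifnot(inherits(model, "rate_model"))
  if (length(pair) != 2L || anyDuplicated(pair))
    abort("`pair` must name two distinct rates")
  miss <- setdiff(pair, model$params)
  if (length(miss))
    abort(paste0("unknown rate name(s): ", paste(miss, collapse = ", "),
                 " (model has: ", paste(model$params, collapse = ", "), ")"))
  if (is.null(name)) name <- paste(pair, collapse = "=")
  i <- match(pair, model$params)
  keep <- setdiff(seq_along(model$params), i[2])
  params <- model$params[keep]
  params[params == pair[1]] <- name
  remap <- integer(length(model$params))
  remap[keep] <- seq_along(keep)
  remap[i[2]] <- remap[i[1]]
  idx <- model$index
  idx[idx > 0L] <- remap[idx[idx > 0L]]
  new_rate_model(paste0(model$name, " [", name, "]"), model$k, params, idx)
}

#' The four canonical single-rate restrictions of the dependent model
#'
#' Each restriction ties one trait-change rate across the two states of the
#' other trait. With trait 1 the focal trait (e.g. iris colour, 0 = dark,
#' 1 = bright) and trait 2 the environment trait (e.g. nesting, 0 =
#' non-cavity, 1 = cavity), the four rows ask whether: trait 1 gains
#' (`q13`/`q24`), trait 1 losses (`q31`/`q42`), trait 2 losses (`q21`/`q43`)
#' and trait 2 gains (`q12`/`q34`) depend on the other trait's state.
#'
#' @return A named list of rate-name pairs, suitable for
#'   [restricted_suite()].
#' @export
canonical_restrictions <- function() {
  list(
    t1_gain_by_t2 = c("q13", "q24"),
    t1_loss_by_t2 = c("q31", "q42"),
    t2_loss_by_t1 = c("q21", "q43"),
    t2_gain_by_t1 = c("q12", "q34"))
}

#' Build an instantaneous rate matrix from a model and rates
#'
#' @param model A `rate_model`.
#' @param rates Numeric vector of nonnegative rates, one per free parameter;
#'   if named, names must match `model$params`.
#' @return A k-by-k rate matrix with zero row sums and the model's structural
#'   zeros, with states labelled `0..k-1` (for 4-state pair models these are
#'   `(0,0),(0,1),(1,0),(1,1)`).
#' @examples
#' build_q(dependent_model(), rep(1, 8))
#' @export
build_q <- function(model, rates) {
  stopifnot(inherits(model, "rate_model"))
  if (!is.null(names(rates))) {
    miss <- setdiff(model$params, names(rates))
    if (length(miss))
      abort(paste0("missing rate(s): ", paste(miss, collapse = ", ")))
    rates <- rates[model$params]
  }
  if (length(rates) != length(model$params))
    abort(paste0("expected ", length(model$params), " rates, got ", length(rates)))
  if (any(!is.finite(rates)) || any(rates < 0))
    abort("all rates must be finite and nonnegative")
  Q <- matrix(0, model$k, model$k)
  fill <- model$index > 0L
  Q[fill] <- rates[model$index[fill]]
  diag(Q) <- -rowSums(Q)
  dimnames(Q) <- list(state_labels(model$k), state_labels(model$k))
  Q
}

state_labels <- function(k) {
  if (k == 4L) c("00", "01", "10", "11") else as.character(seq_len(k) - 1L)
}

#' @export
print.rate_model <- function(x, ...) {
  cat("Rate model:", x$name, "\n")
  cat(" states:", x$k, " free rates:", length(x$params), "\n")
  cat(" parameters:", paste(x$params, collapse = ", "), "\n")
  invisible(x)
}

n_free_rates <- function(model) length(model$params)
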