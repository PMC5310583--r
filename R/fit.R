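#' Fit a rate model by maximum likelihood with multi-start optimization
#'
#' Maximizes the pruning log-likelihood over the model's free rates using
#' bounded quasi-Newton optimization (`nlminb`) in log-rate space, from
#' `attempts` random starting points with log10-rates drawn uniformly on
#' \[-3, 1\]. The best attempt is returned; all attempt log-likelihoods are
#' kept for diagnosing multimodality.
#'
#' @param tree Rooted binary `phylo` with branch lengths.
#' @param states Named 0-based tip states (NA = missing) or tip-likelihood
#'   matrix; the state count must match the model.
#' @param model A `rate_model` (e.g. [dependent_model()]).
#' @param attempts Number of random starts (default 25).
#' @param seed Optional seed controlling the random starts.
#' @param root A [root_treatment()] or mode string.
#' @param lower,upper Rate bounds (per unit branch length).
#' @param control Passed to [stats::nlminb()]; defaults cap evaluations at
#'   2000 with a 1e-8 relative tolerance.
#' @param hessian Also compute the observed information at the optimum (in
#'   log-rate space); adds approximate standard errors of the log rates,
#'   which are relative standard errors of the rates themselves. Rates whose
#'   relative SE is large (or not finite) are not identifiable from the tip
#'   data.
#' @return A `trait_fit` object: ML rates, log-likelihood, per-attempt
#'   diagnostics, and (with `hessian = TRUE`) `rel_se`. Supports [tidy()],
#'   [glance()], `logLik()` and `autoplot()`.
#' @examples
#' tr <- set_equal_branch_lengths(simulate_tree(40, seed = 1))
#' sim <- simulate_traits(tr, build_q(mk2_model(), c(0.3, 0.3)), seed = 2)
#' fit_model(tr, sim$tip_states, mk2_model(), attempts = 5, seed = 3)
#' @export
fit_model <- function(tree, states, model, attempts = 25, seed = NULL,
                      root = root_treatment("uniform"),
                      lower = 1e-8, upper = 1e3, control = list(),
                      hessian = FALSE) {
  stopifnot(inherits(model, "rate_model"))
  root <- as_root_treatment(root)
  if (attempts < 1) abort("`attempts` must be >= 1")
  tree <- prepare_tree(tree)
  np <- n_free_rates(model)
  L <- tip_likelihoods(tree, states, model$k)  # validates early
  control <- utils::modifyList(
    list(eval.max = 2000, iter.max = 1000, rel.tol = 1e-8), control)

  # postorder structure is fixed across evaluations; compute it once
  po <- ape::reorder.phylo(tree, "postorder")
  n_tip <- ape::Ntip(po)
  fill <- model$index > 0L
  negll <- function(x) {
    Q <- matrix(0, model$k, model$k)
    Q[fill] <- exp(x)[model$index[fill]]
    diag(Q) <- -rowSums(Q)
    res <- .pruning_partials_cpp(po$edge, po$edge.length, n_tip, L, Q)
    if (isTRUE(res$loglik_impossible)) return(1e10)
    w <- root_weights(root, Q, as.numeric(res$root_partial))
    lik <- sum(w * as.numeric(res$root_partial))
    if (lik <= 0) return(1e10)
    ll <- log(lik) + res$log_scaler
    if (!is.finite(ll)) 1e10 else -ll
  }

  starts <- with_seed(seed,
    matrix(log(10) * runif(attempts * np, -3, 1), nrow = attempts))
  res <- vector("list", attempts)
  for (a in seq_len(attempts)) {
    res[[a]] <- tryCatch(
      nlminb(starts[a, ], negll, lower = log(lower), upper = log(upper),
             control = control),
      error = function(e) list(objective = Inf, convergence = 1L,
                               message = conditionMessage(e), par = starts[a, ]))
  }
  lls <- vapply(res, function(r) -r$objective, numeric(1))
  attempt_tbl <- tibble::tibble(
    attempt = seq_len(attempts),
    loglik = lls,
    convergence = vapply(res, function(r) as.integer(r$convergence), integer(1)),
    message = vapply(res, function(r) as.character(r$message %||% ""), character(1)))
  if (all(!is.finite(lls)))
    abort(paste0("all ", attempts, " optimization attempts failed; messages: ",
                 paste(unique(attempt_tbl$message), collapse = "; ")))
  best <- which.max(lls)
  rates <- setNames(exp(res[[best]]$par), model$params)
  rel_se <- NULL
  if (hessian) {
    H <- tryCatch(stats::optimHess(res[[best]]$par, negll),
                  error = function(e) NULL)
    V <- if (!is.null(H)) tryCatch(solve(H), error = function(e) NULL)
    rel_se <- if (!is.null(V)) setNames(sqrt(pmax(diag(V), 0)), model$params)
              else setNames(rep(NA_real_, np), model$params)
  }
  structure(list(
    rel_se = rel_se,
    model_name = model$name, model = model,
    rates = rates, loglik = lls[best], n_params = np,
    attempts = attempts, best_attempt = best,
    attempt_results = attempt_tbl,
    convergence = res[[best]]$convergence,
    root = root, seed = seed, n_tips = ape::Ntip(tree)),
    class = "trait_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.trait_fit <- function(x, ...) {
  cat("ML fit of", x$model_name, "model:", x$n_params, "free rates,",
      x$n_tips, "tips\n")
  cat(sprintf(" log-likelihood: %.2f (best of %d attempts, root: %s)\n",
              x$loglik, x$attempts, x$root$mode))
  print(round(x$rates, 6))
  invisible(x)
}

#' @export
logLik.trait_fit <- function(object, ...) {
  structure(object$loglik, df = object$n_params, class = "logLik")
}

#' @rdname fit_model
#' @param x,object A `trait_fit`.
#' @param ... Unused.
#' @export
tidy.trait_fit <- function(x, ...) {
  out <- tibble::tibble(term = names(x$rates), estimate = unname(x$rates))
  if (!is.null(x$rel_se)) out$rel_std_error <- unname(x$rel_se)
  out
}

#' @rdname fit_model
#' @export
glance.trait_fit <- function(x, ...) {
  tibble::tibble(model = x$model_name, logLik = x$loglik, df = x$n_params,
                 n_tips = x$n_tips, attempts = x$attempts,
                 converged = x$convergence == 0)
}

#' Chi-squared likelihood-ratio test from two log-likelihoods
#'
#' The statistic is `2 * (ll_full - ll_restricted)`, clamped at zero
#' (optimizer noise can make it marginally negative), referred to the
#' chi-squared upper tail with `df` degrees of freedom.
#'
#' @param ll_full Log-likelihood of the richer model.
#' @param ll_restricted Log-likelihood of the nested model.
#' @param df Difference in free-parameter counts (>= 1).
#' @return A one-row tibble: `statistic`, `df`, `p.value`, `ll_full`,
#'   `ll_restricted`.
#' @examples
#' lrt(-924.50, -932.13, df = 4)
#' @export
lrt <- function(ll_full, ll_restricted, df) {
  stopifnot(is.numeric(ll_full), is.numeric(ll_restricted),
            length(ll_full) == 1L, length(ll_restricted) == 1L)
  if (!is.numeric(df) || length(df) != 1L || df < 1 || df != floor(df))
    abort("`df` must be an integer >= 1")
  stat <- max(0, 2 * (ll_full - ll_restricted))
  tibble::tibble(statistic = stat, df = as.integer(df),
                 p.value = pchisq(stat, df = df, lower.tail = FALSE),
                 ll_full = ll_full, ll_restricted = ll_restricted)
}

#' Test correlated evolution: dependent versus independent model
#'
#' Fits the 8-rate dependent and 4-rate independent models to a paired
#' 4-state character and compares them with a 4-df likelihood-ratio test. A
#' small p-value indicates that each trait's transition rates depend on the
#' state of the other trait, i.e. correlated evolution.
#'
#' @inheritParams fit_model
#' @param alpha Significance level for the verdict (default 0.05).
#' @return A `pagel_comparison`: both fits, the test tibble and a verdict.
#' @export
dependent_vs_independent <- function(tree, states, attempts = 25, seed = NULL,
                                     alpha = 0.05,
                                     root = root_treatment("uniform")) {
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must be in (0, 1)")
  fit_dep <- fit_model(tree, states, dependent_model(), attempts = attempts,
                       seed = child_seed(seed, 1L), root = root)
  fit_ind <- fit_model(tree, states, independent_model(), attempts = attempts,
                       seed = child_seed(seed, 2L), root = root)
  if (fit_dep$loglik < fit_ind$loglik - 1e-6) {
    # nesting violated: the dependent optimum was missed; restart from the
    # independent solution mapped into dependent-rate space
    x0 <- log(pmax(1e-8, independent_to_dependent(fit_ind$rates)))
    dep <- dependent_model()
    refit <- nlminb(x0, function(x) {
      ll <- pruning_loglik(tree, states, build_q(dep, exp(x)), root)
      if (!is.finite(ll)) 1e10 else -ll
    }, lower = log(1e-8), upper = log(1e3))
    if (-refit$objective > fit_dep$loglik) {
      fit_dep$loglik <- -refit$objective
      fit_dep$rates <- setNames(exp(refit$par), dep$params)
    }
  }
  test <- lrt(fit_dep$loglik, fit_ind$loglik, df = 4L)
  structure(list(fit_dependent = fit_dep, fit_independent = fit_ind,
                 test = test, alpha = alpha,
                 verdict = if (test$p.value < alpha) "dependent" else "independent"),
            class = "pagel_comparison")
}

# Expand a restricted fit's rates into the 8 dependent-model rates.
restricted_to_dependent <- function(fit) {
  dep <- dependent_model()
  idx <- fit$model$index
  out <- setNames(numeric(8), dep$params)
  for (nm in dep$params) {
    pos <- which(dep$index == match(nm, dep$params), arr.ind = TRUE)[1, ]
    out[nm] <- fit$rates[idx[pos[1], pos[2]]]
  }
  out
}

# Map independent-model rates onto the 8 dependent-model rates they imply.
independent_to_dependent <- function(r) {
  c(q12 = unname(r["q01_2"]), q13 = unname(r["q01_1"]),
    q21 = unname(r["q10_2"]), q24 = unname(r["q01_1"]),
    q31 = unname(r["q10_1"]), q34 = unname(r["q01_2"]),
    q42 = unname(r["q10_1"]), q43 = unname(r["q10_2"]))
}

#' @export
print.pagel_comparison <- function(x, ...) {
  cat("Correlated-evolution test (dependent vs independent model)\n")
  cat(sprintf(" dependent   log-likelihood: %.2f (8 rates)\n",
              x$fit_dependent$loglik))
  cat(sprintf(" independent log-likelihood: %.2f (4 rates)\n",
              x$fit_independent$loglik))
  cat(sprintf(" chi-squared = %.2f, d.f. = %d, p = %.3g (alpha = %g)\n",
              x$test$statistic, x$test$df, x$test$p.value, x$alpha))
  cat(" verdict:", x$verdict, "evolution\n")
  invisible(x)
}

#' @rdname dependent_vs_independent
#' @param x A `pagel_comparison`.
#' @param ... Unused.
#' @export
tidy.pagel_comparison <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(tidy(x$fit_dependent), model = "dependent"),
    dplyr::mutate(tidy(x$fit_independent), model = "independent"))
}

#' @rdname dependent_vs_independent
#' @export
glance.pagel_comparison <- function(x, ...) {
  tibble::tibble(ll_dependent = x$fit_dependent$loglik,
                 ll_independent = x$fit_independent$loglik,
                 statistic = x$test$statistic, df = x$test$df,
                 p.value = x$test$p.value, verdict = x$verdict)
}

#' Fit and test a suite of single-constraint restricted models
#'
#' For each named restriction (a pair of dependent-model rate names forced
#' equal), fits the 7-rate restricted model and tests it against the 8-rate
#' unrestricted dependent model with a 1-df likelihood-ratio test. The four
#' canonical restrictions ([canonical_restrictions()]) ask, for each of the
#' four trait-change types, whether its rate depends on the other trait's
#' state.
#'
#' @inheritParams fit_model
#' @param restrictions Named list of rate-name pairs (default the canonical
#'   four).
#' @param fit_full Optional pre-computed unrestricted dependent-model
#'   `trait_fit` to reuse.
#' @return A tibble with one row per restriction: restricted and full
#'   log-likelihoods, `statistic`, `df` and `p.value`.
#' @export
restricted_suite <- function(tree, states, restrictions = canonical_restrictions(),
                             attempts = 25, seed = NULL,
                             root = root_treatment("uniform"), fit_full = NULL) {
  if (length(restrictions) == 0L)
    return(tibble::tibble(restriction = character(), rates_equal = character(),
                          ll_restricted = numeric(), ll_full = numeric(),
                          statistic = numeric(), df = integer(),
                          p.value = numeric()))
  if (is.null(names(restrictions)))
    names(restrictions) <- vapply(restrictions, paste, "", collapse = "=")
  if (is.null(fit_full))
    fit_full <- fit_model(tree, states, dependent_model(), attempts = attempts,
                          seed = child_seed(seed, 0L), root = root)
  rows <- purrr::imap(restrictions, function(pair, nm) {
    m <- constrain_equal(dependent_model(), pair)
    fit_model(tree, states, m, attempts = attempts,
              seed = child_seed(seed, match(nm, names(restrictions))),
              root = root)
  })
  # nesting violations (restricted beating the full model by more than
  # optimizer slack) mean the full-model optimum was missed: lift the full
  # fit by a polish run started from the offending restricted solution
  for (fr in rows) {
    if (fr$loglik > fit_full$loglik + 1e-6) {
      x0 <- log(pmax(1e-8, restricted_to_dependent(fr)))
      dep <- dependent_model()
      refit <- nlminb(x0, function(x) {
        ll <- pruning_loglik(tree, states, build_q(dep, exp(x)), root)
        if (!is.finite(ll)) 1e10 else -ll
      }, lower = log(1e-8), upper = log(1e3))
      if (-refit$objective > fit_full$loglik) {
        fit_full$loglik <- -refit$objective
        fit_full$rates <- setNames(exp(refit$par), dep$params)
      }
    }
  }
  purrr::imap_dfr(rows, function(fr, nm) {
    dplyr::mutate(
      lrt(fit_full$loglik, min(fr$loglik, fit_full$loglik), df = 1L),
      restriction = nm, rates_equal = paste(restrictions[[nm]], collapse = "="),
      .before = 1)
  })
}
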