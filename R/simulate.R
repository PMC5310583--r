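#' Simulate a Yule (pure-birth) tree
#'
#' Grows a tree from two root lineages by a Gillespie process: with `k`
#' extant lineages the next speciation occurs after an Exp(`k * birth_rate`)
#' wait on a uniformly chosen lineage. Growth stops at `n_tips` lineages and
#' the present is placed after one further Exp(`n_tips * birth_rate`) wait
#' (the time to the next, unrealized, speciation), so the expected tree
#' height is `sum_{k=2..n} 1 / (birth_rate * k)`. The result is ultrametric
#' and fully resolved, with tips labelled `t1..tn`.
#'
#' @param n_tips Number of tips (>= 2).
#' @param birth_rate Speciation rate per lineage.
#' @param seed Optional seed (the caller's RNG stream is preserved).
#' @return A rooted ultrametric `phylo`.
#' @examples
#' simulate_tree(10, seed = 1)
#' @export
simulate_tree <- function(n_tips, birth_rate = 1, seed = NULL) {
  if (n_tips < 2) abort("`n_tips` must be >= 2")
  if (birth_rate <= 0) abort("`birth_rate` must be positive")
  with_seed(seed, {
    n_internal <- n_tips - 1L
    # active lineages: parent internal node (1-based internal id) + start time
    par <- c(1L, 1L)
    start <- c(0, 0)
    node_count <- 1L
    edge_par <- integer(0); edge_chi <- integer(0); edge_len <- numeric(0)
    t_now <- 0
    while (length(par) < n_tips) {
      t_now <- t_now + rexp(1, rate = birth_rate * length(par))
      i <- sample.int(length(par), 1L)
      node_count <- node_count + 1L
      edge_par <- c(edge_par, par[i]); edge_chi <- c(edge_chi, node_count)
      edge_len <- c(edge_len, t_now - start[i])
      par <- c(par[-i], node_count, node_count)
      start <- c(start[-i], t_now, t_now)
    }
    t_end <- t_now + rexp(1, rate = birth_rate * n_tips)
    # internal ids 1..n-1 -> ape ids n_tips + id; tips get ids 1..n_tips
    edge <- rbind(
      cbind(n_tips + edge_par, n_tips + edge_chi),
      cbind(n_tips + par, seq_len(n_tips)))
    len <- c(edge_len, t_end - start)
    tree <- structure(list(
      edge = edge, edge.length = len, Nnode = n_internal,
      tip.label = paste0("t", seq_len(n_tips))), class = "phylo")
    ape::reorder.phylo(tree, "cladewise")
  })
}

#' Simulate trait evolution along a tree with a full event log
#'
#' Runs an exact Gillespie simulation of the continuous-time Markov chain
#' `Q` down every branch (exponential waiting times between competing
#' permitted transitions), recording every change event. For 4-state pair
#' models the structural zeros of `Q` guarantee the two traits never change
#' simultaneously.
#'
#' @param tree A rooted binary `phylo` with branch lengths.
#' @param Q Rate matrix (any state count).
#' @param root_state 0-based root state, or a length-k probability vector to
#'   draw it from; default uniform.
#' @param seed Optional seed.
#' @return A `trait_sim` list: `tip_states` (named 0-based vector),
#'   `node_states` (all ape node ids), `events` tibble (`edge`, `parent`,
#'   `child`, `time` along the edge, `from`, `to`), `root_state`, `tree`,
#'   `Q`.
#' @export
simulate_traits <- function(tree, Q, root_state = NULL, seed = NULL) {
  check_q(Q)
  tree <- prepare_tree(tree)
  k <- nrow(Q)
  with_seed(seed, {
    if (is.null(root_state)) root_state <- sample.int(k, 1L) - 1L
    else if (length(root_state) > 1L) {
      if (length(root_state) != k) abort("`root_state` probability vector must have k entries")
      root_state <- sample.int(k, 1L, prob = root_state) - 1L
    }
    root_state <- as.integer(root_state)
    if (root_state < 0 || root_state >= k) abort("`root_state` outside state space")
    cw <- ape::reorder.phylo(tree, "cladewise")
    n_node <- ape::Ntip(cw) + cw$Nnode
    node_state <- rep(NA_integer_, n_node)
    node_state[ape::Ntip(cw) + 1L] <- root_state
    ev <- list()
    for (e in seq_len(nrow(cw$edge))) {
      s <- node_state[cw$edge[e, 1]]
      len <- cw$edge.length[e]
      t_at <- 0
      repeat {
        out_rate <- -Q[s + 1L, s + 1L]
        if (out_rate <= 0) break
        t_at <- t_at + rexp(1, out_rate)
        if (t_at > len) break
        probs <- Q[s + 1L, ]; probs[s + 1L] <- 0
        s_new <- sample.int(k, 1L, prob = probs) - 1L
        ev[[length(ev) + 1L]] <- c(e, cw$edge[e, 1], cw$edge[e, 2], t_at, s, s_new)
        s <- s_new
      }
      node_state[cw$edge[e, 2]] <- s
    }
    events <- if (length(ev)) {
      m <- do.call(rbind, ev)
      tibble::tibble(edge = as.integer(m[, 1]), parent = as.integer(m[, 2]),
                     child = as.integer(m[, 3]), time = m[, 4],
                     from = as.integer(m[, 5]), to = as.integer(m[, 6]))
    } else {
      tibble::tibble(edge = integer(), parent = integer(), child = integer(),
                     time = numeric(), from = integer(), to = integer())
    }
    structure(list(
      tip_states = setNames(node_state[seq_len(ape::Ntip(cw))], cw$tip.label),
      node_states = node_state, events = events, root_state = root_state,
      tree = cw, Q = Q), class = "trait_sim")
  })
}

#' Replay a simulation's event log from the root state
#'
#' Re-derives every node state by applying the logged events in order along
#' each edge; used to verify event-log consistency.
#'
#' @param sim A `trait_sim`.
#' @return Named tip-state vector.
#' @export
replay_events <- function(sim) {
  stopifnot(inherits(sim, "trait_sim"))
  cw <- sim$tree
  n_node <- ape::Ntip(cw) + cw$Nnode
  state <- rep(NA_integer_, n_node)
  state[ape::Ntip(cw) + 1L] <- sim$root_state
  for (e in seq_len(nrow(cw$edge))) {
    s <- state[cw$edge[e, 1]]
    ee <- sim$events[sim$events$edge == e, ]
    if (nrow(ee)) {
      ee <- ee[order(ee$time), ]
      stopifnot(ee$from[1] == s, all(ee$from[-1] == ee$to[-nrow(ee)]))
      s <- ee$to[nrow(ee)]
    }
    state[cw$edge[e, 2]] <- s
  }
  setNames(state[seq_len(ape::Ntip(cw))], cw$tip.label)
}

#' Study-emulating simulation configuration
#'
#' Bundles the generating conditions for [make_study_like_dataset()]: a Yule
#' tree at the scale of the motivating dataset (1582 species scored for both
#' iris colour and nesting), a dependent-model truth in which the loss rate
#' of the bright state is elevated in the non-cavity environment (rate
#' `q31 = base_rate * asymmetry`), and per-trait missing-data dropout
#' producing unequal per-analysis sample sizes. The default `base_rate` of
#' 0.15 per unit time on a unit-birth-rate Yule tree gives roughly one
#' expected change per trait per root-to-tip path, inside the identifiability
#' sweet spot of about 0.5-2 changes per path.
#'
#' @param n_tips Tree size.
#' @param birth_rate Yule speciation rate.
#' @param base_rate Baseline transition rate for all 8 dependent-model rates.
#' @param asymmetry Multiplier applied to `q31` (trait 1 loss while trait 2
#'   is 0, i.e. bright-to-dark in non-cavity nesters); 1 recovers an
#'   independence-satisfying truth.
#' @param missing Length-2 fraction of species with the first/second trait
#'   missing (MCAR).
#' @param root_state 0-based root state (default 0 = dark, non-cavity).
#' @param seed Seed for tree, traits and dropout.
#' @return A `study_config` list.
#' @export
study_config <- function(n_tips = 1582, birth_rate = 1, base_rate = 0.15,
                         asymmetry = 8, missing = c(0.05, 0.15),
                         root_state = 0, seed = NULL) {
  stopifnot(n_tips >= 4, base_rate > 0, asymmetry > 0,
            length(missing) == 2, all(missing >= 0), all(missing < 1))
  rates <- setNames(rep(base_rate, 8), dependent_model()$params)
  rates["q31"] <- base_rate * asymmetry
  structure(list(n_tips = n_tips, birth_rate = birth_rate, rates = rates,
                 missing = missing, root_state = root_state, seed = seed),
            class = "study_config")
}

#' Generate a study-like synthetic dataset
#'
#' Simulates a Yule tree and a two-trait history under a dependent-model
#' truth (see [study_config()]), applies per-trait MCAR dropout, and
#' optionally writes the tree (Newick) and trait table (CSV, using the
#' default codebook's state names for iris colour and nest type) so the full
#' pipeline can be exercised end to end with no external data.
#'
#' @param config A [study_config()].
#' @param dir Optional output directory for `tree.nwk` and `traits.csv`.
#' @return A list: `tree`, `traits` (tibble of species, iris, nest state
#'   names with NAs), `sim` (the `trait_sim` with event log), `q_true`,
#'   `config`, and `files` when written.
#' @export
make_study_like_dataset <- function(config = study_config(), dir = NULL) {
  stopifnot(inherits(config, "study_config"))
  tree <- simulate_tree(config$n_tips, config$birth_rate,
                        seed = child_seed(config$seed, 101L))
  q_true <- build_q(dependent_model(), config$rates)
  sim <- simulate_traits(tree, q_true, root_state = config$root_state,
                         seed = child_seed(config$seed, 102L))
  dec <- decode_pair(unname(sim$tip_states))
  drop <- with_seed(child_seed(config$seed, 103L), cbind(
    runif(config$n_tips) < config$missing[1],
    runif(config$n_tips) < config$missing[2]))
  iris <- c("dark", "bright")[dec$trait1 + 1L]
  nest <- c("non-cavity", "cavity")[dec$trait2 + 1L]
  iris[drop[, 1]] <- NA
  nest[drop[, 2]] <- NA
  traits <- tibble::tibble(species = names(sim$tip_states),
                           iris = iris, nest = nest)
  files <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    files <- c(tree = file.path(dir, "tree.nwk"),
               traits = file.path(dir, "traits.csv"))
    write_trees(tree, files[["tree"]])
    utils::write.csv(traits, files[["traits"]], row.names = FALSE, na = "")
  }
  list(tree = tree, traits = traits, sim = sim, q_true = q_true,
       config = config, files = files)
}
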