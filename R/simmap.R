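# Stochastic character mapping: sampling full state histories along the
# tree conditional on the tip data and a fitted Mk model.  Node states are
# drawn from their joint conditional distribution (pruning pass followed by
# root-to-tip sampling); each branch history is then an endpoint-conditioned
# CTMC path, sampled by rejection with a uniformization fallback.

#' Sample stochastic character maps
#'
#' @inheritParams mk_loglik
#' @param n_maps Number of histories to sample.
#' @param seed RNG seed.
#' @param max_rejection_tries Forward-simulation attempts per branch before
#'   switching to the uniformization sampler.
#' @return A list of class `simmap_history_list`; each element is a
#'   `simmap_history` with
#'   * `node_states`: sampled state of every node (phylo numbering),
#'   * `maps`: per-edge named numeric vectors of segment durations (names =
#'     states, in order along the branch; durations sum to the branch
#'     length; consecutive states differ),
#'   * `events`: data frame `edge`, `time` (from the parent end), `from`,
#'     `to`.
#' @export
stochastic_map <- function(tree, tips, model, n_maps = 1000L, seed = NULL,
                           max_rejection_tries = 50L) {
  .assert(inherits(tree, "phylo"), "`tree` must be a phylo object")
  tips <- tip_state_matrix(tips, model$states, tree$tip.label)
  .seed_if(seed)
  pp <- .pruning_pass(tree, tips, model, keep_pmats = TRUE)
  nt <- length(tree$tip.label)
  root <- nt + 1L
  preorder <- rev(pp$postorder)
  states <- model$states
  K <- model$K
  unif_cache <- new.env(parent = emptyenv())
  unif_cache$powers <- list(diag(K))        # B^0
  mu <- max(-diag(model$Q))
  unif_cache$B <- if (mu > 0) diag(K) + model$Q / mu else diag(K)

  root_p <- model$root_prior * pp$part[root, ]
  .assert(sum(root_p) > 0, "zero likelihood at the root")

  out <- vector("list", n_maps)
  for (m in seq_len(n_maps)) {
    node_state <- integer(nt + tree$Nnode)
    node_state[root] <- sample.int(K, 1L, prob = root_p)
    maps <- vector("list", nrow(tree$edge))
    evs <- list()
    for (e in preorder) {
      par <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
      p <- pp$pmats[[e]][node_state[par], ] * pp$part[ch, ]
      node_state[ch] <- sample.int(K, 1L, prob = p)
      path <- .sample_bridge(model$Q, node_state[par], node_state[ch],
                             tree$edge.length[e], pp$pmats[[e]], mu,
                             unif_cache, max_rejection_tries)
      maps[[e]] <- setNames(path$durations, states[path$states])
      if (length(path$states) > 1L) {
        times <- cumsum(path$durations)
        evs[[length(evs) + 1L]] <- data.frame(
          edge = e, time = times[-length(times)],
          from = states[path$states[-length(path$states)]],
          to = states[path$states[-1L]], stringsAsFactors = FALSE)
      }
    }
    events <- if (length(evs)) do.call(rbind, evs) else
      data.frame(edge = integer(), time = numeric(),
                 from = character(), to = character(),
                 stringsAsFactors = FALSE)
    out[[m]] <- structure(list(node_states = states[node_state],
                               maps = maps, events = events),
                          class = "simmap_history")
  }
  structure(out, class = "simmap_history_list",
            tree = tree, states = states)
}

#' Endpoint-conditioned CTMC path from state i to j over time t
#'
#' Returns run-length-encoded segments: `states` (indices) and `durations`
#' (summing to t).  Forward rejection first; uniformization when rejection
#' keeps failing or is hopeless (P[i,j] tiny).
#' @noRd
.sample_bridge <- function(Q, i, j, t, P, mu, cache, max_tries) {
  if (t <= 0 || mu <= 0)
    return(list(states = i, durations = t))
  for (try in seq_len(max_tries)) {
    path <- .sample_forward(Q, i, t)
    if (path$states[length(path$states)] == j) return(path)
  }
  .sample_uniformization(Q, i, j, t, P, mu, cache)
}

#' @noRd
.sample_forward <- function(Q, i, t) {
  s <- i; tt <- 0
  states <- i; durations <- numeric(0)
  repeat {
    rate <- -Q[s, s]
    dt <- if (rate > 0) rexp(1L, rate) else Inf
    if (tt + dt >= t) {
      durations <- c(durations, t - tt)
      break
    }
    tt <- tt + dt
    durations <- c(durations, dt)
    probs <- Q[s, ]; probs[s] <- 0
    s <- sample.int(nrow(Q), 1L, prob = probs)
    states <- c(states, s)
  }
  list(states = states, durations = durations)
}

#' Powers of the uniformized jump matrix, cached
#' @noRd
.b_power <- function(cache, n) {
  while (length(cache$powers) < n + 1L)
    cache$powers[[length(cache$powers) + 1L]] <-
      cache$powers[[length(cache$powers)]] %*% cache$B
  cache$powers[[n + 1L]]
}

#' @noRd
.sample_uniformization <- function(Q, i, j, t, P, mu, cache) {
  pij <- P[i, j]
  .assert(pij > 0, "endpoint pair with zero transition probability")
  # draw the number of uniformized jumps N | endpoints
  u <- runif(1L) * pij
  n <- -1L; acc <- 0
  nmax <- max(20L, ceiling(mu * t + 10 * sqrt(mu * t + 1)))
  repeat {
    n <- n + 1L
    acc <- acc + dpois(n, mu * t) * .b_power(cache, n)[i, j]
    if (acc >= u || n > 10L * nmax) break
  }
  if (n == 0L) return(list(states = i, durations = t))
  # intermediate states of the jump chain, sampled sequentially
  B <- cache$B
  seq_states <- integer(n + 1L)
  seq_states[1L] <- i; seq_states[n + 1L] <- j
  if (n > 1L) {
    s <- i
    for (k in seq_len(n - 1L)) {
      m <- n - k                       # jumps remaining after this one
      w <- B[s, ] * .b_power(cache, m)[, j]
      s <- sample.int(nrow(Q), 1L, prob = w)
      seq_states[k + 1L] <- s
    }
  }
  jump_times <- sort(runif(n, 0, t))
  # collapse virtual jumps (state unchanged)
  real <- which(seq_states[-1L] != seq_states[-(n + 1L)])
  if (length(real) == 0L) return(list(states = i, durations = t))
  states <- c(i, seq_states[real + 1L])
  bounds <- c(0, jump_times[real], t)
  list(states = states, durations = diff(bounds))
}

#' Per-node state frequencies across a set of stochastic maps
#'
#' The empirical analogue of the marginal ancestral posteriors: the
#' fraction of sampled histories in which each node is in each state
#' (displayed as pie charts at nodes in the usual figures).
#'
#' @param histories A `simmap_history_list` from [stochastic_map()].
#' @return Matrix nodes x states of frequencies, rows summing to 1.
#' @export
summarize_node_states <- function(histories) {
  .assert(inherits(histories, "simmap_history_list") && length(histories) > 0,
          "`histories` must be a non-empty simmap_history_list")
  states <- attr(histories, "states")
  n_nodes <- length(histories[[1]]$node_states)
  freq <- matrix(0, n_nodes, length(states),
                 dimnames = list(NULL, states))
  for (h in histories) {
    idx <- cbind(seq_len(n_nodes), match(h$node_states, states))
    freq[idx] <- freq[idx] + 1
  }
  freq / length(histories)
}
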