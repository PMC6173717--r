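# Simulated dated trees and continuous-time Markov character histories,
# used as the test harness for the ancestral-state machinery.

#' Simulate a dated ultrametric tree
#'
#' Draws a pure-birth (Yule) tree and rescales it so every tip-to-root path
#' equals `root_age`, giving an ultrametric tree with branch lengths in Myr
#' by construction.
#'
#' @param n_tips Number of tips (at least 2).
#' @param root_age Root age in Myr.
#' @param seed RNG seed.
#' @return An [ape::read.tree()]-style `phylo` object.
#' @examples
#' tr <- simulate_tree(10, root_age = 50, seed = 1)
#' @export
simulate_tree <- function(n_tips, root_age = 55, seed = NULL) {
  .assert(n_tips >= 2, "`n_tips` must be at least 2")
  .assert(root_age > 0, "`root_age` must be positive")
  .seed_if(seed)
  tr <- ape::rphylo(n_tips, birth = 1, death = 0)
  depth <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length * (root_age / depth)
  tr$tip.label <- sprintf("t%03d", seq_len(n_tips))
  tr
}

#' Validate a CTMC generator matrix
#' @noRd
.check_q <- function(Q) {
  .assert(is.matrix(Q) && nrow(Q) == ncol(Q) && nrow(Q) >= 2,
          "`Q` must be a square matrix with at least 2 states")
  off <- Q; diag(off) <- 0
  .assert(all(off >= 0), "off-diagonal rates of `Q` must be >= 0")
  .assert(max(abs(rowSums(Q))) < 1e-8, "rows of `Q` must sum to 0")
  if (is.null(rownames(Q))) {
    dimnames(Q) <- list(paste0("S", seq_len(nrow(Q))),
                        paste0("S", seq_len(nrow(Q))))
  }
  Q
}

#' Simulate a discrete character along a dated tree
#'
#' Runs a continuous-time Markov chain with generator `Q` from the root
#' towards the tips, recording every transition (branch, time from the
#' parent end of the branch, from-state, to-state).  The emitted history is
#' the ground truth against which inferred histories (stochastic maps) can
#' be compared.
#'
#' @param tree A `phylo` tree with branch lengths.
#' @param Q Generator matrix (rows sum to 0, off-diagonals >= 0); state
#'   names are taken from its rownames.
#' @param root_state State at the root (name or index).
#' @param seed RNG seed.
#' @return A list of class `ctmc_sim`: `tip_states` (named character),
#'   `node_states` (states at every node, tips first in `phylo` node
#'   numbering), `history` (data frame `edge`, `parent`, `child`, `time`,
#'   `from`, `to`), and the `tree` and `states` used.
#' @export
simulate_states_on_tree <- function(tree, Q, root_state = 1L, seed = NULL) {
  .assert(inherits(tree, "phylo"), "`tree` must be a phylo object")
  Q <- .check_q(Q)
  states <- rownames(Q)
  if (is.character(root_state)) {
    .assert(root_state %in% states, "unknown root state '%s'", root_state)
    root_state <- match(root_state, states)
  }
  .seed_if(seed)

  nt <- length(tree$tip.label)
  n_nodes <- nt + tree$Nnode
  node_state <- integer(n_nodes)
  node_state[nt + 1L] <- root_state

  # preorder: parents before children
  ord <- rev(ape::postorder(tree))
  ev <- list()
  for (e in ord) {
    par <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
    len <- tree$edge.length[e]
    s <- node_state[par]; t <- 0
    repeat {
      rate <- -Q[s, s]
      if (rate <= 0) break
      dt <- rexp(1L, rate)
      if (t + dt > len) break
      t <- t + dt
      probs <- Q[s, ]; probs[s] <- 0
      s_new <- sample.int(length(states), 1L, prob = probs)
      ev[[length(ev) + 1L]] <- data.frame(
        edge = e, parent = par, child = ch, time = t,
        from = states[s], to = states[s_new], stringsAsFactors = FALSE)
      s <- s_new
    }
    node_state[ch] <- s
  }
  history <- if (length(ev)) do.call(rbind, ev) else
    data.frame(edge = integer(), parent = integer(), child = integer(),
               time = numeric(), from = character(), to = character(),
               stringsAsFactors = FALSE)
  tips <- setNames(states[node_state[seq_len(nt)]], tree$tip.label)
  structure(list(tip_states = tips, node_states = states[node_state],
                 history = history, tree = tree, states = states),
            class = "ctmc_sim")
}
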