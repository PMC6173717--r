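# Independent oracles used across the test suite.  Each is a deliberately
# naive implementation (exhaustive enumeration, per-locus loops, fine-step
# discrete-time simulation) kept free of the code paths it checks.

# Exhaustive-enumeration Mk log-likelihood: sums over every internal-node
# state assignment; tip probability rows are summed per edge.
enum_loglik <- function(tree, tipm, model) {
  nt <- length(tree$tip.label)
  K <- model$K
  P <- lapply(seq_len(nrow(tree$edge)), function(e)
    as.matrix(Matrix::expm(model$Q * tree$edge.length[e])))
  grid <- as.matrix(expand.grid(rep(list(seq_len(K)), tree$Nnode)))
  tot <- 0
  for (g in seq_len(nrow(grid))) {
    st <- grid[g, ]
    pr <- model$root_prior[st[1L]]          # root is node nt + 1
    for (e in seq_len(nrow(tree$edge))) {
      a <- tree$edge[e, 1L]; b <- tree$edge[e, 2L]
      sa <- st[a - nt]
      pr <- pr * if (b <= nt)
        sum(P[[e]][sa, ] * tipm[tree$tip.label[b], ]) else P[[e]][sa, st[b - nt]]
    }
    tot <- tot + pr
  }
  log(tot)
}

# Enumeration-based marginal posteriors for the internal nodes.
enum_internal_marginals <- function(tree, tipm, model) {
  nt <- length(tree$tip.label)
  K <- model$K
  P <- lapply(seq_len(nrow(tree$edge)), function(e)
    as.matrix(Matrix::expm(model$Q * tree$edge.length[e])))
  grid <- as.matrix(expand.grid(rep(list(seq_len(K)), tree$Nnode)))
  mass <- matrix(0, tree$Nnode, K)
  for (g in seq_len(nrow(grid))) {
    st <- grid[g, ]
    pr <- model$root_prior[st[1L]]
    for (e in seq_len(nrow(tree$edge))) {
      a <- tree$edge[e, 1L]; b <- tree$edge[e, 2L]
      sa <- st[a - nt]
      pr <- pr * if (b <= nt)
        sum(P[[e]][sa, ] * tipm[tree$tip.label[b], ]) else P[[e]][sa, st[b - nt]]
    }
    mass[cbind(seq_len(tree$Nnode), st)] <- mass[cbind(seq_len(tree$Nnode), st)] + pr
  }
  mass / rowSums(mass)
}

# Plain per-locus recomputation of the three screens (one locus at a time,
# no matrix algebra).
oracle_screens <- function(gm, tags, sex, orientation,
                           p = screen_params()) {
  het_sex <- if (orientation == "XY") "M" else "F"
  hom_sex <- setdiff(c("M", "F"), het_sex)
  out <- list(freq = character(0), het = character(0),
              sex_limited = character(0))
  for (i in seq_len(nrow(gm))) {
    g_het <- gm[i, sex == het_sex]; g_het <- g_het[!is.na(g_het)]
    g_hom <- gm[i, sex == hom_sex]; g_hom <- g_hom[!is.na(g_hom)]
    if (length(g_het) == 0 || length(g_hom) == 0) next
    f_alt_hom <- sum(g_hom) / (2 * length(g_hom))
    x_is_ref <- f_alt_hom <= 0.5
    x_hom <- if (x_is_ref) 1 - f_alt_hom else f_alt_hom
    f_alt_het <- sum(g_het) / (2 * length(g_het))
    x_het <- if (x_is_ref) 1 - f_alt_het else f_alt_het
    if (x_hom >= p$x_freq_min_homogametic &&
        x_het >= p$x_freq_band_heterogametic[1] &&
        x_het <= p$x_freq_band_heterogametic[2])
      out$freq <- c(out$freq, rownames(gm)[i])
    if (sum(g_hom == 1) == 0 &&
        mean(g_het == 1) >= p$min_het_fraction_heterogametic)
      out$het <- c(out$het, rownames(gm)[i])
  }
  for (i in seq_len(nrow(tags))) {
    pres_het <- tags[i, sex == het_sex]
    pres_hom <- tags[i, sex == hom_sex]
    if (sum(pres_hom) == 0 &&
        mean(pres_het) >= p$min_presence_fraction_heterogametic)
      out$sex_limited <- c(out$sex_limited, rownames(tags)[i])
  }
  out
}

# Plain per-locus recomputation of the locus filters.
oracle_filter <- function(gm, sex, p = filter_params()) {
  keep <- logical(nrow(gm))
  for (i in seq_len(nrow(gm))) {
    g <- gm[i, ]
    gm_m <- g[sex == "M"]; gm_f <- g[sex == "F"]
    pres_m <- mean(!is.na(gm_m)); pres_f <- mean(!is.na(gm_f))
    gg <- g[!is.na(g)]
    if (length(gg) == 0) next
    f_alt <- sum(gg) / (2 * length(gg))
    maf <- min(f_alt, 1 - f_alt)
    het <- mean(gg == 1)
    keep[i] <- pres_m >= p$min_presence_per_sex &&
      pres_f >= p$min_presence_per_sex &&
      maf >= p$min_maf && het <= p$max_obs_het
  }
  rownames(gm)[keep]
}

# Fine-step discrete-time simulation of a Markov character on a tree;
# returns the transition count of one replicate.
disc_time_events <- function(tree, Q, root_state, dt = 0.01) {
  K <- nrow(Q)
  P1 <- diag(K) + Q * dt
  stopifnot(all(diag(P1) > 0))
  nt <- length(tree$tip.label)
  node_state <- integer(nt + tree$Nnode)
  node_state[nt + 1L] <- root_state
  n_events <- 0L
  for (e in rev(ape::postorder(tree))) {
    s <- node_state[tree$edge[e, 1L]]
    for (step in seq_len(round(tree$edge.length[e] / dt))) {
      s_new <- sample.int(K, 1L, prob = P1[s, ])
      if (s_new != s) n_events <- n_events + 1L
      s <- s_new
    }
    node_state[tree$edge[e, 2L]] <- s
  }
  n_events
}

# Small random ARD generator with unit state names.
random_q <- function(K, max_rate = 0.3) {
  Q <- matrix(runif(K * K, 0.01, max_rate), K, K)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  dimnames(Q) <- list(LETTERS[seq_len(K)], LETTERS[seq_len(K)])
  Q
}
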