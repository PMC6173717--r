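# Mk (k-state continuous-time Markov) models of discrete character
# evolution on a dated tree: generator construction under the ER / SYM /
# ARD constraints, Felsenstein-pruning likelihood with probabilistic tip
# rows, maximum-likelihood fitting with AIC comparison, profile confidence
# intervals, and marginal ancestral-state posteriors.

#' Construct an Mk model
#'
#' @param states Character vector of state names (K >= 2).
#' @param constraint `"ER"` (one rate), `"SYM"` (K(K-1)/2 rates, Q
#'   symmetric) or `"ARD"` (K(K-1) rates).  SYM rates fill the upper
#'   triangle column-by-column; ARD rates fill off-diagonals column-by-column.
#' @param rates Numeric vector of non-negative rates, length matching the
#'   constraint.
#' @param root_prior `"uniform"`, `"equilibrium"` (stationary distribution
#'   of Q) or a numeric probability vector of length K.
#' @return An object of class `mk_model` with elements `states`, `K`,
#'   `constraint`, `rates`, `Q`, `root_prior`.
#' @examples
#' m <- mk_model(c("Chr01", "Chr03", "Chr05"), "ER", rates = 0.05)
#' @export
mk_model <- function(states, constraint = c("ER", "SYM", "ARD"), rates,
                     root_prior = "uniform") {
  constraint <- match.arg(constraint)
  K <- length(states)
  .assert(K >= 2, "need at least 2 states")
  .assert(!anyDuplicated(states), "state names must be unique")
  np <- mk_n_params(K, constraint)
  .assert(length(rates) == np,
          "constraint %s with K = %d needs %d rate(s), got %d",
          constraint, K, np, length(rates))
  .assert(all(rates >= 0), "rates must be non-negative")
  Q <- .build_q(K, constraint, rates)
  dimnames(Q) <- list(states, states)
  prior <- .resolve_root_prior(root_prior, Q)
  structure(list(states = states, K = K, constraint = constraint,
                 rates = rates, Q = Q, root_prior = prior),
            class = "mk_model")
}

#' Number of free rate parameters under a constraint
#' @param K Number of states.
#' @param constraint `"ER"`, `"SYM"` or `"ARD"`.
#' @export
mk_n_params <- function(K, constraint) {
  switch(constraint,
         ER = 1L, SYM = as.integer(K * (K - 1) / 2),
         ARD = as.integer(K * (K - 1)),
         stop("unknown constraint: ", constraint))
}

#' @noRd
.build_q <- function(K, constraint, rates) {
  Q <- matrix(0, K, K)
  if (constraint == "ER") {
    Q[] <- rates[1]
  } else if (constraint == "SYM") {
    Q[upper.tri(Q)] <- rates
    Q <- Q + t(Q)
  } else {
    off <- row(Q) != col(Q)
    Q[off] <- rates
  }
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q
}

#' @noRd
.resolve_root_prior <- function(root_prior, Q) {
  K <- nrow(Q)
  if (is.numeric(root_prior)) {
    .assert(length(root_prior) == K && all(root_prior >= 0) &&
              abs(sum(root_prior) - 1) < 1e-9,
            "numeric root prior must be a length-%d probability vector", K)
    return(root_prior)
  }
  if (identical(root_prior, "uniform")) return(rep(1 / K, K))
  if (identical(root_prior, "equilibrium")) {
    # left null vector of Q
    ns <- tryCatch({
      e <- eigen(t(Q))
      v <- Re(e$vectors[, which.min(abs(e$values))])
      v / sum(v)
    }, error = function(e) rep(1 / K, K))
    if (any(!is.finite(ns)) || any(ns < -1e-8)) ns <- rep(1 / K, K)
    return(pmax(ns, 0) / sum(pmax(ns, 0)))
  }
  stop("unknown root prior: ", root_prior)
}

#' @export
print.mk_model <- function(x, ...) {
  cat(sprintf("mk_model: %d states, constraint %s\n", x$K, x$constraint))
  print(round(x$Q, 6))
  invisible(x)
}

# -- transition probabilities ------------------------------------------------

#' Factory for P(t) = expm(Qt)
#'
#' Eigendecomposition of Q is computed once; each branch then needs only a
#' K x K reconstruction.  When the eigenvector matrix is ill-conditioned
#' (possible for ARD generators), falls back to Matrix::expm per call.
#' Every returned matrix is checked to have rows summing to 1 within 1e-10
#' (then clamped to [0, 1] and renormalized against round-off).
#' @noRd
.pmat_factory <- function(Q) {
  K <- nrow(Q)
  eg <- tryCatch(eigen(Q), error = function(e) NULL)
  use_eigen <- !is.null(eg) && {
    Vinv <- tryCatch(solve(eg$vectors), error = function(e) NULL)
    !is.null(Vinv) &&
      max(Mod(eg$vectors %*% diag(eg$values, K) %*% Vinv - Q)) < 1e-8
  }
  finalize <- function(P) {
    rs <- rowSums(P)
    if (any(abs(rs - 1) > 1e-10) || any(P < -1e-10)) return(NULL)
    P[P < 0] <- 0
    P / rowSums(P)
  }
  if (use_eigen) {
    V <- eg$vectors; Vinv <- solve(V); lam <- eg$values
    f_eigen <- function(t) {
      if (t == 0) return(diag(K))
      P <- Re(V %*% (exp(lam * t) * Vinv))
      finalize(P)
    }
  } else f_eigen <- function(t) NULL
  f_expm <- function(t) {
    if (t == 0) return(diag(K))
    P <- as.matrix(Matrix::expm(Q * t))
    out <- finalize(P)
    .assert(!is.null(out), "matrix exponential failed row-sum check (t = %g)", t)
    out
  }
  function(t) {
    P <- f_eigen(t)
    if (is.null(P)) P <- f_expm(t)
    P
  }
}

# -- tip-state matrices ------------------------------------------------------

#' Build or validate a tip-state probability matrix
#'
#' Each tip gets a probability row over the K states; rows must sum to 1
#' (within 1e-9).  A character vector of observed states is expanded to
#' one-hot rows; `NA` entries (state unknown) get the uniform row, as do
#' tips present in the tree but absent from the input.
#'
#' @param x Either a named character vector of tip states (NA = unknown) or
#'   a numeric matrix with tip rownames and state colnames.
#' @param states Character vector of state names.
#' @param tips Optional character vector of required tip labels; missing
#'   tips are added with the uniform row.
#' @return Numeric matrix tips x states with unit row sums.
#' @export
tip_state_matrix <- function(x, states, tips = NULL) {
  K <- length(states)
  if (is.matrix(x)) {
    .assert(!is.null(rownames(x)), "tip-state matrix needs tip rownames")
    if (!is.null(colnames(x))) {
      .assert(setequal(colnames(x), states), "matrix columns must match states")
      x <- x[, states, drop = FALSE]
    } else {
      .assert(ncol(x) == K, "matrix must have %d columns", K)
      colnames(x) <- states
    }
    m <- x
  } else {
    .assert(!is.null(names(x)), "a state vector needs tip names")
    m <- matrix(1 / K, length(x), K, dimnames = list(names(x), states))
    known <- !is.na(x)
    .assert(all(x[known] %in% states), "unknown state(s): %s",
            paste(setdiff(x[known], states), collapse = ", "))
    m[known, ] <- 0
    m[cbind(which(known), match(x[known], states))] <- 1
  }
  if (!is.null(tips)) {
    extra <- setdiff(tips, rownames(m))
    if (length(extra)) {
      add <- matrix(1 / K, length(extra), K, dimnames = list(extra, states))
      m <- rbind(m, add)
    }
    m <- m[tips, , drop = FALSE]
  }
  .assert(all(abs(rowSums(m) - 1) < 1e-9), "tip-state rows must sum to 1")
  .assert(all(m >= 0), "tip-state probabilities must be non-negative")
  m
}

# -- pruning likelihood ------------------------------------------------------

#' Postorder partial likelihoods with per-branch rescaling
#'
#' Returns the (rescaled) partial-likelihood matrix over all nodes, the
#' accumulated log-scale factor, and the per-edge transition matrices.
#' @noRd
.pruning_pass <- function(tree, tips, model, keep_pmats = FALSE) {
  nt <- length(tree$tip.label)
  n_nodes <- nt + tree$Nnode
  .assert(setequal(rownames(tips), tree$tip.label),
          "tip labels of the tree and the tip-state matrix must match")
  tips <- tips[tree$tip.label, , drop = FALSE]
  pmat <- .pmat_factory(model$Q)
  part <- matrix(1, n_nodes, model$K)
  part[seq_len(nt), ] <- tips
  logscale <- 0
  po <- ape::postorder(tree)
  pmats <- if (keep_pmats) vector("list", nrow(tree$edge)) else NULL
  for (e in po) {
    par <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
    P <- pmat(tree$edge.length[e])
    if (keep_pmats) pmats[[e]] <- P
    v <- as.vector(P %*% part[ch, ])
    s <- sum(v)
    .assert(is.finite(s) && s > 0, "numerical underflow in pruning (edge %d)", e)
    part[par, ] <- part[par, ] * (v / s)
    logscale <- logscale + log(s)
  }
  list(part = part, logscale = logscale, pmats = pmats, postorder = po,
       pmat_fun = pmat)
}

#' Mk log-likelihood by Felsenstein pruning
#'
#' Probabilistic tip rows enter directly as tip partial likelihoods; the
#' root combines the root partials with the model's root prior.
#'
#' @param tree A rooted `phylo` tree with branch lengths.
#' @param tips Tip states: anything accepted by [tip_state_matrix()].
#' @param model An [mk_model()].
#' @return The log-likelihood (scalar).
#' @export
mk_loglik <- function(tree, tips, model) {
  .assert(inherits(tree, "phylo"), "`tree` must be a phylo object")
  tips <- tip_state_matrix(tips, model$states, tree$tip.label)
  pp <- .pruning_pass(tree, tips, model)
  root <- length(tree$tip.label) + 1L
  lik <- sum(model$root_prior * pp$part[root, ])
  log(lik) + pp$logscale
}

# -- fitting -----------------------------------------------------------------

#' Fit an Mk model by maximum likelihood
#'
#' Rates are optimized on the log scale within `bounds`.  The ER model uses
#' golden-section search; SYM and ARD use multi-start L-BFGS-B with
#' log-spaced starting rates, plus any user-supplied `init` (used for warm
#' starts from a nested fit).  If the optimizer ends below the best
#' starting point, the starting point is kept, so warm-started fits can
#' never fall below their nested model.
#'
#' @inheritParams mk_loglik
#' @param constraint `"ER"`, `"SYM"` or `"ARD"`.
#' @param n_starts Number of optimization starts (SYM/ARD).
#' @param bounds Rate bounds (per Myr).
#' @param init Optional numeric vector of starting rates.
#' @param root_prior Passed to [mk_model()].
#' @return An object of class `mk_fit`: `model` (fitted), `lnL`, `AIC`,
#'   `npar`, `convergence` (0 = clean; anything else flagged, best point
#'   still returned).
#' @export
fit_mk <- function(tree, tips, constraint = c("ER", "SYM", "ARD"),
                   n_starts = 10L, bounds = c(1e-8, 1e3), init = NULL,
                   root_prior = "uniform") {
  constraint <- match.arg(constraint)
  states <- if (is.matrix(tips)) colnames(tips) else
    sort(unique(tips[!is.na(tips)]))
  .assert(length(states) >= 2, "need at least 2 states in `tips`")
  tips <- tip_state_matrix(tips, states, tree$tip.label)
  K <- length(states)
  np <- mk_n_params(K, constraint)
  lb <- log(bounds[1]); ub <- log(bounds[2])

  nll <- function(logr) {
    m <- mk_model(states, constraint, exp(logr), root_prior)
    ll <- tryCatch(mk_loglik(tree, tips, m), error = function(e) -Inf)
    if (!is.finite(ll)) 1e10 else -ll
  }

  if (constraint == "ER") {
    opt <- optimize(nll, c(lb, ub), tol = 1e-8)
    par <- opt$minimum; val <- opt$objective; conv <- 0L
  } else {
    base <- 10^seq(-4, 0, length.out = max(1L, n_starts))
    starts <- lapply(base, function(b)
      pmin(pmax(log(b) + runif(np, -0.5, 0.5), lb), ub))
    if (!is.null(init)) {
      .assert(length(init) == np, "`init` must have %d rates", np)
      starts <- c(list(pmin(pmax(log(init), lb), ub)), starts)
    }
    best <- NULL
    for (s in starts) {
      v0 <- nll(s)
      o <- tryCatch(
        optim(s, nll, method = "L-BFGS-B", lower = lb, upper = ub,
              control = list(maxit = 500)),
        error = function(e) list(par = s, value = v0, convergence = 99L))
      if (o$value > v0) o <- list(par = s, value = v0, convergence = 0L)
      if (is.null(best) || o$value < best$value) best <- o
    }
    par <- best$par; val <- best$value; conv <- best$convergence
    if (conv != 0L)
      warning("optimizer did not converge cleanly; best point returned",
              call. = FALSE)
  }
  model <- mk_model(states, constraint, exp(par), root_prior)
  lnL <- -val
  structure(list(model = model, lnL = lnL,
                 AIC = 2 * np - 2 * lnL, npar = np, convergence = conv),
            class = "mk_fit")
}

#' @export
print.mk_fit <- function(x, ...) {
  cat(sprintf("mk_fit: %s, lnL = %.4f, AIC = %.4f (%d parameter%s)\n",
              x$model$constraint, x$lnL, x$AIC, x$npar,
              if (x$npar > 1) "s" else ""))
  invisible(x)
}

#' Fit and compare ER, SYM and ARD models
#'
#' Models are fitted in nesting order with warm starts (the SYM fit starts
#' from the ER optimum expanded to pairwise rates, ARD from the SYM
#' optimum), which both speeds up fitting and guarantees the likelihood
#' ordering lnL(ER) <= lnL(SYM) <= lnL(ARD).
#'
#' @inheritParams fit_mk
#' @param constraints Which constraints to fit.
#' @return List with `fits` (named list of `mk_fit`), `comparison` (data
#'   frame of lnL, npar, AIC, dAIC) and `best` (constraint name with lowest
#'   AIC).
#' @export
fit_mk_models <- function(tree, tips, constraints = c("ER", "SYM", "ARD"),
                          n_starts = 10L, bounds = c(1e-8, 1e3),
                          root_prior = "uniform") {
  states <- if (is.matrix(tips)) colnames(tips) else
    sort(unique(tips[!is.na(tips)]))
  K <- length(states)
  order_all <- c("ER", "SYM", "ARD")
  .assert(all(constraints %in% order_all), "unknown constraint requested")
  needed <- order_all[seq_len(max(match(constraints, order_all)))]
  fits <- list(); init <- NULL
  for (cons in needed) {
    fit <- fit_mk(tree, tips, cons, n_starts, bounds, init = init,
                  root_prior = root_prior)
    if (cons %in% constraints) fits[[cons]] <- fit
    # expand this fit's rates into the next constraint's parameterization
    init <- switch(cons,
                   ER = rep(fit$model$rates, mk_n_params(K, "SYM")),
                   SYM = { Qf <- fit$model$Q
                           Qf[row(Qf) != col(Qf)] },
                   ARD = NULL)
  }
  comparison <- data.frame(
    constraint = names(fits),
    lnL = vapply(fits, `[[`, numeric(1), "lnL"),
    npar = vapply(fits, `[[`, integer(1), "npar"),
    AIC = vapply(fits, `[[`, numeric(1), "AIC"),
    row.names = NULL, stringsAsFactors = FALSE)
  comparison$dAIC <- comparison$AIC - min(comparison$AIC)
  list(fits = fits, comparison = comparison,
       best = comparison$constraint[which.min(comparison$AIC)])
}

#' Profile confidence interval for the ER rate
#'
#' Finds the rates at which the profile log-likelihood drops
#' `qchisq(level, 1) / 2` units below the maximum; an endpoint pinned at a
#' rate bound is returned as that bound.
#'
#' @inheritParams mk_loglik
#' @param fit An ER `mk_fit`.
#' @param level Confidence level.
#' @param bounds Rate bounds.
#' @return Numeric `c(lower, upper)`.
#' @export
mk_profile_ci <- function(tree, tips, fit, level = 0.95,
                          bounds = c(1e-8, 1e3)) {
  .assert(inherits(fit, "mk_fit") && fit$model$constraint == "ER",
          "`fit` must be an ER mk_fit")
  states <- fit$model$states
  tips <- tip_state_matrix(tips, states, tree$tip.label)
  ll <- function(r) mk_loglik(tree, tips, mk_model(states, "ER", r,
                                                   fit$model$root_prior))
  target <- fit$lnL - qchisq(level, 1) / 2
  r_hat <- min(max(fit$model$rates[1], bounds[1] * 1.001), bounds[2] / 1.001)
  f <- function(logr) ll(exp(logr)) - target
  lo <- if (f(log(bounds[1])) >= 0) bounds[1] else
    exp(uniroot(f, c(log(bounds[1]), log(r_hat)))$root)
  hi <- if (f(log(bounds[2])) >= 0) bounds[2] else
    exp(uniroot(f, c(log(r_hat), log(bounds[2])))$root)
  c(lower = lo, upper = hi)
}

# -- marginal ancestral posteriors -------------------------------------------

#' Marginal ancestral-state posteriors at every node
#'
#' Standard two-pass algorithm: postorder partial likelihoods, then a
#' preorder pass propagating the out-of-subtree ("down") partials; the
#' marginal posterior at a node is proportional to the product of the two,
#' with the root prior entering at the root.
#'
#' @inheritParams mk_loglik
#' @return Matrix (tips + internal nodes) x states of posterior
#'   probabilities, rows summing to 1; rows follow `phylo` node numbering.
#' @export
mk_node_marginals <- function(tree, tips, model) {
  tips <- tip_state_matrix(tips, model$states, tree$tip.label)
  pp <- .pruning_pass(tree, tips, model, keep_pmats = TRUE)
  nt <- length(tree$tip.label)
  n_nodes <- nt + tree$Nnode
  root <- nt + 1L

  # children-of lists and per-edge "sibling message": P_e %*% part[child]
  edge_msg <- matrix(0, nrow(tree$edge), model$K)
  for (e in seq_len(nrow(tree$edge)))
    edge_msg[e, ] <- pp$pmats[[e]] %*% pp$part[tree$edge[e, 2L], ]
  edges_of_parent <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])

  down <- matrix(0, n_nodes, model$K)
  down[root, ] <- model$root_prior
  for (e in rev(pp$postorder)) {        # preorder: parent before child
    par <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
    sibs <- setdiff(edges_of_parent[[as.character(par)]], e)
    msg <- down[par, ]
    for (s in sibs) msg <- msg * edge_msg[s, ]
    v <- as.vector(msg %*% pp$pmats[[e]])   # t(P) %*% msg
    s <- sum(v)
    .assert(s > 0, "underflow in down-pass (edge %d)", e)
    down[ch, ] <- v / s
  }
  post <- pp$part * down
  post / rowSums(post)
}
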