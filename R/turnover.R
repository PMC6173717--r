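# Turnover counting and the statistical tests on turnover patterns: rate
# per Myr of evolutionary time, exact binomial tests of heterogamety
# preservation, the gene-resampling recruitment null, and the
# recruitment-vs-gene-count regression.
#
# A "turnover history" is a data frame of transition events with columns
#   ancestral_chr, derived_chr   chromosome identities ("unknown" allowed)
#   ancestral_system, derived_system   "XY" or "ZW" (NA when unknown)
#   scope   "interspecific", "intraspecific" or "homologous"
# A homologous event changes the heterogamety system without changing the
# chromosome.  Independent recruitments of a chromosome are events whose
# derived state is that chromosome.

#' Validate / coerce a turnover-history data frame
#'
#' @param events Data frame with the columns documented above (missing
#'   system columns are filled with NA, missing scope with
#'   "interspecific").
#' @return The validated data frame with class `turnover_history`.
#' @export
turnover_history <- function(events) {
  .assert(is.data.frame(events), "`events` must be a data frame")
  .assert(all(c("ancestral_chr", "derived_chr") %in% names(events)),
          "`events` needs ancestral_chr and derived_chr columns")
  for (cc in c("ancestral_system", "derived_system"))
    if (!cc %in% names(events)) events[[cc]] <- rep(NA_character_, nrow(events))
  if (!"scope" %in% names(events))
    events$scope <- rep("interspecific", nrow(events))
  bad <- setdiff(unique(events$scope),
                 c("interspecific", "intraspecific", "homologous"))
  .assert(length(bad) == 0, "unknown scope value(s): %s",
          paste(bad, collapse = ", "))
  sys_vals <- c(events$ancestral_system, events$derived_system)
  bad <- setdiff(sys_vals[!is.na(sys_vals)], c("XY", "ZW"))
  .assert(length(bad) == 0, "systems must be XY or ZW (got %s)",
          paste(bad, collapse = ", "))
  homol <- events$scope == "homologous"
  .assert(all(events$ancestral_chr[homol] == events$derived_chr[homol] &
                events$ancestral_system[homol] != events$derived_system[homol]),
          "homologous events must change system without changing chromosome")
  class(events) <- c("turnover_history", "data.frame")
  events
}

#' @noRd
.summarize_turnovers <- function(events) {
  known <- events$derived_chr[events$derived_chr != "unknown" &
                                !is.na(events$derived_chr)]
  recr <- if (length(known)) {
    tb <- table(known)
    setNames(as.integer(tb), names(tb))
  } else setNames(integer(0), character(0))
  sys_known <- !is.na(events$ancestral_system) & !is.na(events$derived_system)
  structure(list(
    total = nrow(events),
    per_derived_chromosome = recr[order(names(recr))],
    n_system_known = sum(sys_known),
    n_preserving_heterogamety =
      sum(events$ancestral_system[sys_known] == events$derived_system[sys_known]),
    by_scope = table(factor(events$scope,
                            c("interspecific", "intraspecific", "homologous"))),
    events = events
  ), class = "turnover_counts")
}

#' @export
print.turnover_counts <- function(x, ...) {
  cat(sprintf("turnover_counts: %d event(s); %d/%d preserve heterogamety\n",
              x$total, x$n_preserving_heterogamety, x$n_system_known))
  cat("independent recruitments per chromosome:\n")
  print(x$per_derived_chromosome)
  invisible(x)
}

#' Count turnovers from a history fixture or from stochastic maps
#'
#' For a turnover-history data frame (e.g. [load_fig1_fixture()]`$events`)
#' the events are counted directly.  For a `simmap_history_list` the
#' consensus state of each node is taken as the state with the most sampled
#' histories (ties are unresolved and excluded, with their count reported);
#' a turnover is a branch whose two resolved endpoint consensus states
#' differ, and `extra_events` (intraspecific or homologous events invisible
#' to interspecific mapping) can be appended before summarizing.
#'
#' @param x A `turnover_history` data frame or `simmap_history_list`.
#' @param ... Passed to methods.
#' @return A `turnover_counts` object: `total`, `per_derived_chromosome`
#'   (unknown-state events counted in the total but excluded here),
#'   `n_preserving_heterogamety` out of `n_system_known`, `by_scope`, and
#'   the event table.
#' @export
count_turnovers <- function(x, ...) UseMethod("count_turnovers")

#' @rdname count_turnovers
#' @export
count_turnovers.turnover_history <- function(x, ...) .summarize_turnovers(x)

#' @rdname count_turnovers
#' @export
count_turnovers.data.frame <- function(x, ...)
  .summarize_turnovers(turnover_history(x))

#' @rdname count_turnovers
#' @param extra_events Optional `turnover_history` of additional events.
#' @export
count_turnovers.simmap_history_list <- function(x, extra_events = NULL, ...) {
  tree <- attr(x, "tree")
  freq <- summarize_node_states(x)
  states <- colnames(freq)
  consensus <- apply(freq, 1, function(p) {
    top <- which(p == max(p))
    if (length(top) > 1L) NA_integer_ else top
  })
  par_c <- consensus[tree$edge[, 1L]]
  ch_c <- consensus[tree$edge[, 2L]]
  resolved <- !is.na(par_c) & !is.na(ch_c)
  change <- resolved & par_c != ch_c
  n_ev <- sum(change)
  events <- data.frame(
    edge = which(change),
    ancestral_chr = states[par_c[change]],
    derived_chr = states[ch_c[change]],
    ancestral_system = rep(NA_character_, n_ev),
    derived_system = rep(NA_character_, n_ev),
    scope = rep("interspecific", n_ev), stringsAsFactors = FALSE)
  if (!is.null(extra_events)) {
    extra <- turnover_history(as.data.frame(extra_events))
    extra$edge <- NA_integer_
    events <- rbind(events, extra[, names(events)])
  }
  out <- .summarize_turnovers(turnover_history(events))
  out$n_unresolved_nodes <- sum(is.na(consensus))
  out
}

#' Turnover rate per Myr of independent evolutionary time
#'
#' The rate is the event count divided by the total branch length of the
#' dated tree (the summed Myr of independent evolution it contains); its
#' reciprocal is the expected Myr of independent evolution per turnover, so
#' e.g. 13 events on 650 Myr of total branch length give 0.02 turnovers per
#' Myr, one turnover per 50 Myr.
#'
#' @param tree A `phylo` tree with branch lengths in Myr, or directly the
#'   total branch length (numeric, Myr).
#' @param n_events Number of turnover events.
#' @return List with `rate` (events per Myr), `myr_per_turnover`, and
#'   `total_branch_length`.
#' @export
turnover_rate <- function(tree, n_events) {
  total <- if (inherits(tree, "phylo")) sum(tree$edge.length) else
    as.numeric(tree)
  .assert(is.finite(total) && total > 0, "total branch length must be positive")
  .assert(n_events >= 0, "`n_events` must be non-negative")
  rate <- n_events / total
  list(rate = rate,
       myr_per_turnover = if (rate > 0) 1 / rate else Inf,
       total_branch_length = total)
}

#' Exact binomial test of heterogamety preservation
#'
#' Computes the exact tail probability, by direct enumeration of binomial
#' terms, of observing at least `n_preserved` heterogamety-preserving
#' transitions out of `n_total` when each transition independently
#' preserves the system with probability `p0` (0.5 for
#' direction-indifferent turnovers; 3/4 under drift-driven fixation, where
#' the doubly frequent X or Z is the likelier chromosome to fix).
#'
#' @param n_preserved Number of transitions preserving the system.
#' @param n_total Total transitions.
#' @param p0 Null preservation probability, in (0, 1).
#' @param alternative `"greater"` (upper tail, default) or `"two.sided"`
#'   (sum of all outcome probabilities not exceeding the observed one).
#' @return The p-value (scalar).
#' @examples
#' heterogamety_binomial(13, 13, 0.5)  # (1/2)^13
#' @export
heterogamety_binomial <- function(n_preserved, n_total, p0 = 0.5,
                                  alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  .assert(n_total >= 1 && n_preserved >= 0 && n_preserved <= n_total,
          "need 0 <= n_preserved <= n_total")
  .assert(p0 > 0 && p0 < 1, "`p0` must be in (0, 1)")
  pk <- function(k) exp(lchoose(n_total, k) + k * log(p0) +
                          (n_total - k) * log1p(-p0))
  probs <- pk(0:n_total)
  if (alternative == "greater")
    return(sum(probs[(n_preserved + 1L):(n_total + 1L)]))
  obs <- probs[n_preserved + 1L]
  sum(probs[probs <= obs * (1 + 1e-7)])
}

#' Gene-resampling null for chromosome recruitment
#'
#' Tests whether the observed number of independent recruitments per
#' chromosome departs from a model where each recruitment lands on a gene
#' drawn uniformly from the genome (so larger, more gene-rich chromosomes
#' are recruited more often).  Each replicate samples `sum(observed)` genes
#' without replacement from the pooled genome and tallies their
#' chromosomes.
#'
#' @param gene_counts Named positive integer vector: genes per chromosome.
#' @param observed Named integer vector of observed recruitments per
#'   chromosome (chromosomes absent from the vector count as 0).
#' @param n_replicates Number of resampling replicates (100 also in common
#'   use; default 1000).
#' @param seed RNG seed.
#' @return List with `null` (replicates x chromosomes count matrix),
#'   `p_upper` (per chromosome, add-one-corrected fraction of replicates
#'   with a count at least the observed: (r + 1)/(n + 1)), `p_upper_raw`
#'   (uncorrected fraction), `expected` (null mean counts) and `observed`.
#' @export
recruitment_null_test <- function(gene_counts, observed,
                                  n_replicates = 1000L, seed = NULL) {
  .assert(!is.null(names(gene_counts)) && all(gene_counts > 0),
          "`gene_counts` must be a named vector of positive counts")
  .assert(!is.null(names(observed)), "`observed` must be named")
  bad <- setdiff(names(observed), names(gene_counts))
  .assert(length(bad) == 0, "observed chromosome(s) absent from gene_counts: %s",
          paste(bad, collapse = ", "))
  chroms <- names(gene_counts)
  obs <- setNames(rep(0L, length(chroms)), chroms)
  obs[names(observed)] <- as.integer(observed)
  n_recr <- sum(obs)
  .assert(n_recr >= 1, "need at least one recruitment event")
  .assert(n_recr <= sum(gene_counts),
          "more recruitments (%d) than genes (%d)", n_recr, sum(gene_counts))
  .seed_if(seed)
  pool <- rep.int(seq_along(chroms), gene_counts)
  null <- matrix(0L, n_replicates, length(chroms),
                 dimnames = list(NULL, chroms))
  for (r in seq_len(n_replicates))
    null[r, ] <- tabulate(pool[sample.int(length(pool), n_recr)],
                          nbins = length(chroms))
  ge <- sweep(null, 2, obs, ">=")
  list(null = null,
       p_upper = (colSums(ge) + 1) / (n_replicates + 1),
       p_upper_raw = colMeans(ge),
       expected = colMeans(null),
       observed = obs)
}

#' Regression of recruitment counts on gene counts
#'
#' Ordinary least squares of the number of independent recruitments per
#' chromosome on the number of genes the chromosome carries.
#'
#' @param recruit_counts,gene_counts Equal-length numeric vectors (n >= 3);
#'   `gene_counts` must vary.
#' @return List with `slope`, `r_squared`, `p_value` and the underlying
#'   `lm` fit.
#' @export
recruitment_regression <- function(recruit_counts, gene_counts) {
  .assert(length(recruit_counts) == length(gene_counts),
          "vectors must have equal length")
  .assert(length(gene_counts) >= 3, "need at least 3 chromosomes")
  .assert(var(gene_counts) > 0, "`gene_counts` has zero variance")
  fit <- lm(recruit_counts ~ gene_counts)
  sm <- summary(fit)
  list(slope = unname(coef(fit)[2]),
       r_squared = sm$r.squared,
       p_value = sm$coefficients[2, 4],
       fit = fit)
}
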