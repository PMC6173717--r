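# Sex-permutation empirical nulls for the screens.
#
# All six screens report markers in every dataset, sex-linked or not, so an
# observed marker count is only credible if it exceeds what random sex
# assignments produce.  The null is built by shuffling the M/F labels
# across the sample set (a permutation: sex counts preserved) and re-running
# all six screens on every shuffle; the same shuffles are shared by the six
# screens.

#' Permutation-null configuration
#'
#' @param n_permutations Number of sex-label permutations.
#' @param percentile Percentile of the null an observed count must strictly
#'   exceed to pass (in (0, 100)).
#' @param seed Master seed; each permutation uses the sub-seed
#'   `seed + counter` so individual shuffles are reproducible.
#' @export
permutation_config <- function(n_permutations = 1000L, percentile = 99,
                               seed = NULL) {
  .assert(n_permutations >= 1, "`n_permutations` must be >= 1")
  .assert(percentile > 0 && percentile < 100, "`percentile` must be in (0, 100)")
  structure(list(n_permutations = as.integer(n_permutations),
                 percentile = percentile, seed = seed),
            class = "permutation_config")
}

#' Sample-membership matrix for permuted sex labels
#' @noRd
.perm_membership <- function(sex, cfg) {
  n <- length(sex)
  seeds <- if (is.null(cfg$seed)) rep(NA_integer_, cfg$n_permutations) else
    as.integer(cfg$seed) + seq_len(cfg$n_permutations)
  member <- matrix(0, n, cfg$n_permutations)
  for (j in seq_len(cfg$n_permutations)) {
    if (!is.na(seeds[j])) set.seed(seeds[j])
    member[, j] <- (sample(sex) == "M") + 0
  }
  attr(member, "perm_seeds") <- seeds
  member
}

#' Screen counts for every column of a membership matrix
#' @noRd
.screen_count_matrix <- function(ind, tags, member, n_m, n_f, params) {
  counts <- .group_counts(ind, member)
  pres_m <- tags %*% member
  pres_f <- rowSums(tags) - pres_m
  out <- matrix(NA_real_, ncol(member), 6L,
                dimnames = list(NULL, c("freq_XY", "het_XY", "sex_limited_XY",
                                        "freq_ZW", "het_ZW", "sex_limited_ZW")))
  for (orient in c("XY", "ZW")) {
    gr <- .orient_groups(counts, orient)
    out[, paste0("freq_", orient)] <-
      colSums(.flag_freq(gr$homo, gr$hetero, params)$flag)
    out[, paste0("het_", orient)] <-
      colSums(.flag_het(gr$homo, gr$hetero, params)$flag)
    if (orient == "XY")
      res <- .flag_tags(pres_f, pres_m, rep(n_f, ncol(member)),
                        rep(n_m, ncol(member)), params)
    else
      res <- .flag_tags(pres_m, pres_f, rep(n_m, ncol(member)),
                        rep(n_f, ncol(member)), params)
    out[, paste0("sex_limited_", orient)] <- colSums(res$flag)
  }
  out
}

#' Build the sex-permutation empirical null for all six screens
#'
#' @param gm Genotype matrix (filtered).
#' @param tags Tag presence matrix over the same samples.
#' @param sheet Sample sheet.
#' @param params A [screen_params()] object.
#' @param config A [permutation_config()] object.
#' @return An `empirical_null`: list with `observed` (named length-6 counts
#'   under the true labels), `null` (n_permutations x 6 count matrix),
#'   `percentile`, `n_permutations`, `perm_seeds`.
#' @export
build_null <- function(gm, tags, sheet, params = screen_params(),
                       config = permutation_config()) {
  .check_gm(gm)
  .check_sheet(sheet, unique(c(colnames(gm), colnames(tags))))
  .assert(identical(colnames(gm), colnames(tags)),
          "`gm` and `tags` must have identical sample columns")
  sex <- sheet$sex[match(colnames(gm), sheet$sample_id)]
  .assert(all(c("M", "F") %in% sex), "both sexes must be present")
  n_m <- sum(sex == "M"); n_f <- sum(sex == "F")

  ind <- .geno_indicators(gm)
  obs <- .screen_count_matrix(ind, tags, matrix((sex == "M") + 0, ncol = 1L),
                              n_m, n_f, params)[1L, ]
  member <- .perm_membership(sex, config)
  null <- .screen_count_matrix(ind, tags, member, n_m, n_f, params)
  structure(list(observed = obs, null = null,
                 percentile = config$percentile,
                 n_permutations = config$n_permutations,
                 perm_seeds = attr(member, "perm_seeds")),
            class = "empirical_null")
}

#' @export
print.empirical_null <- function(x, ...) {
  cat(sprintf("empirical_null: %d permutations, %gth percentile rule\n",
              x$n_permutations, x$percentile))
  print(validate_screens(x))
  invisible(x)
}

#' Null-exceedance threshold of one count series
#'
#' Uses the linear-interpolation empirical percentile (type 7).  When the
#' permutation count is too small to resolve the requested percentile
#' (fewer than `100 / (100 - percentile)` permutations), warns and falls
#' back to the exact rank rule (type 1).
#' @noRd
.null_threshold <- function(series, percentile, warn = TRUE) {
  n_needed <- ceiling(100 / (100 - percentile))
  if (length(series) < n_needed) {
    if (warn)
      warning(sprintf(
        "%d permutations cannot resolve the %gth percentile; using exact rank rule",
        length(series), percentile), call. = FALSE)
    return(quantile(series, percentile / 100, type = 1, names = FALSE))
  }
  quantile(series, percentile / 100, type = 7, names = FALSE)
}

#' Decide which screens produced credible marker sets
#'
#' A screen PASSes when its observed marker count strictly exceeds the
#' `percentile` threshold of its permutation null; an observed count equal
#' to the threshold fails (a conservative reading of "probability < 0.01 of
#' occurring by chance").
#'
#' @param null An `empirical_null` from [build_null()].
#' @param percentile Override of the percentile stored in `null`.
#' @return Data frame with one row per screen: `screen`, `approach`,
#'   `orientation`, `observed`, `threshold`, `pass`.
#' @export
validate_screens <- function(null, percentile = NULL) {
  .assert(inherits(null, "empirical_null"), "`null` must come from build_null()")
  pct <- if (is.null(percentile)) null$percentile else percentile
  screens <- colnames(null$null)
  thr <- vapply(screens, function(s) .null_threshold(null$null[, s], pct),
                numeric(1))
  data.frame(
    screen = screens,
    approach = sub("_(XY|ZW)$", "", screens),
    orientation = sub("^.*_", "", screens),
    observed = as.numeric(null$observed[screens]),
    threshold = as.numeric(thr),
    pass = as.numeric(null$observed[screens]) > as.numeric(thr),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Subsampling diagnostics: screen and validate under reduced designs
#'
#' Re-runs the full screen-plus-permutation-validation procedure on
#' subsamples of a dataset, to probe how total sample size, sex skew and
#' Y-haplotype structure drive marker yield and validation outcome.
#'
#' @param gm,tags,sheet The full dataset (the sheet may carry a
#'   `y_haplotype` column, required by designs with `male_haplotypes`).
#' @param designs A list of designs as produced by [scenario_catalog()].
#' @param params A [screen_params()] object.
#' @param config A [permutation_config()] object; design `i` uses master
#'   seed `config$seed + 10000 * i` so designs are independently seeded.
#' @param select `"first"` (deterministic: first matching samples) or
#'   `"random"`.
#' @return Data frame with one row per design x screen: observed count,
#'   null threshold and PASS decision.
#' @export
subsample_experiment <- function(gm, tags, sheet,
                                 designs = scenario_catalog(),
                                 params = screen_params(),
                                 config = permutation_config(),
                                 select = c("first", "random")) {
  select <- match.arg(select)
  .check_sheet(sheet, colnames(gm))
  out <- list()
  for (i in seq_along(designs)) {
    d <- designs[[i]]
    males <- sheet$sample_id[sheet$sex == "M"]
    females <- sheet$sample_id[sheet$sex == "F"]
    .assert(length(males) >= d$n_males && length(females) >= d$n_females,
            "design '%s' needs %d M / %d F but only %d M / %d F available",
            d$name, d$n_males, d$n_females, length(males), length(females))
    take <- function(pool, k) {
      if (select == "random") sample(pool, k) else pool[seq_len(k)]
    }
    if (!is.null(d$male_haplotypes)) {
      .assert("y_haplotype" %in% names(sheet),
              "design '%s' needs a y_haplotype column in the sheet", d$name)
      picked_m <- character(0)
      for (h in seq_along(d$male_haplotypes)) {
        pool <- sheet$sample_id[sheet$sex == "M" &
                                  !is.na(sheet$y_haplotype) &
                                  sheet$y_haplotype == h]
        .assert(length(pool) >= d$male_haplotypes[h],
                "design '%s' needs %d males of haplotype %d, found %d",
                d$name, d$male_haplotypes[h], h, length(pool))
        picked_m <- c(picked_m, take(pool, d$male_haplotypes[h]))
      }
    } else {
      picked_m <- take(males, d$n_males)
    }
    picked <- c(picked_m, take(females, d$n_females))
    cfg_i <- config
    if (!is.null(config$seed)) cfg_i$seed <- config$seed + 10000L * i
    nul <- build_null(gm[, picked, drop = FALSE],
                      tags[, picked, drop = FALSE],
                      sheet[sheet$sample_id %in% picked, , drop = FALSE],
                      params, cfg_i)
    dec <- validate_screens(nul)
    dec$design <- d$name
    out[[d$name]] <- dec
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("design", "screen", "approach", "orientation",
          "observed", "threshold", "pass")]
}
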