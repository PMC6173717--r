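# The three rule-based screens for sex-linked markers, in XY and ZW
# orientation.  All rules are stated here for XY (male heterogametic); the
# ZW orientation swaps the sex roles.
#
#   Approach "freq":        a Y-specific SNP sits at frequency ~0.5 in males
#                           and 0 in females, so the X allele (the major
#                           allele among female calls) must have frequency
#                           >= 0.95 in females and within [0.4, 0.6] in
#                           males.
#   Approach "het":         homozygous in *all* females and heterozygous in
#                           at least half of the males.
#   Approach "sex_limited": a RADtag completely absent in females and
#                           present in at least half of the males.
#
# The decision logic is implemented once over per-locus genotype-class
# counts.  The same engine is driven with a single sex-label column for an
# observed screen, or with a samples x n_permutations membership matrix to
# produce the whole permutation null in a handful of matrix products.

#' Screening thresholds
#'
#' @param x_freq_min_homogametic Minimum X-allele frequency among
#'   non-missing calls of the homogametic sex (approach "freq").
#' @param x_freq_band_heterogametic Closed interval the X-allele frequency
#'   must fall in among the heterogametic sex (approach "freq").
#' @param min_het_fraction_heterogametic Minimum fraction of non-missing
#'   heterogametic-sex calls that are heterozygous (approach "het").
#' @param min_presence_fraction_heterogametic Minimum fraction of
#'   heterogametic-sex samples in which a sex-limited tag must be present
#'   (approach "sex_limited").
#' @return A `screen_params` list.
#' @export
screen_params <- function(x_freq_min_homogametic = 0.95,
                          x_freq_band_heterogametic = c(0.4, 0.6),
                          min_het_fraction_heterogametic = 0.5,
                          min_presence_fraction_heterogametic = 0.5) {
  .check_frac(x_freq_min_homogametic, "x_freq_min_homogametic")
  .assert(length(x_freq_band_heterogametic) == 2 &&
            x_freq_band_heterogametic[1] <= x_freq_band_heterogametic[2],
          "`x_freq_band_heterogametic` must be c(low, high) with low <= high")
  .check_frac(x_freq_band_heterogametic[1], "x_freq_band_heterogametic[1]")
  .check_frac(x_freq_band_heterogametic[2], "x_freq_band_heterogametic[2]")
  .check_frac(min_het_fraction_heterogametic, "min_het_fraction_heterogametic")
  .check_frac(min_presence_fraction_heterogametic,
              "min_presence_fraction_heterogametic")
  structure(list(
    x_freq_min_homogametic = x_freq_min_homogametic,
    x_freq_band_heterogametic = x_freq_band_heterogametic,
    min_het_fraction_heterogametic = min_het_fraction_heterogametic,
    min_presence_fraction_heterogametic = min_presence_fraction_heterogametic
  ), class = "screen_params")
}

# -- count engine ------------------------------------------------------------

#' Per-locus genotype-class indicator matrices (NA counted nowhere)
#' @noRd
.geno_indicators <- function(gm) {
  obs <- !is.na(gm)
  g <- gm
  g[!obs] <- -1L
  list(het = (g == 1L) + 0, hom2 = (g == 2L) + 0, obs = obs + 0)
}

#' Per-locus counts for one or more sample groupings
#'
#' `member` is a samples x P matrix of 0/1 group membership; returns counts
#' of each genotype class within (cnt) and outside (cmp) the group, as
#' loci x P matrices.
#' @noRd
.group_counts <- function(ind, member) {
  tot_het <- rowSums(ind$het); tot_hom2 <- rowSums(ind$hom2)
  tot_obs <- rowSums(ind$obs)
  cnt <- list(het = ind$het %*% member, hom2 = ind$hom2 %*% member,
              obs = ind$obs %*% member)
  cmp <- list(het = tot_het - cnt$het, hom2 = tot_hom2 - cnt$hom2,
              obs = tot_obs - cnt$obs)
  list(in_group = cnt, out_group = cmp)
}

#' Approach-"freq" decision from homogametic/heterogametic counts
#'
#' The X allele is operationalized as the major allele among homogametic-sex
#' calls, ties broken towards the reference allele.
#' @noRd
.flag_freq <- function(homo, hetero, p) {
  evaluable <- homo$obs > 0 & hetero$obs > 0
  # guarded denominators keep the arithmetic NA-free; unevaluable loci are
  # masked out at the end
  f_alt_homo <- (2 * homo$hom2 + homo$het) / pmax(2 * homo$obs, 1)
  x_is_ref <- f_alt_homo <= 0.5
  x_homo <- f_alt_homo + (1 - 2 * f_alt_homo) * x_is_ref
  f_alt_hetero <- (2 * hetero$hom2 + hetero$het) / pmax(2 * hetero$obs, 1)
  x_hetero <- f_alt_hetero + (1 - 2 * f_alt_hetero) * x_is_ref
  ok <- evaluable &
    x_homo >= p$x_freq_min_homogametic &
    x_hetero >= p$x_freq_band_heterogametic[1] &
    x_hetero <= p$x_freq_band_heterogametic[2]
  list(flag = ok, x_homo = x_homo, x_hetero = x_hetero,
       unevaluable = !evaluable)
}

#' Approach-"het" decision
#' @noRd
.flag_het <- function(homo, hetero, p) {
  evaluable <- homo$obs > 0 & hetero$obs > 0
  frac <- hetero$het / pmax(hetero$obs, 1)
  ok <- evaluable & homo$het == 0 &
    frac >= p$min_het_fraction_heterogametic
  list(flag = ok, het_fraction_heterogametic = frac,
       unevaluable = !evaluable)
}

#' Approach-"sex_limited" decision from tag presence counts
#'
#' `n_homo`/`n_hetero` are the per-grouping sample counts (length-P
#' vectors); presence fractions use all samples of the sex as denominator.
#' @noRd
.flag_tags <- function(pres_homo, pres_hetero, n_homo, n_hetero, p) {
  frac <- sweep(pres_hetero, 2, n_hetero, "/")
  ok <- pres_homo == 0 & frac >= p$min_presence_fraction_heterogametic
  list(flag = ok, presence_fraction_heterogametic = frac)
}

#' @noRd
.orient_groups <- function(counts, orientation) {
  # counts$in_group are male counts; XY: heterogametic = M, ZW: = F
  if (orientation == "XY")
    list(hetero = counts$in_group, homo = counts$out_group)
  else
    list(hetero = counts$out_group, homo = counts$in_group)
}

#' @noRd
.new_marker_set <- function(approach, orientation, markers, stats,
                            n_unevaluable = 0L) {
  structure(list(approach = approach, orientation = orientation,
                 markers = markers, stats = stats,
                 n_unevaluable = n_unevaluable),
            class = "marker_set")
}

#' @export
print.marker_set <- function(x, ...) {
  cat(sprintf("marker_set: approach '%s', orientation %s, %d marker(s)\n",
              x$approach, x$orientation, length(x$markers)))
  invisible(x)
}

#' @noRd
.sex_member <- function(gm, sheet) {
  .check_sheet(sheet, colnames(gm))
  sex <- sheet$sex[match(colnames(gm), sheet$sample_id)]
  .assert(all(c("M", "F") %in% sex), "both sexes must be present")
  matrix((sex == "M") + 0, ncol = 1L)
}

# -- user-facing screens -----------------------------------------------------

#' Screen for sex linkage via allele frequencies (approach "freq")
#'
#' Flags a locus when the putative X (or Z) allele — the major allele among
#' calls of the homogametic sex — has frequency at least 0.95 in the
#' homogametic sex and frequency within \[0.4, 0.6\] in the heterogametic
#' sex, the pattern produced by a fully penetrant Y- (or W-) specific SNP.
#' Frequencies use non-missing calls only; loci with no calls in either sex
#' are counted as unevaluable, never flagged.
#'
#' @param gm Genotype matrix (ideally already passed through
#'   [filter_loci()]).
#' @param sheet Sample sheet.
#' @param orientation `"XY"` or `"ZW"`.
#' @param params A [screen_params()] object.
#' @return A `marker_set`: flagged marker ids plus per-marker supporting
#'   statistics.
#' @export
screen_allele_freq <- function(gm, sheet, orientation = c("XY", "ZW"),
                               params = screen_params()) {
  orientation <- match.arg(orientation)
  .check_gm(gm)
  member <- .sex_member(gm, sheet)
  counts <- .group_counts(.geno_indicators(gm), member)
  gr <- .orient_groups(counts, orientation)
  res <- .flag_freq(gr$homo, gr$hetero, params)
  flagged <- which(res$flag[, 1])
  stats <- data.frame(locus_id = rownames(gm)[flagged],
                      x_freq_homogametic = res$x_homo[flagged, 1],
                      x_freq_heterogametic = res$x_hetero[flagged, 1],
                      stringsAsFactors = FALSE)
  .new_marker_set("freq", orientation, rownames(gm)[flagged], stats,
                  sum(res$unevaluable[, 1]))
}

#' Screen for sex linkage via heterozygosity patterns (approach "het")
#'
#' Flags a locus when it is homozygous in every non-missing call of the
#' homogametic sex and heterozygous in at least half of the non-missing
#' calls of the heterogametic sex.  More stringent than the
#' allele-frequency screen: a frequency near 0.5 can arise by chance or
#' from population structure, whereas ubiquitous single-sex heterozygosity
#' cannot.
#'
#' @inheritParams screen_allele_freq
#' @return A `marker_set`.
#' @export
screen_heterozygosity <- function(gm, sheet, orientation = c("XY", "ZW"),
                                  params = screen_params()) {
  orientation <- match.arg(orientation)
  .check_gm(gm)
  member <- .sex_member(gm, sheet)
  counts <- .group_counts(.geno_indicators(gm), member)
  gr <- .orient_groups(counts, orientation)
  res <- .flag_het(gr$homo, gr$hetero, params)
  flagged <- which(res$flag[, 1])
  stats <- data.frame(
    locus_id = rownames(gm)[flagged],
    het_fraction_heterogametic = res$het_fraction_heterogametic[flagged, 1],
    stringsAsFactors = FALSE)
  .new_marker_set("het", orientation, rownames(gm)[flagged], stats,
                  sum(res$unevaluable[, 1]))
}

#' Screen for sex-limited RADtags (approach "sex_limited")
#'
#' Flags a tag present in none of the homogametic-sex samples and in at
#' least half of the heterogametic-sex samples — the signature of
#' Y-specific restriction sites, X-chromosome null alleles, or under-merged
#' highly diverged gametologs.
#'
#' @param tags 0/1 tag presence matrix (tags x samples).
#' @inheritParams screen_allele_freq
#' @return A `marker_set`.
#' @export
screen_sex_limited <- function(tags, sheet, orientation = c("XY", "ZW"),
                               params = screen_params()) {
  orientation <- match.arg(orientation)
  .assert(is.matrix(tags) && all(tags %in% 0:1),
          "`tags` must be a 0/1 matrix")
  .check_sheet(sheet, colnames(tags))
  sex <- sheet$sex[match(colnames(tags), sheet$sample_id)]
  .assert(all(c("M", "F") %in% sex), "both sexes must be present")
  member <- matrix((sex == "M") + 0, ncol = 1L)
  pres_m <- tags %*% member
  pres_f <- rowSums(tags) - pres_m
  n_m <- sum(member); n_f <- length(sex) - n_m
  if (orientation == "XY")
    res <- .flag_tags(pres_f, pres_m, n_f, n_m, params)
  else
    res <- .flag_tags(pres_m, pres_f, n_m, n_f, params)
  flagged <- which(res$flag[, 1])
  stats <- data.frame(
    locus_id = rownames(tags)[flagged],
    presence_fraction_heterogametic =
      res$presence_fraction_heterogametic[flagged, 1],
    stringsAsFactors = FALSE)
  .new_marker_set("sex_limited", orientation, rownames(tags)[flagged], stats)
}

#' Run all six screens (three approaches x two orientations)
#'
#' @param gm Genotype matrix.
#' @param tags Tag presence matrix (same samples as `gm`).
#' @param sheet Sample sheet.
#' @param params A [screen_params()] object.
#' @return A `screen_report`: list with `sets` (named list of six
#'   `marker_set`s, names like `"freq_XY"`) and `overlap_freq_het` (per
#'   orientation, the intersection size of the freq and het sets).
#' @export
run_all_screens <- function(gm, tags, sheet, params = screen_params()) {
  sets <- list()
  for (orient in c("XY", "ZW")) {
    sets[[paste0("freq_", orient)]] <-
      screen_allele_freq(gm, sheet, orient, params)
    sets[[paste0("het_", orient)]] <-
      screen_heterozygosity(gm, sheet, orient, params)
    sets[[paste0("sex_limited_", orient)]] <-
      screen_sex_limited(tags, sheet, orient, params)
  }
  overlap <- vapply(c("XY", "ZW"), function(orient) {
    length(intersect(sets[[paste0("freq_", orient)]]$markers,
                     sets[[paste0("het_", orient)]]$markers))
  }, integer(1))
  structure(list(sets = sets, overlap_freq_het = overlap),
            class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  cat("screen_report:\n")
  for (nm in names(x$sets))
    cat(sprintf("  %-16s %d marker(s)\n", nm, length(x$sets[[nm]]$markers)))
  cat(sprintf("  freq/het overlap: XY %d, ZW %d\n",
              x$overlap_freq_het[["XY"]], x$overlap_freq_het[["ZW"]]))
  invisible(x)
}

#' Write a list of marker sets as one TSV
#'
#' @param sets A list of `marker_set` objects (e.g. `report$sets`).
#' @param path Output path.
#' @export
write_marker_sets <- function(sets, path) {
  rows <- lapply(sets, function(s) {
    if (length(s$markers) == 0L) return(NULL)
    data.frame(marker_id = s$markers, approach = s$approach,
               orientation = s$orientation, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(marker_id = character(), approach = character(),
                      orientation = character())
  con <- .open_maybe_gz(path, "wt")
  on.exit(close(con))
  writeLines(paste0("#", paste(names(out), collapse = "\t")), con)
  if (nrow(out))
    write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  invisible(path)
}
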