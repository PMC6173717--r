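# Sex-chromosome identification: tally where validated sex-linked markers
# align, and compare each chromosome's tally against a null built from
# random same-size subsets of the whole marker catalogue.  The random-subset
# null absorbs chromosome-specific mapping-rate biases (assembly coverage,
# repeat content) that would otherwise masquerade as sex linkage.

#' Chromosome-assignment configuration
#'
#' @param n_random_subsets Number of random catalogue subsets for the null.
#' @param percentile Null percentile an observed count must strictly exceed.
#' @param min_markers_on_chrom Minimum observed sex-linked markers aligning
#'   to a chromosome for it to be identifiable (applies to observed counts
#'   only, never to null replicates).
#' @param seed RNG seed.
#' @param replace Sample catalogue subsets with replacement (default FALSE:
#'   a subsample in the strict sense).
#' @export
assignment_config <- function(n_random_subsets = 1000L, percentile = 99,
                              min_markers_on_chrom = 10L, seed = NULL,
                              replace = FALSE) {
  .assert(n_random_subsets >= 1, "`n_random_subsets` must be >= 1")
  .assert(percentile > 0 && percentile < 100, "`percentile` must be in (0, 100)")
  .assert(min_markers_on_chrom >= 1, "`min_markers_on_chrom` must be >= 1")
  structure(list(n_random_subsets = as.integer(n_random_subsets),
                 percentile = percentile,
                 min_markers_on_chrom = as.integer(min_markers_on_chrom),
                 seed = seed, replace = isTRUE(replace)),
            class = "assignment_config")
}

#' Chromosome of each query, via its retained best hit
#' @noRd
.chrom_of <- function(ids, filtered_hits, scaffold_map, warn = TRUE) {
  hit_row <- match(ids, filtered_hits$qseqid)
  scaf <- filtered_hits$sseqid[hit_row]
  chrom <- scaffold_map$chromosome[match(scaf, scaffold_map$scaffold)]
  unplaced <- !is.na(scaf) & is.na(chrom)
  if (warn && any(unplaced))
    warning(sprintf("%d marker(s) hit scaffolds absent from the map; counted as unplaced",
                    sum(unplaced)), call. = FALSE)
  list(chrom = chrom, n_unaligned = sum(is.na(scaf)),
       n_unplaced = sum(unplaced))
}

#' Tally sex-linked markers per chromosome
#'
#' Each marker contributes to at most one chromosome: the chromosome of the
#' scaffold carrying its retained best hit (see
#' [filter_alignment_hits()]).  Markers without a retained hit are counted
#' as unaligned; hits to scaffolds missing from the map are counted as
#' unplaced (with a warning).
#'
#' @param markers A `marker_set` or a character vector of marker ids.
#' @param filtered_hits Best-hit table from [filter_alignment_hits()].
#' @param scaffold_map Data frame `scaffold`, `chromosome`.
#' @return List with `counts` (named integer vector over all chromosomes in
#'   the map, zero-padded names sorted), `n_unaligned`, `n_unplaced`.
#' @export
assign_markers <- function(markers, filtered_hits, scaffold_map) {
  ids <- if (inherits(markers, "marker_set")) markers$markers else markers
  chroms <- sort(unique(scaffold_map$chromosome))
  res <- .chrom_of(ids, filtered_hits, scaffold_map)
  counts <- table(factor(res$chrom, levels = chroms))
  list(counts = setNames(as.integer(counts), chroms),
       n_unaligned = res$n_unaligned, n_unplaced = res$n_unplaced)
}

#' Per-chromosome null from random catalogue subsets
#'
#' Each replicate draws `set_size` markers uniformly (without replacement by
#' default) from the full catalogue and tallies their per-chromosome
#' alignment counts, giving the expected alignment distribution for a
#' marker set of that size with no sex signal.
#'
#' @param catalogue_ids All marker ids in the catalogue (must contain the
#'   sex-linked set).
#' @param filtered_hits,scaffold_map As in [assign_markers()].
#' @param set_size Size of each random subset (the sex-linked set size).
#' @param config An [assignment_config()] object.
#' @return Matrix `n_random_subsets` x chromosomes of null counts.
#' @export
random_subset_null <- function(catalogue_ids, filtered_hits, scaffold_map,
                               set_size, config = assignment_config()) {
  .assert(set_size <= length(catalogue_ids) || config$replace,
          "`set_size` (%d) exceeds the catalogue (%d)",
          set_size, length(catalogue_ids))
  .seed_if(config$seed)
  chroms <- sort(unique(scaffold_map$chromosome))
  chrom <- .chrom_of(catalogue_ids, filtered_hits, scaffold_map,
                     warn = FALSE)$chrom
  chrom_idx <- match(chrom, chroms)            # NA = unaligned/unplaced
  null <- matrix(0L, config$n_random_subsets, length(chroms),
                 dimnames = list(NULL, chroms))
  n <- length(catalogue_ids)
  for (r in seq_len(config$n_random_subsets)) {
    pick <- sample.int(n, set_size, replace = config$replace)
    null[r, ] <- tabulate(chrom_idx[pick], nbins = length(chroms))
  }
  null
}

#' Identify the sex chromosome
#'
#' A chromosome passes when its observed sex-linked marker count is at
#' least `min_markers_on_chrom` *and* strictly exceeds the `percentile`
#' threshold of its random-subset null.  With no passing chromosome the
#' identification is "none"; if several pass, all are reported and flagged
#' rather than forced to a single winner.
#'
#' @param counts Named observed counts from [assign_markers()].
#' @param null Null matrix from [random_subset_null()] over the same
#'   chromosomes.
#' @param config An [assignment_config()] object.
#' @return List of class `chrom_assignment`: `table` (per-chromosome
#'   observed, null mean, null threshold, pass) and `identified` (character
#'   vector of passing chromosomes, length 0 when none).
#' @export
identify_sex_chromosome <- function(counts, null,
                                    config = assignment_config()) {
  .assert(identical(sort(names(counts)), sort(colnames(null))),
          "`counts` and `null` must cover identical chromosome sets")
  chroms <- names(counts)
  thr <- vapply(chroms, function(cc)
    .null_threshold(null[, cc], config$percentile, warn = FALSE), numeric(1))
  pass <- counts >= config$min_markers_on_chrom & counts > thr
  tab <- data.frame(chromosome = chroms,
                    observed = as.integer(counts),
                    null_mean = colMeans(null[, chroms, drop = FALSE]),
                    null_threshold = as.numeric(thr),
                    pass = as.logical(pass),
                    row.names = NULL, stringsAsFactors = FALSE)
  identified <- chroms[pass]
  if (length(identified) > 1L)
    warning(sprintf("multiple chromosomes pass (%s); all reported",
                    paste(identified, collapse = ", ")), call. = FALSE)
  structure(list(table = tab, identified = identified),
            class = "chrom_assignment")
}

#' @export
print.chrom_assignment <- function(x, ...) {
  cat("chrom_assignment:",
      if (length(x$identified)) paste(x$identified, collapse = ", ")
      else "none identified", "\n")
  print(x$table, digits = 3)
  invisible(x)
}
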